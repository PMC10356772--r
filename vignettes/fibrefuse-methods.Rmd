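---
title: "Models and methods in fibrefuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fibrefuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrefuse)
```

fibrefuse analyses co-registered diffusion MRI and section microscopy of the
same tissue: polarised light imaging (PLI) and myelin-stained histology give
in-plane fibre orientations at micrometre resolution, diffusion MRI gives 3D
orientations at millimetre resolution, and the package fuses the two into
hybrid 3D fibre orientations at microscopy resolution. Because co-registered
multimodal data of this kind are rare and large, every stage is paired with a
synthetic phantom generator that renders the same ground-truth fibre field as
diffusion-weighted volumes, polarimetric stacks and oriented-texture
histology, so the whole chain is testable end to end.

## The ground-truth fibre field and its renderings

A `fibre_field` is a voxel grid in which each voxel holds up to three fibre
populations (unit axis, signal fraction $f_i$, axial concentration
$\kappa_b$; $\infty$ means no dispersion) plus an isotropic "ball" fraction
$1-\sum f_i$. Four recipes cover the canonical white-matter geometries:
coherent bundle, two interdigitated bundles crossing at a fixed angle, a
linear fan, and a sinusoidal undulation.

**Diffusion MRI.** The forward signal is the ball-and-stick model
$$S(\mathbf g, b) = S_0\Big[(1-\textstyle\sum_i f_i)\,e^{-bd} +
\sum_i f_i \langle e^{-bd(\mathbf g\cdot\mathbf n)^2}\rangle_{\mathrm{FOD}_i}\Big],$$
with $b$ in ms/um^2 and $d$ in um^2/ms. Dispersed populations average the
stick response over an axial Watson density by quadrature on the shared
antipodally paired sphere grid. Spherical tensor encoding attenuates each
compartment by its mean diffusivity ($d$ for the ball, $d/3$ for sticks).
Noise is Rician — the standard model for magnitude MR — with `noise_sigma`
in $S_0$ units; microscopy renderings use additive Gaussian noise. Default
diffusivity is $d = 0.1$ um^2/ms, a typical fixed ex-vivo white-matter
value, so $b d \le 1$ across the 4/7/10 ms/um^2 shells.

**PLI.** Frame $k$ at analyser angle $\rho_k = k\,(180^\circ/9)$ (nine
equidistant steps, the duplicate 180 degree endpoint excluded so the discrete
Fourier inversion is exact) has
$$I(\rho_k) = \tfrac{I_T}{2}\Big[1 + \sum_i f_i \sin(\delta_{\max}\cos^2\alpha_i)
\sin(2\rho_k - 2\varphi_i)\Big],$$
where $\varphi_i$ and $\alpha_i$ are the population's in-plane and
through-plane angles in the section frame. Components mix linearly at
intensity level; this reproduces the signature cancellation of perpendicular
equal crossings (dark bands between tracts) without a full Jones-matrix
treatment. $\delta_{\max}$ defaults to $\pi/2$, so a fully in-plane fibre has
retardance 1.

**Histology.** Oriented texture is rendered as long (about 120 px)
anti-aliased dark strokes on a bright background; stroke density scales with
the local stick fraction and each stroke's local tangent follows the
population axis plus an angular jitter drawn from the population's
dispersion. The jitter is drawn per spatial correlation cell (20 px) rather
than i.i.d. per stroke: angular variation on scales below the structure
tensor's 10 px integration window is provably invisible to any
structure-tensor pipeline (the tensor averages it away), so realisable
dispersion must live at larger scales — as it does in real fibre bundles.
Strokes are splatted bilinearly onto an additive ink canvas, blurred slightly
and mapped through a smooth saturation, because staircase edges and
along-stroke intensity ripple would otherwise inject spurious off-axis
gradient energy.

What the phantom does *not* emulate: stain chemistry, patchy staining and
bubble artefacts, section deformation, and whole-brain geometry. Passing
recovery tests on these textures therefore demonstrates that the estimator
chain is calibrated and self-consistent, not that it is robust to every
artefact of real slides.

## Gradient schemes

`generate_directions()` minimises the antipodally symmetric electrostatic
energy $\sum_{i<j} 1/|\mathbf g_i-\mathbf g_j| + 1/|\mathbf g_i+\mathbf g_j|$
by projected gradient descent with backtracking (energy is non-increasing by
construction). `order_incremental()` reorders a set so that any leading
subset keeps good coverage if a scan is cut short. Plain greedy maximin
appending leaves early prefixes well below what a freely optimised subset of
that size achieves, so the implementation builds a hierarchy of nested
subsets (each about 80% of the next) by greedy selection plus exchange
polishing, with simulated-annealing refinement at sizes up to 64 where the
greedy gap is largest. A nested prefix can still not match a *fresh*
electrostatic set: on a 60-direction set the best free 10-subset reaches only
about 86% of a fresh 10-set's minimal pairwise angle, and prefixes are
additionally constrained to be nested — the tests assert the achievable
level (75%). Coverage is quantified as the minimal pairwise axial angle in
degrees; the threshold for consecutive-direction separation in
`interleave_batches()` defaults to 10 degrees, with one $b\approx 0$ volume
inserted before each batch of 25 diffusion-weighted volumes and a repair pass
that swaps batch positions until consecutive directions clear the threshold.

## PLI inversion

With equidistant angles the per-pixel Fourier components
$a_0=\overline I$, $a_2=\frac2N\sum I_k\cos 2\rho_k$,
$b_2=\frac2N\sum I_k\sin 2\rho_k$ give transmittance $I_T=2a_0$, retardance
$r=\sqrt{a_2^2+b_2^2}/a_0$ and in-plane angle
$\varphi=\tfrac12\mathrm{atan2}(-a_2,b_2)$ exactly; non-equidistant stacks
fall back to least-squares harmonic regression on the same model. Pixels with
$r \le r_{\min}$ (default 0.01) carry no orientation and are flagged invalid.
Under the constant-myelin assumption the inclination is
$\alpha=\arccos\sqrt{\arcsin(r)/\delta_{\max}}$; it inherits the arbitrary
$\delta_{\max}$ and is intended for co-registration and fusion, not as a
quantitative microscopy metric. Flat-field correction divides each frame by
the background frame normalised to its global mean; a mean-one vignette is
removed exactly. Angles are measured counter-clockwise from the image x axis
and are axial (modulo 180 degrees) throughout.

## Structure tensor and superpixel dispersion

Gradients are computed by Gaussian-derivative filtering at
$\sigma_{\mathrm{deriv}} = 1$ px and the tensor components averaged at the
integration scale $\sigma_{\mathrm{window}} = 10$ px — the 10 px kernel is
read as the integration scale, its most common meaning; the derivative scale
is a separate, smaller parameter. The fibre angle is perpendicular to the
dominant gradient, and the coherence $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
grades local anisotropy. 150 px superpixels pool valid pixels into 2-degree
axial histograms weighted by coherence (switchable off).

The superpixel concentration $\kappa$ is the axial von Mises maximum
likelihood — the exact 2D restriction of the Bingham distribution — obtained
by inverting the Bessel ratio $I_1(\kappa)/I_0(\kappa)=\bar R$ and capped at
$10^4$; $\mathrm{ODI} = \tfrac2\pi\arctan(1/\kappa)$. The resultant $\bar R$
is computed as the energy-weighted tensor phasor over the summed tensor
energy, $\bar R = |\sum \mathrm{tr}\,c\,e^{2i\theta}| / \sum \mathrm{tr}$
(tr = tensor trace, $c$ = coherence): a blended pixel's
$\mathrm{tr}\,c\,e^{2i\theta}$ is exactly the vector sum of the orientation
content mixed under the averaging window, so this estimator is invariant to
sub-window blending, whereas dividing by the summed coherence inflates the
concentration wherever the window mixes orientations. Residual biases that
remain are the finite number of independent orientation patches per
superpixel (which biases $\bar R$ upward at high dispersion) and a small
orientation-noise floor from stroke ends; across ODI targets
{0.05, 0.1, 0.3, 0.6} the mean absolute recovery error is about 0.04.

## Diffusion and relaxometry fitting

**Preprocessing.** Signal drift is removed multiplicatively: a line
$S_0(t)=c_0+c_1 t$ is fitted to the mean $b\approx0$ intensities and every
volume at time $t$ divided by $(1+c_1t/c_0)$. Normalisation divides by the
mean $b\approx0$ volume (or a designated reference shell), masking
non-positive reference voxels.

**DTI** is the log-linear least-squares fit of the six tensor elements plus
$\log S_0$, with FA/MD/V1 from the eigendecomposition.

**Ball-and-stick** fitting is staged: sticks are added one at a time, each
initialised from the DTI first eigenvector (first stick) or from the gradient
direction where the current model most over-predicts the signal (a missing
stick depresses the signal along its own axis), with one fixed and one seeded
random restart; short Levenberg-Marquardt runs screen the candidates and the
best is polished with an analytic Jacobian. A population is kept only if it
improves the Bayesian information criterion and carries $f\ge0.05$.
Orientation samples (50 per population) come from a residual bootstrap:
resampled residuals are added to the fitted curve and the model refitted from
the point estimate by damped Gauss-Newton with the Jacobian frozen at the
optimum (three steps suffice there; a short LM run is the fallback). This is
a deterministic-seeded, dependency-free stand-in for MCMC posterior samples
with the same downstream contract. The precision of a sample set is the
dyadic cone half-angle $\arccos\sqrt{\lambda_{\max}}$ of
$\langle\mathbf{vv}^T\rangle$: 0 for identical samples, 54.7 degrees for
isotropic ones.

**Ball-and-rackets** replaces each stick with a Bingham FOD
($\kappa_1\le\kappa_2$, two spread axes) integrated against the stick
response by quadrature. The quadrature grid is expressed in the Bingham body
frame and rotated with the fitted axis (one node pinned to the FOD peak), so
the model stays smooth in orientation up to the concentration cap of 256 —
the sharpest FOD the grid resolves; beyond it every node weight underflows
and the gradients vanish. The fit uses a 1024-point quadrature: resolving a
tight spread axis ($\kappa\approx16$) requires quadrature error below the
small signal difference it produces, which a 256-point grid cannot deliver.
Starts are asymmetric in $(\kappa_1,\kappa_2)$ at two spread-frame angles
(the symmetric point is a saddle where the frame angle is unidentifiable),
plus a near-isotropic start. Distinguishing an isotropic-FOD stick
compartment from a faster ball requires multi-shell data; on a single shell
the two are exactly degenerate.

**DIVIDE.** Powder (directional) averages per shell and encoding are fitted
with the Laplace transform of a gamma diffusivity distribution,
$S(b)/S_0 = (1+b\,\mu_2/\mu_1)^{-\mu_1^2/\mu_2}$, sharing the mean
diffusivity $\mu_1$ across encodings. The spherical-encoding second moment
isolates isotropic heterogeneity $V_{\mathrm{iso}}$; the linear encoding adds
the anisotropic variance $\Delta V = \mu_2^{\mathrm{lin}}-\mu_2^{\mathrm{sph}}$,
and
$$\mu\mathrm{FA} = \sqrt{\tfrac32}\sqrt{\frac{\Delta V}
{\Delta V + \tfrac25(\mu_1^2 + V_{\mathrm{iso}})}},$$
which reduces to the FA of a single microtensor when all microtensors are
identical and merely reoriented — the package's validation oracle (for
eigenvalues (2, 0.5, 0.5) um^2/ms, $\mu$FA $= \sqrt{0.5}$). $\Delta V<0$
within fit noise clamps $\mu$FA to 0 and flags the voxel. The oracle
simulations use shells at $b$ = 0.2–2 ms/um^2 so that $b\,\mathrm{MD}\le2$,
the cumulant regime in which the gamma approximation is accurate for these
microtensors; this mirrors how the ex-vivo shells at $b$ = 4–10 ms/um^2 pair
with diffusivities an order of magnitude lower.

**T1 mapping** fits $S(\mathrm{TI}) = a + b\,e^{-\mathrm{TI}/T_1}$ per
voxel. The model is linear in $(a,b)$ given $T_1$, so a log-spaced $T_1$ grid
(20 nodes, 10–6000 ms) is solved linearly and the best node polished by LM.
With perfect inversion the fitted curve crosses zero at
$\mathrm{TI} = T_1\ln 2$.

## Fusion

Section planes are right-handed orthonormal frames with a pixel-to-voxel
affine. Projection onto the plane gives the axial in-plane angle
$\mathrm{atan2}(\mathbf a\cdot\mathbf e_2, \mathbf a\cdot\mathbf e_1)$ and
in-plane magnitude; axes along the normal are flagged. 2D FODs are 2-degree
axial histograms; their ODI reuses the superpixel estimator on bin centres
weighted by mass. The modality comparison regression is ordinary least
squares with $F=(n-2)R^2/(1-R^2)$ against the intercept-only model.

**Hybrid matching.** Per valid microscopy pixel, the ball-and-stick samples
of the underlying voxel (populations with $f\ge0.05$) are projected onto the
plane and the sample with the smallest axial in-plane difference to the
microscopy angle is selected ("most similar" is read as this angular
difference; ties break towards the higher-fraction population, then the lower
sample index). The hybrid axis keeps the microscopy in-plane angle — the
higher-confidence in-plane information — and takes only the through-plane
(inclination) angle from the matched sample, signed by orienting the sample
along the microscopy direction. Samples enter unweighted once past the
fraction threshold; fraction-weighted matching is a possible variant the
package does not implement.

**3D histograms and export.** Hybrid axes populate per-voxel histograms on
the shared 256-point electrostatic sphere grid, stored with explicit
antipodal pairing; each axis contributes half its weight to both paired
points, so the histogram is exactly symmetric under $\mathbf v\to-\mathbf v$.
Order-8 real even spherical harmonics (45 coefficients) are fitted by least
squares — band-limited inputs are reproduced exactly — and exported as a
45-volume NIfTI in the real-SH convention of common tractography software
($m<0\to\sqrt2\,\mathrm{Im}\,Y_l^{|m|}$, $m=0\to Y_l^0$,
$m>0\to\sqrt2\,\mathrm{Re}\,Y_l^m$; Condon-Shortley phase included), with a
JSON sidecar recording basis and ordering since the convention is fixed by
the downstream tool rather than asserted.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: uniform images are wholly invalid
(tensor-trace floor with an absolute guard against FFT round-off), perfectly
aligned angles hit the concentration cap, empty FODs and sub-threshold
populations are flagged rather than fitted. All simulators are
bit-reproducible given (configuration, seed), and every stochastic routine
takes an explicit seed.

The shipped validation suite runs at desk scale by design: recovery sweeps
use 300–450 px texture images over 20 seeds, the crossing-fibre benchmark
fits 1000 voxels at 250 directions, the angular-resolution study fits 500
voxels across direction subsets {64, 128, 250, 500, 1000} at SNR 20 (two
populations searched, since the phantom contains two), and the fusion
end-to-end check uses a 6 x 6 x 2 voxel crossing phantom sectioned at 20
pixels per voxel with a 500-direction shell. These sizes estimate the same
quantities as larger runs with proportionally wider Monte-Carlo error.

## Known limitations

Inclination from retardance is sign-ambiguous and quantitatively unreliable
by construction; the hybrid axis resolves the through-plane sign from the
diffusion samples. The PLI forward model mixes populations at intensity
level, so strong multi-population interference beyond the documented
cancellation is approximate. The superpixel concentration estimator remains
biased upward (ODI biased low) when fewer than a few dozen independent
orientation patches fall in a superpixel, and biased in the opposite
direction by texture below the tensor window — both are properties of the
measurement geometry, not removable by the estimator. The ball-and-rackets
concentration is only resolved up to the quadrature cap, and distinguishing
dispersion anisotropy ($\kappa_1\ne\kappa_2$) requires high-b, high-SNR
data.
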