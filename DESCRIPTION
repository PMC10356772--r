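Package: fibrefuse
Title: Co-Registered Diffusion MRI and Microscopy Fibre Orientation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of diffusion MRI and polarised light
    imaging (PLI) or myelin-stained histology of the same tissue. Includes a
    synthetic phantom generator producing co-registered multi-shell diffusion
    MRI, polarimetric image stacks and oriented-texture histology from a known
    ground-truth fibre field; electrostatic gradient-scheme generation with
    incremental ordering and batch interleaving; inversion of PLI stacks into
    transmittance, retardance, in-plane angle and inclination maps;
    structure-tensor orientation mapping with superpixel fibre orientation
    distributions and dispersion indices; diffusion and relaxometry model
    fitting (DTI, ball-and-stick with bootstrap orientation samples,
    ball-and-rackets, DIVIDE gamma fitting for microscopic anisotropy, Barral
    inversion-recovery T1); and fusion of the modalities into hybrid 3D fibre
    orientations, spherical orientation histograms and order-8 spherical
    harmonic images for tractography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    RNifti,
    tiff,
    jsonlite,
    minpack.lm,
    pracma,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
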