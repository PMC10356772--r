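# Shared fixtures: small schemes, phantoms and oracle helpers built in code.

# single-shell scheme with one leading b=0
shell_scheme <- function(n_dirs, b, seed = 1L) {
  dirs <- generate_directions(n_dirs, seed = seed)
  gradient_scheme(rbind(c(0, 0, 1), dirs), c(0, rep(b, n_dirs)))
}

# noiseless synthetic pixel intensities of the polarimetric sinusoid
pli_pixel_signal <- function(angles_deg, phi_deg, r, mean_intensity = 0.5) {
  mean_intensity * (1 + r * sin(2 * angles_deg * pi / 180 - 2 * phi_deg * pi / 180))
}

# stack with one uniform synthetic pixel value per (phi, r) combination
synthetic_pli_stack <- function(phi_deg, r, n_frames = 9, mean_intensity = 0.5) {
  angs <- (seq_len(n_frames) - 1) * 180 / n_frames
  fr <- array(NA_real_, c(length(phi_deg), 1, n_frames))
  for (k in seq_len(n_frames))
    fr[, 1, k] <- pli_pixel_signal(angs[k], phi_deg, r, mean_intensity)
  pli_stack(fr, angs)
}

# sinusoidal grating with stripes along `angle_deg` (x = col, y = row)
grating_image <- function(angle_deg, H = 180, W = 180, period = 8) {
  k <- 2 * pi / period
  rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
  a <- angle_deg * pi / 180
  0.5 + 0.4 * sin(k * (-sin(a) * cc + cos(a) * rr))
}

# orientationally averaged stick attenuation (closed form)
powder_stick_analytic <- function(bd) {
  sqrt(pi) / (2 * sqrt(bd)) * pracma::erf(sqrt(bd))
}

expect_axial_close <- function(a, b, tol) {
  expect_lt(max(axial_diff(a, b)), tol)
}
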