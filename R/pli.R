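# Polarised light imaging: stack container, flat-field correction, sinusoid
# inversion into transmittance/retardance/in-plane-angle maps, inclination
# estimation and HSV rendering.
#
# The polarimetric signal of birefringent myelin under a rotating analyser is
# pi-periodic: I(rho) = (I_T/2) * (1 + r * sin(2 rho - 2 phi)), where I_T is
# the transmittance, r the retardance (relative modulation amplitude) and phi
# the in-plane fibre angle.

#' Construct a PLI stack
#'
#' @param frames `H x W x N` array of intensities (one page per analyser
#'   angle).
#' @param analyser_angles Analyser angles in degrees, strictly increasing in
#'   [0, 180); default `k * 180/N`, k = 0..N-1.
#' @param pixel_size Pixel size in um.
#' @param section_thickness Section thickness in um.
#' @return A `pli_stack` object.
#' @export
pli_stack <- function(frames, analyser_angles = NULL, pixel_size = 4,
                      section_thickness = 50) {
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (n < 3) stop("need at least 3 frames")
  if (is.null(analyser_angles)) analyser_angles <- (seq_len(n) - 1) * 180 / n
  if (length(analyser_angles) != n) stop("one angle per frame required")
  if (any(diff(analyser_angles) <= 0) || any(analyser_angles < 0) ||
      any(analyser_angles >= 360))
    stop("angles must be strictly increasing within [0, 360)")
  if (any(frames < 0, na.rm = TRUE)) stop("negative intensities")
  structure(list(frames = frames, analyser_angles = analyser_angles,
                 pixel_size = pixel_size, section_thickness = section_thickness),
            class = "pli_stack")
}

#' @export
print.pli_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("PLI stack:", d[1], "x", d[2], "pixels,", d[3], "frames at",
      paste0(round(x$analyser_angles, 1), collapse = ", "), "deg\n")
  cat("  pixel", x$pixel_size, "um, section", x$section_thickness, "um\n")
  invisible(x)
}

#' Flat-field (background) correction of a PLI stack
#'
#' Divides each pixel of each frame by the background frame normalised to its
#' global mean, removing light-source variation across the field of view while
#' preserving overall intensity scale. A spatially uniform background leaves
#' the stack unchanged. Non-positive background pixels are masked to `NA`.
#'
#' @param stack A `pli_stack` acquired with tissue.
#' @param background_stack A `pli_stack` acquired with no tissue in the same
#'   geometry (same frame count).
#' @return A corrected `pli_stack`.
#' @export
flatfield_correct <- function(stack, background_stack) {
  stopifnot(inherits(stack, "pli_stack"), inherits(background_stack, "pli_stack"))
  if (!all(dim(stack$frames) == dim(background_stack$frames)))
    stop("stack and background dimensions differ")
  out <- stack$frames
  for (k in seq_len(dim(out)[3])) {
    B <- background_stack$frames[, , k]
    bad <- !(B > 0)
    Bn <- B / mean(B[!bad])
    Bn[bad] <- NA
    out[, , k] <- stack$frames[, , k] / Bn
  }
  res <- stack
  res$frames <- out
  res
}

#' Fit the pixelwise polarimetric sinusoid
#'
#' Inverts a PLI stack into transmittance, retardance and in-plane angle maps.
#' For equidistant analyser angles covering one period of the `2 rho` harmonic
#' the discrete Fourier solution is exact: with `a0 = mean(I)`,
#' `a2 = (2/N) sum I_k cos(2 rho_k)`, `b2 = (2/N) sum I_k sin(2 rho_k)`:
#' `I_T = 2 a0`, `r = sqrt(a2^2 + b2^2)/a0`, `phi = atan2(-a2, b2)/2 mod 180`.
#' Non-equidistant angles fall back to per-pixel least-squares harmonic
#' regression (same model), with a message.
#'
#' @param stack A `pli_stack`.
#' @param r_min Validity threshold on retardance: pixels with `r <= r_min`
#'   carry no orientation information and are flagged invalid.
#' @return A `pli_maps` object with elements `transmittance`, `retardance`,
#'   `angle` (degrees in [0,180)), `valid`, and `NULL` `inclination` until
#'   [estimate_inclination()] is run.
#' @export
fit_pli_sinusoid <- function(stack, r_min = 0.01) {
  stopifnot(inherits(stack, "pli_stack"))
  A <- stack$analyser_angles
  n <- length(A)
  fr <- stack$frames
  H <- dim(fr)[1]; W <- dim(fr)[2]
  Y <- matrix(fr, H * W, n)  # pixels x frames
  rho <- deg2rad(A)
  equi <- (max(abs(diff(A) - 180 / n)) < 1e-9) && abs(A[1]) < 1e-9
  if (equi) {
    a0 <- rowMeans(Y)
    a2 <- (2 / n) * as.vector(Y %*% cos(2 * rho))
    b2 <- (2 / n) * as.vector(Y %*% sin(2 * rho))
  } else {
    message("non-equidistant analyser angles: using least-squares harmonic regression")
    X <- cbind(1, cos(2 * rho), sin(2 * rho))
    cf <- t(qr.solve(X, t(Y)))
    a0 <- cf[, 1]; a2 <- cf[, 2]; b2 <- cf[, 3]
  }
  amp <- sqrt(a2^2 + b2^2)
  r <- ifelse(a0 > 0, amp / a0, NA_real_)
  phi <- wrap_axial(rad2deg(atan2(-a2, b2) / 2))
  valid <- !is.na(r) & a0 > 0 & r > r_min
  phi[!valid] <- NA_real_
  structure(list(transmittance = matrix(2 * a0, H, W),
                 retardance = matrix(pmin(pmax(r, 0), 1), H, W),
                 angle = matrix(phi, H, W),
                 inclination = NULL,
                 valid = matrix(valid, H, W),
                 pixel_size = stack$pixel_size,
                 section_thickness = stack$section_thickness),
            class = "pli_maps")
}

#' @export
print.pli_maps <- function(x, ...) {
  cat("PLI maps:", nrow(x$retardance), "x", ncol(x$retardance), "pixels;",
      sum(x$valid), "valid\n")
  cat("  median retardance (valid):",
      round(stats::median(x$retardance[x$valid]), 4), "\n")
  if (!is.null(x$inclination)) cat("  inclination map present\n")
  invisible(x)
}

#' Estimate fibre inclination from retardance
#'
#' Assuming approximately constant myelin content across the white matter,
#' retardance relates to the through-plane (inclination) angle `alpha` as
#' `r = sin(delta_max cos^2 alpha)`; this inverts it:
#' `alpha = acos(sqrt(asin(r)/delta_max))`. Retardance above `sin(delta_max)`
#' is clipped (counted in attribute `n_clipped`). Inclination estimates
#' depend on the assumed peak retardation and are for co-registration and
#' fusion, not a quantitative microscopy metric.
#'
#' @param maps A `pli_maps` object.
#' @param delta_max Peak retardation in radians, in (0, pi/2].
#' @return The `pli_maps` with an `inclination` map (degrees, 0 = in-plane,
#'   90 = through-plane) added.
#' @export
estimate_inclination <- function(maps, delta_max = pi / 2) {
  stopifnot(inherits(maps, "pli_maps"))
  if (delta_max <= 0 || delta_max > pi / 2) stop("delta_max outside (0, pi/2]")
  r <- maps$retardance
  rmax <- sin(delta_max)
  n_clipped <- sum(r > rmax, na.rm = TRUE)
  r <- pmin(pmax(r, 0), rmax)
  alpha <- rad2deg(acos(sqrt(asin(r) / delta_max)))
  alpha[!maps$valid] <- NA_real_
  maps$inclination <- alpha
  attr(maps$inclination, "n_clipped") <- n_clipped
  maps
}

#' Render PLI maps as an HSV fibre-orientation image
#'
#' Hue encodes the in-plane angle (`phi/180`), saturation is 1, and value is
#' the retardance, so coherent in-plane fibres appear bright and saturated
#' while unmodulated pixels are black.
#'
#' @param maps A `pli_maps` object.
#' @return An `H x W x 3` RGB array in [0, 1].
#' @export
render_hsv <- function(maps) {
  stopifnot(inherits(maps, "pli_maps"))
  H <- nrow(maps$retardance); W <- ncol(maps$retardance)
  h <- wrap_axial(maps$angle) / 180
  v <- maps$retardance
  h[!maps$valid] <- 0
  v[!maps$valid] <- 0
  cols <- grDevices::hsv(pmin(pmax(as.vector(h), 0), 1 - 1e-12), 1,
                         pmin(pmax(as.vector(v), 0), 1))
  rgb <- t(grDevices::col2rgb(cols)) / 255
  array(rgb, dim = c(H, W, 3))
}
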