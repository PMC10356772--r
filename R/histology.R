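# Structure-tensor orientation mapping of stained sections and aggregation
# into superpixel fibre orientation distributions with dispersion statistics.

# Sampled Gaussian and Gaussian-derivative kernels (2D separable, built as
# outer products for a single FFT convolution via EBImage::filter2).
gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  list(x = x, g = g / sum(g))
}

conv2_replicate <- function(img, kern) {
  EBImage::filter2(img, kern, boundary = "replicate")
}

#' Structure-tensor orientation analysis
#'
#' Extracts the dominant local texture orientation per pixel of a stained
#' section. Intensity gradients are computed by Gaussian-derivative filtering
#' at scale `sigma_deriv`; the tensor components `Jxx = <Ix^2>`,
#' `Jxy = <Ix Iy>`, `Jyy = <Iy^2>` are then averaged with a Gaussian window at
#' scale `sigma_window` (the integration scale). The fibre angle is
#' perpendicular to the dominant gradient:
#' `angle = atan2(2 Jxy, Jxx - Jyy)/2 + 90 mod 180`, and the coherence
#' `(l1 - l2)/(l1 + l2)` of the tensor eigenvalues grades how anisotropic the
#' local texture is. Pixels whose tensor trace falls below
#' `tensor_floor_rel * var(image)` carry no gradient energy and are invalid.
#'
#' @param image Grey-level matrix, or `H x W x 3` RGB array (converted by
#'   luminance).
#' @param sigma_deriv Derivative (noise) scale in pixels.
#' @param sigma_window Tensor-averaging (integration) scale in pixels.
#' @param tensor_floor_rel Relative validity floor on the tensor trace.
#' @return An `orientation_image`: list of `angle` (degrees in [0,180)),
#'   `coherence` in [0,1], and `valid` mask.
#' @export
structure_tensor <- function(image, sigma_deriv = 1, sigma_window = 10,
                             tensor_floor_rel = 1e-12) {
  if (length(dim(image)) == 3) {
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (min(dim(image)) < 6 * sigma_window)
    stop("image smaller than 6 * sigma_window")
  kd <- gauss_kernel_1d(sigma_deriv)
  dgd <- -kd$x / sigma_deriv^2 * kd$g  # derivative-of-Gaussian
  # x = column direction, y = row direction
  Kx <- outer(kd$g, dgd)   # rows smooth, cols differentiate -> Ix
  Ky <- outer(dgd, kd$g)   # rows differentiate, cols smooth  -> Iy
  Ix <- conv2_replicate(image, Kx)
  Iy <- conv2_replicate(image, Ky)
  kw <- gauss_kernel_1d(sigma_window)
  Kw <- outer(kw$g, kw$g)
  Jxx <- conv2_replicate(Ix * Ix, Kw)
  Jxy <- conv2_replicate(Ix * Iy, Kw)
  Jyy <- conv2_replicate(Iy * Iy, Kw)
  tr <- Jxx + Jyy
  # absolute term guards against FFT round-off on (near-)constant images
  floor_val <- max(tensor_floor_rel * stats::var(as.vector(image)),
                   1e-15 * mean(image^2), .Machine$double.xmin)
  valid <- tr > floor_val
  diff2 <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  coherence <- ifelse(valid, diff2 / tr, 0)
  # note image row index increases downwards; angles reported in the
  # mathematical x-(column), y-(row) convention used throughout
  angle <- wrap_axial(rad2deg(0.5 * atan2(2 * Jxy, Jxx - Jyy)) + 90)
  angle[!valid] <- NA_real_
  structure(list(angle = angle, coherence = pmin(pmax(coherence, 0), 1),
                 energy = tr, valid = valid),
            class = "orientation_image")
}

#' @export
print.orientation_image <- function(x, ...) {
  cat("Orientation image:", nrow(x$coherence), "x", ncol(x$coherence),
      "pixels;", sum(x$valid), "valid\n")
  invisible(x)
}

#' Maximum-likelihood axial concentration
#'
#' Fits the in-plane restriction of the Bingham distribution — the axial von
#' Mises density `p(theta) ~ exp(kappa cos 2(theta - mu))` — to axial angles.
#' The sufficient statistic is the mean resultant length `Rbar` of the doubled
#' angles; `kappa` solves `I1(kappa)/I0(kappa) = Rbar` (modified Bessel
#' ratio), capped at `kappa_max` for degenerate (perfectly aligned) data.
#'
#' @param angles Axial angles in degrees, [0, 180).
#' @param weights Optional non-negative weights.
#' @param kappa_max Cap on the concentration.
#' @return The concentration `kappa >= 0`.
#' @export
fit_axial_concentration <- function(angles, weights = NULL, kappa_max = 1e4) {
  rbar <- resultant_axial(angles, weights)
  kappa_from_resultant(rbar, kappa_max)
}

# Invert the Bessel ratio A(kappa) = I1/I0 at rbar.
kappa_from_resultant <- function(rbar, kappa_max = 1e4) {
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  if (rbar <= 1e-12) return(0)
  if (rbar >= A(kappa_max)) return(kappa_max)
  stats::uniroot(function(k) A(k) - rbar, c(1e-8, kappa_max), tol = 1e-10)$root
}

#' Orientation dispersion index from a concentration parameter
#'
#' `ODI = 2/pi * atan(1/kappa)`: 0 for perfectly aligned fibres
#' (`kappa -> Inf`), 1 for isotropic dispersion (`kappa = 0`).
#'
#' @param kappa Concentration(s), `>= 0`.
#' @return ODI value(s) in [0, 1].
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("negative kappa")
  2 / pi * atan(1 / kappa)
}

#' Aggregate an orientation image into superpixels
#'
#' Tiles the image into square superpixels and, per tile, pools the valid
#' pixel orientations into a 2-degree-bin fibre orientation distribution
#' (weighted by structure-tensor coherence by default), computes the circular
#' mean, the axial concentration `kappa`, the orientation dispersion index,
#' the mean RGB value and the valid-pixel count. Partial edge tiles are kept
#' with their reduced `n_pixels`.
#'
#' @param orient An `orientation_image`.
#' @param rgb_image Optional matching grey matrix or RGB array for the mean
#'   colour columns.
#' @param window Superpixel edge length in pixels.
#' @param bin Histogram bin width in degrees.
#' @param weight_by_coherence Weight histogram entries by coherence.
#' @param kappa_max Concentration cap.
#' @return A `superpixel_table` data frame (one row per tile) with columns
#'   `row`, `col`, `centre_x`, `centre_y`, `n_pixels`, `circ_mean`, `kappa`,
#'   `odi`, `mean_r`, `mean_g`, `mean_b`, `valid`, and the FOD histograms as a
#'   tiles x nbins matrix in attribute `fod`.
#' @export
aggregate_superpixels <- function(orient, rgb_image = NULL, window = 150L,
                                  bin = 2, weight_by_coherence = TRUE,
                                  kappa_max = 1e4) {
  stopifnot(inherits(orient, "orientation_image"))
  H <- nrow(orient$angle); W <- ncol(orient$angle)
  nbins <- round(180 / bin)
  row_starts <- seq(1, H, by = window)
  col_starts <- seq(1, W, by = window)
  rows <- list(); fods <- list()
  if (!is.null(rgb_image) && length(dim(rgb_image)) == 2) {
    rgb_image <- array(rep(rgb_image, 3), dim = c(dim(rgb_image), 3))
  }
  for (r0 in row_starts) for (c0 in col_starts) {
    r1 <- min(r0 + window - 1, H); c1 <- min(c0 + window - 1, W)
    ang <- orient$angle[r0:r1, c0:c1]
    coh <- orient$coherence[r0:r1, c0:c1]
    energy <- orient$energy[r0:r1, c0:c1]
    ok <- orient$valid[r0:r1, c0:c1] & !is.na(ang)
    n_ok <- sum(ok)
    w <- if (weight_by_coherence) coh[ok] else rep(1, n_ok)
    if (n_ok > 0 && sum(w) > 0) {
      fod <- axial_histogram(ang[ok], w, bin = bin)
      cm <- circ_mean_axial(ang[ok], w)
      kap <- if (weight_by_coherence) {
        # the tensor's energy-times-coherence phasor is the (unnormalised)
        # vector sum of the orientation content blended under the averaging
        # window, so the superpixel resultant is that vector sum over the
        # summed tensor energy; this keeps the concentration estimate
        # invariant to sub-window orientation blending
        en <- energy[ok]
        rbar <- Mod(sum(en * w * exp(2i * ang[ok] * pi / 180))) / sum(en)
        kappa_from_resultant(min(rbar, 1), kappa_max)
      } else {
        fit_axial_concentration(ang[ok], w, kappa_max = kappa_max)
      }
      odi <- odi_from_kappa(kap)
      valid <- TRUE
    } else {
      fod <- rep(NA_real_, nbins); cm <- NA_real_; kap <- NA_real_
      odi <- NA_real_; valid <- FALSE
    }
    mrgb <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(rgb_image)) {
      mrgb <- vapply(1:3, function(ch) mean(rgb_image[r0:r1, c0:c1, ch]), numeric(1))
    }
    rows[[length(rows) + 1]] <- data.frame(
      row = r0, col = c0,
      centre_y = (r0 + r1) / 2, centre_x = (c0 + c1) / 2,
      n_pixels = n_ok, circ_mean = cm, kappa = kap, odi = odi,
      mean_r = mrgb[1], mean_g = mrgb[2], mean_b = mrgb[3], valid = valid)
    fods[[length(fods) + 1]] <- fod
  }
  out <- do.call(rbind, rows)
  attr(out, "fod") <- do.call(rbind, fods)
  attr(out, "bin") <- bin
  class(out) <- c("superpixel_table", class(out))
  out
}

# Normalised axial histogram over [0, 180) with the given bin width (deg).
axial_histogram <- function(angles, weights, bin = 2) {
  nbins <- round(180 / bin)
  idx <- floor(wrap_axial(angles) / bin) + 1
  idx[idx > nbins] <- nbins
  h <- vapply(seq_len(nbins), function(b) sum(weights[idx == b]), numeric(1))
  h / sum(h)
}

#' Render an orientation image in HSV
#'
#' Hue encodes orientation (angle/180), saturation coherence, and value
#' `1 - grey` of the underlying stain image so dark (myelin-rich) pixels are
#' bright in the rendering.
#'
#' @param orient An `orientation_image`.
#' @param grey Matching grey-level image in [0, 1].
#' @return An `H x W x 3` RGB array.
#' @export
render_orientation_hsv <- function(orient, grey) {
  h <- orient$angle / 180
  h[!orient$valid] <- 0
  s <- orient$coherence
  v <- pmin(pmax(1 - grey, 0), 1)
  v[!orient$valid] <- 0
  cols <- grDevices::hsv(pmin(pmax(as.vector(h), 0), 1 - 1e-12),
                         pmin(pmax(as.vector(s), 0), 1), as.vector(v))
  array(t(grDevices::col2rgb(cols)) / 255, dim = c(dim(grey), 3))
}
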