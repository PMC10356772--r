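# Fusion of microscopy and diffusion MRI: plane geometry, 2D/3D fibre
# orientation distributions, hybrid per-pixel 3D orientations, and the
# ODI/FA comparison regression.

#' Define a microscopy section plane in scanner space
#'
#' @param origin World coordinates (mm) of the centre of pixel (row 1,
#'   col 1).
#' @param e1,e2 Orthonormal in-plane basis vectors; columns advance along
#'   `e1`, rows along `e2`. The normal is `e1 x e2` (right-handed).
#' @param pixel_size Pixel size in um.
#' @param dims Image dimensions `c(rows, cols)`.
#' @param voxel_size Voxel size (mm) of the co-registered MRI grid, used by
#'   the pixel-to-voxel affine.
#' @param section_thickness Section thickness in um.
#' @return A `plane_frame` object.
#' @export
plane_frame <- function(origin, e1, e2, pixel_size, dims,
                        voxel_size = c(1, 1, 1), section_thickness = 50) {
  e1 <- unit(e1); e2 <- unit(e2)
  if (abs(sum(e1 * e2)) > 1e-8) stop("e1 and e2 must be orthonormal")
  if (pixel_size <= 0) stop("pixel size must be positive")
  structure(list(origin = origin, e1 = e1, e2 = e2, normal = cross3(e1, e2),
                 pixel_size = pixel_size, dims = as.integer(dims),
                 voxel_size = voxel_size, section_thickness = section_thickness),
            class = "plane_frame")
}

# World coordinates (mm) of pixel centres (col, row may be fractional).
pixel_to_world <- function(frame, col, row) {
  ps <- frame$pixel_size / 1000
  cbind(frame$origin[1] + (col - 1) * ps * frame$e1[1] + (row - 1) * ps * frame$e2[1],
        frame$origin[2] + (col - 1) * ps * frame$e1[2] + (row - 1) * ps * frame$e2[2],
        frame$origin[3] + (col - 1) * ps * frame$e1[3] + (row - 1) * ps * frame$e2[3])
}

# 3x3 affine mapping homogeneous pixel coordinates (col, row, 1) to
# continuous voxel coordinates (0-based voxel index = floor of the result).
pixel_to_voxel_affine <- function(frame, voxel_size = frame$voxel_size) {
  ps <- frame$pixel_size / 1000
  A <- cbind(frame$e1 * ps / voxel_size,
             frame$e2 * ps / voxel_size,
             (frame$origin - (frame$e1 + frame$e2) * ps) / voxel_size)
  rownames(A) <- c("i", "j", "k"); colnames(A) <- c("col", "row", "1")
  A
}

#' Project 3D axes onto a section plane
#'
#' Decomposes unit axes into the plane spanned by `e1`, `e2`: the in-plane
#' angle is `atan2(axis.e2, axis.e1) mod 180` and the in-plane magnitude
#' `sqrt((axis.e1)^2 + (axis.e2)^2)`. Axes along the plane normal have no
#' defined in-plane angle and are flagged invalid.
#'
#' @param axis Unit 3-vector or matrix of row axes.
#' @param frame A `plane_frame`.
#' @param eps Magnitude below which the angle is invalid.
#' @return List of `angle` (degrees in [0,180)), `magnitude`, `valid`.
#' @export
project_to_plane <- function(axis, frame, eps = 1e-8) {
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 1)
  x1 <- as.vector(axis %*% frame$e1)
  x2 <- as.vector(axis %*% frame$e2)
  mag <- sqrt(x1^2 + x2^2)
  ang <- wrap_axial(rad2deg(atan2(x2, x1)))
  valid <- mag >= eps
  ang[!valid] <- NA_real_
  list(angle = ang, magnitude = mag, valid = valid)
}

#' Build a 2D fibre orientation distribution
#'
#' Weighted axial histogram over [0, 180) at the given bin width, normalised
#' to unit mass. Used for microscopy orientations pooled within an MR voxel
#' and for projected model FODs alike.
#'
#' @param angles Axial angles in degrees.
#' @param weights Optional non-negative weights.
#' @param bin Bin width in degrees (default 2).
#' @return A `fod2d` object: normalised `weights` with bin `centres`
#'   (degrees) as an attribute.
#' @export
build_fod2d <- function(angles, weights = NULL, bin = 2) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0) {
    out <- structure(list(weights = rep(NA_real_, round(180 / bin)), valid = FALSE),
                     class = "fod2d")
    attr(out, "centres") <- seq(bin / 2, 180 - bin / 2, by = bin)
    return(out)
  }
  if (is.null(weights)) weights <- rep(1, length(angles))
  h <- axial_histogram(angles, weights, bin = bin)
  out <- structure(list(weights = h, valid = TRUE), class = "fod2d")
  attr(out, "centres") <- seq(bin / 2, 180 - bin / 2, by = bin)
  out
}

#' Orientation dispersion index of a 2D FOD
#'
#' Fits the axial concentration to the bin-centre angles weighted by bin
#' mass and converts it: `ODI = 2/pi atan(1/kappa)`.
#'
#' @param fod A `fod2d`.
#' @param kappa_max Concentration cap.
#' @return ODI in [0, 1].
#' @export
odi_of_fod2d <- function(fod, kappa_max = 1e4) {
  stopifnot(inherits(fod, "fod2d"))
  if (!fod$valid) stop("invalid FOD")
  odi_from_kappa(fit_axial_concentration(attr(fod, "centres"), fod$weights,
                                         kappa_max = kappa_max))
}

#' Ordinary least squares with an F-test against the constant model
#'
#' Simple linear regression of `y` on `x` with the Pearson correlation, the
#' F-statistic `F = (n-2) R^2 / (1 - R^2)` against the degenerate
#' intercept-only model, its p-value from `F(1, n-2)`, and 95% confidence
#' bands evaluated over the range of `x`.
#'
#' @param x,y Paired finite numeric vectors (n >= 3).
#' @return A `linreg_ftest` list: `slope`, `intercept`, `r`, `r_squared`,
#'   `f_stat`, `p_value`, `n`, and a `bands` data frame (`x`, `fit`, `lwr`,
#'   `upr`).
#' @export
linreg_ftest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired finite values")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here (noiseless phantoms); silence the
  # perfect-fit note from summary.lm
  r2 <- suppressWarnings(summary(fit)$r.squared)
  fstat <- (n - 2) * r2 / (1 - r2)
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  grid <- data.frame(x = seq(min(x), max(x), length.out = 50))
  cb <- stats::predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(sign(stats::coef(fit)[2]) * sqrt(r2)),
                 r_squared = r2, f_stat = fstat, p_value = p, n = n,
                 bands = data.frame(x = grid$x, fit = cb[, "fit"],
                                    lwr = cb[, "lwr"], upr = cb[, "upr"])),
            class = "linreg_ftest")
}

#' @export
print.linreg_ftest <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g + %.4g x  (n = %d)\n", x$intercept, x$slope, x$n))
  cat(sprintf("  r = %.4f, F(1, %d) = %.4g, p = %.3g\n",
              x$r, x$n - 2, x$f_stat, x$p_value))
  invisible(x)
}

#' Hybrid microscopy-MRI 3D fibre orientations
#'
#' For each valid microscopy pixel, gathers the ball-and-stick orientation
#' samples of the underlying MRI voxel (populations with signal fraction
#' below `f_threshold` excluded), projects them onto the section plane, and
#' selects the sample whose in-plane angle is axially closest to the
#' microscopy in-plane angle. The through-plane (inclination) angle of that
#' sample is combined with the microscopy in-plane angle into a 3D hybrid
#' axis `v = cos(a) cos(phi) e1 + cos(a) sin(phi) e2 + sin(a) n`, keeping the
#' higher-confidence in-plane information from microscopy. Ties are broken by
#' higher population fraction, then lower sample index.
#'
#' @param pli_maps A `pli_maps` with valid in-plane angles.
#' @param bas_fit A `bas_fit` (with bootstrap samples) on the co-registered
#'   MRI grid.
#' @param frame The `plane_frame` mapping pixels to voxels.
#' @param f_threshold Exclusion threshold on population signal fraction.
#' @return A `hybrid_orientation_map`: `axes` (H, W, 3), `population`,
#'   `ang_diff` (degrees), `valid`.
#' @export
match_hybrid_orientations <- function(pli_maps, bas_fit, frame, f_threshold = 0.05) {
  stopifnot(inherits(pli_maps, "pli_maps"), inherits(bas_fit, "bas_fit"),
            inherits(frame, "plane_frame"))
  if (is.null(bas_fit$samples)) stop("bas_fit has no orientation samples")
  H <- nrow(pli_maps$angle); W <- ncol(pli_maps$angle)
  dims_b <- dim(bas_fit$f)[1:3]
  axes <- array(NA_real_, c(H, W, 3))
  popm <- array(NA_integer_, c(H, W))
  adiff <- array(NA_real_, c(H, W))
  valid <- array(FALSE, c(H, W))
  n_samples <- dim(bas_fit$samples)[5]

  px <- expand.grid(row = seq_len(H), col = seq_len(W))
  world <- pixel_to_world(frame, px$col, px$row)
  vx <- floor(sweep(world, 2, frame$voxel_size, "/")) + 1
  vox_ok <- vx[, 1] >= 1 & vx[, 1] <= dims_b[1] &
            vx[, 2] >= 1 & vx[, 2] <= dims_b[2] &
            vx[, 3] >= 1 & vx[, 3] <= dims_b[3]

  # cache per-voxel candidate tables (projected samples)
  cache <- new.env(parent = emptyenv())
  voxel_cands <- function(i, j, k) {
    key <- paste(i, j, k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pops <- which(!is.na(bas_fit$f[i, j, k, ]) & bas_fit$f[i, j, k, ] >= f_threshold)
    if (length(pops) == 0) {
      cache[[key]] <- NULL
      return(NULL)
    }
    rows <- list()
    for (p in pops) {
      Sm <- bas_fit$samples[i, j, k, p, , , drop = TRUE]
      Sm <- matrix(Sm, n_samples, 3)
      keep <- stats::complete.cases(Sm)
      if (!any(keep)) next
      Sk <- Sm[keep, , drop = FALSE]
      pr <- project_to_plane(Sk, frame)
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, f = bas_fit$f[i, j, k, p], sample = which(keep),
        angle = pr$angle, mag = pr$magnitude,
        x1 = as.vector(Sk %*% frame$e1),
        x2 = as.vector(Sk %*% frame$e2),
        xn = as.vector(Sk %*% frame$normal))
    }
    if (length(rows) == 0) {
      cache[[key]] <- NULL
      return(NULL)
    }
    tab <- do.call(rbind, rows)
    # tie-break order: higher fraction first, then lower sample index
    tab <- tab[order(-tab$f, tab$sample), ]
    cache[[key]] <- tab
    tab
  }

  for (r in seq_len(nrow(px))) {
    ro <- px$row[r]; co <- px$col[r]
    if (!vox_ok[r] || !isTRUE(pli_maps$valid[ro, co])) next
    phi <- pli_maps$angle[ro, co]
    if (is.na(phi)) next
    tab <- voxel_cands(vx[r, 1], vx[r, 2], vx[r, 3])
    if (is.null(tab)) next
    dd <- axial_diff(tab$angle, phi)
    dd[is.na(dd)] <- Inf
    m <- which.min(dd)
    # orient the matched sample so its in-plane part points along the
    # microscopy angle, then take its signed through-plane component
    cphi <- deg2rad(phi)
    sgn <- if (tab$x1[m] * cos(cphi) + tab$x2[m] * sin(cphi) < 0) -1 else 1
    alpha <- asin(pmin(1, pmax(-1, sgn * tab$xn[m])))
    v <- cos(alpha) * cos(cphi) * frame$e1 +
         cos(alpha) * sin(cphi) * frame$e2 +
         sin(alpha) * frame$normal
    if (v[3] < 0) v <- -v
    axes[ro, co, ] <- unit(v)
    popm[ro, co] <- tab$pop[m]
    adiff[ro, co] <- dd[m]
    valid[ro, co] <- TRUE
  }
  structure(list(axes = axes, population = popm, ang_diff = adiff, valid = valid,
                 frame = frame),
            class = "hybrid_orientation_map")
}

#' @export
print.hybrid_orientation_map <- function(x, ...) {
  cat("Hybrid orientation map:", nrow(x$valid), "x", ncol(x$valid), "pixels;",
      sum(x$valid), "valid; median matching difference",
      round(stats::median(x$ang_diff[x$valid]), 2), "deg\n")
  invisible(x)
}

#' Populate per-voxel 3D orientation histograms
#'
#' Assigns each valid hybrid axis to its axially nearest point of the shared
#' antipodal sphere grid, splitting the weight equally between the two paired
#' (antipodal) points so the histogram is exactly symmetric under
#' `v -> -v`, and normalises per voxel. The output voxel grid may be finer or
#' coarser than the MRI grid (`voxel_size` of the grid spec).
#'
#' @param hybrid A `hybrid_orientation_map`.
#' @param voxel_size Edge lengths (mm) of the output FOD grid.
#' @param n_points Sphere points (even).
#' @return A `fod3d`: `points` (n_points x 3), `weights` (voxels x
#'   n_points), `voxels` (integer voxel coordinates per row), `empty` flag.
#' @export
build_fod3d <- function(hybrid, voxel_size = c(1, 1, 1), n_points = 256L) {
  stopifnot(inherits(hybrid, "hybrid_orientation_map"))
  pts <- fod_sphere_grid(n_points)
  half <- n_points / 2
  Ph <- t(pts[seq_len(half), ])
  H <- nrow(hybrid$valid); W <- ncol(hybrid$valid)
  px <- which(hybrid$valid, arr.ind = TRUE)
  if (nrow(px) == 0) stop("no valid hybrid pixels")
  A <- t(vapply(seq_len(nrow(px)), function(r) hybrid$axes[px[r, 1], px[r, 2], ],
                numeric(3)))
  world <- pixel_to_world(hybrid$frame, px[, 2], px[, 1])
  vx <- floor(sweep(world, 2, voxel_size, "/")) + 1
  key <- paste(vx[, 1], vx[, 2], vx[, 3])
  ukey <- unique(key)
  # axially nearest half-grid point
  nearest <- max.col(abs(A %*% Ph))
  weights <- matrix(0, length(ukey), n_points)
  for (u in seq_along(ukey)) {
    sel <- key == ukey[u]
    tab <- tabulate(nearest[sel], nbins = half)
    w <- c(tab, tab) / (2 * sum(tab))
    weights[u, ] <- w
  }
  vox <- do.call(rbind, lapply(strsplit(ukey, " "), as.integer))
  structure(list(points = pts, weights = weights,
                 voxels = vox, voxel_size = voxel_size),
            class = "fod3d")
}

#' @export
print.fod3d <- function(x, ...) {
  cat("3D FODs:", nrow(x$weights), "voxels on a", nrow(x$points),
      "point sphere grid\n")
  invisible(x)
}
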