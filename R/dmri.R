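# Diffusion-weighted volumes: container, drift correction, normalisation and
# the diffusion tensor fit.

#' Construct a diffusion-weighted volume
#'
#' @param data 4D array (x, y, z, volume); 4th dimension matches the scheme.
#' @param scheme A `gradient_scheme`.
#' @param mask Logical 3D array (default: all voxels).
#' @param s0_times Acquisition times of the b~0 volumes (arbitrary units;
#'   default: their volume indices).
#' @param b0_thresh b-values below this count as b~0.
#' @return A `dwi_volume` object.
#' @export
dwi_volume <- function(data, scheme, mask = NULL, s0_times = NULL, b0_thresh = 0.1) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(dim(data)) != 4 || dim(data)[4] != length(scheme$bvals))
    stop("4th dimension must match the scheme length")
  if (any(data < 0, na.rm = TRUE)) stop("negative signals")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data)[1:3])
  b0 <- which(scheme$bvals < b0_thresh)
  if (is.null(s0_times)) s0_times <- as.numeric(b0)
  structure(list(data = data, scheme = scheme, mask = mask,
                 b0_indices = b0, s0_times = s0_times),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("DWI volume:", paste(d[1:3], collapse = " x "), "voxels,", d[4], "volumes",
      sprintf("(%d b~0)\n", length(x$b0_indices)))
  invisible(x)
}

# Mean b~0 intensity (over mask) per b~0 volume.
b0_means <- function(dwi) {
  vapply(dwi$b0_indices, function(v) mean(dwi$data[, , , v][dwi$mask]), numeric(1))
}

#' Correct multiplicative signal drift
#'
#' Scanner signal magnitude decays slowly over long acquisitions. A straight
#' line `S0(t) = c0 + c1 t` is fitted to the mean b~0 intensities against
#' their acquisition times and regressed out multiplicatively: the volume at
#' time `t` is divided by `(1 + c1 t / c0)`, so corrected b~0 means are
#' time-constant and equal the intercept.
#'
#' @param dwi A `dwi_volume` with at least two b~0 volumes.
#' @param times Acquisition time per volume (default: volume index).
#' @return The corrected `dwi_volume`, with attribute `drift` = c(c0, c1).
#' @export
correct_drift <- function(dwi, times = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (length(dwi$b0_indices) < 2) stop("need >= 2 b~0 volumes")
  if (is.null(times)) times <- seq_len(dim(dwi$data)[4])
  m <- b0_means(dwi)
  t0 <- dwi$s0_times
  cf <- stats::lm.fit(cbind(1, t0), m)$coefficients
  c0 <- cf[1]; c1 <- cf[2]
  if (c0 <= 0) stop("non-positive drift intercept")
  scale <- 1 + c1 * times / c0
  for (v in seq_along(times)) dwi$data[, , , v] <- dwi$data[, , , v] / scale[v]
  attr(dwi, "drift") <- c(c0 = unname(c0), c1 = unname(c1))
  dwi
}

#' Normalise a DWI volume to a reference b~0 image
#'
#' Voxelwise division by the mean b~0 volume (or a supplied reference, e.g.
#' the mean b~0 of a designated shell when combining sessions), so reference
#' voxels map to 1. Voxels with a non-positive reference are removed from the
#' mask and counted in attribute `n_masked`.
#'
#' @param dwi A `dwi_volume`.
#' @param reference Optional 3D reference array.
#' @return The normalised `dwi_volume`.
#' @export
normalise_s0 <- function(dwi, reference = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (is.null(reference)) {
    reference <- apply(dwi$data[, , , dwi$b0_indices, drop = FALSE], 1:3, mean)
  }
  bad <- !(reference > 0)
  reference[bad] <- 1
  dwi$data <- sweep(dwi$data, 1:3, reference, "/")
  dwi$data[is.na(dwi$data)] <- 0
  dwi$mask <- dwi$mask & !bad
  attr(dwi, "n_masked") <- sum(bad)
  dwi
}

#' Fit the diffusion tensor model
#'
#' Log-linear least squares for the six tensor elements plus `log S0`;
#' fractional anisotropy, mean diffusivity and the primary eigenvector follow
#' from the eigendecomposition. Non-positive signals are excluded from the
#' log fit voxelwise.
#'
#' @param dwi A `dwi_volume` with at least 6 unique directions plus b~0.
#' @return A `tensor_maps` object: `fa`, `md` (um^2/ms), `v1`
#'   (x, y, z, 3 array), `tensor` (x, y, z, 6: xx, yy, zz, xy, xz, yz), `s0`.
#' @export
fit_dti <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  sch <- dwi$scheme
  lin <- sch$encoding == "linear"
  b <- sch$bvals[lin]; G <- sch$directions[lin, , drop = FALSE]
  X <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3])
  dims <- dim(dwi$data)[1:3]
  fa <- array(NA_real_, dims); md <- array(NA_real_, dims)
  s0 <- array(NA_real_, dims)
  v1 <- array(NA_real_, c(dims, 3)); tens <- array(NA_real_, c(dims, 6))
  idx <- which(dwi$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    S <- dwi$data[i, j, k, lin]
    ok <- S > 0
    if (sum(ok) < 7) next
    cf <- stats::lm.fit(X[ok, , drop = FALSE], log(S[ok]))$coefficients
    D <- matrix(c(cf[2], cf[5], cf[6],
                  cf[5], cf[3], cf[7],
                  cf[6], cf[7], cf[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    ev <- e$values
    mdv <- mean(ev)
    denom <- sum(ev^2)
    fa[i, j, k] <- if (denom > 0) sqrt(1.5 * sum((ev - mdv)^2) / denom) else 0
    md[i, j, k] <- mdv
    s0[i, j, k] <- exp(cf[1])
    v1[i, j, k, ] <- e$vectors[, 1]
    tens[i, j, k, ] <- c(cf[2], cf[3], cf[4], cf[5], cf[6], cf[7])
  }
  structure(list(fa = pmin(pmax(fa, 0), 1), md = md, v1 = v1,
                 tensor = tens, s0 = s0),
            class = "tensor_maps")
}

#' @export
print.tensor_maps <- function(x, ...) {
  ok <- !is.na(x$fa)
  cat("Tensor maps:", sum(ok), "fitted voxels; median FA",
      round(stats::median(x$fa[ok]), 3), "median MD",
      signif(stats::median(x$md[ok]), 3), "um^2/ms\n")
  invisible(x)
}
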