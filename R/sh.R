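# Real even-order spherical harmonics: basis construction, least-squares
# projection of 3D orientation histograms, and NIfTI export in the real-SH
# convention used by common tractography software.

#' Real even-order spherical harmonic basis
#'
#' Evaluates the real, orthonormal, even-order SH basis at unit vectors.
#' Ordering follows the convention of common tractography software: for each
#' even degree `l = 0, 2, ..., lmax`, orders `m = -l..l`, with
#' `m < 0 -> sqrt(2) * Im(Y_l^|m|)`, `m = 0 -> Y_l^0`,
#' `m > 0 -> sqrt(2) * Re(Y_l^m)` (Condon-Shortley phase included in the
#' associated Legendre functions). Odd degrees are identically absent, as
#' appropriate for antipodally symmetric FODs. `lmax = 8` gives 45 basis
#' functions.
#'
#' @param dirs `n x 3` matrix of unit vectors.
#' @param lmax Maximum (even) degree.
#' @return An `n x n_coef` design matrix with attribute `lm` (data frame of
#'   the (l, m) per column).
#' @export
sh_basis <- function(dirs, lmax = 8L) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  if (lmax %% 2 != 0) stop("lmax must be even")
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ct <- cos(theta)
  n <- nrow(dirs)
  cols <- list(); lm <- list()
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)           # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      nrmc <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      base <- nrmc * P[am + 1, ]
      y <- if (m < 0) sqrt(2) * base * sin(am * phi)
           else if (m == 0) base
           else sqrt(2) * base * cos(am * phi)
      cols[[length(cols) + 1]] <- y
      lm[[length(lm) + 1]] <- data.frame(l = l, m = m)
    }
  }
  B <- do.call(cbind, cols)
  attr(B, "lm") <- do.call(rbind, lm)
  B
}

#' Fit spherical harmonics to 3D orientation histograms
#'
#' Least-squares projection of per-voxel FOD weights onto the real even-order
#' SH basis evaluated at the histogram's sphere points. The reconstruction at
#' the points minimises squared error; band-limited inputs are reproduced
#' exactly.
#'
#' @param fod3d A `fod3d` (see [build_fod3d()]), or a plain
#'   voxels-by-points weight matrix with a `points` attribute.
#' @param lmax Maximum even degree (default 8, 45 coefficients).
#' @return An `sh_coeffs` object: `coeffs` (voxels x n_coef), `lm` ordering
#'   table, `voxels`, `lmax`.
#' @export
fit_sh <- function(fod3d, lmax = 8L) {
  if (inherits(fod3d, "fod3d")) {
    W <- fod3d$weights; pts <- fod3d$points; vox <- fod3d$voxels
  } else {
    W <- fod3d; pts <- attr(fod3d, "points"); vox <- NULL
  }
  B <- sh_basis(pts, lmax)
  q <- qr(B)
  if (q$rank < ncol(B)) stop("rank-deficient SH design")
  cf <- t(qr.coef(q, t(W)))
  structure(list(coeffs = cf, lm = attr(B, "lm"), voxels = vox, lmax = lmax,
                 points = pts),
            class = "sh_coeffs")
}

#' @export
print.sh_coeffs <- function(x, ...) {
  cat("SH coefficients: lmax =", x$lmax, ",", ncol(x$coeffs),
      "coefficients x", nrow(x$coeffs), "voxels\n")
  invisible(x)
}

#' Evaluate SH coefficients on directions
#'
#' @param sh An `sh_coeffs` object.
#' @param dirs Unit direction matrix (default: the fitted points).
#' @return Voxels x directions matrix of reconstructed FOD values.
#' @export
sh_eval <- function(sh, dirs = NULL) {
  stopifnot(inherits(sh, "sh_coeffs"))
  if (is.null(dirs)) dirs <- sh$points
  B <- sh_basis(dirs, sh$lmax)
  sh$coeffs %*% t(B)
}

#' Export SH coefficient images as 4D NIfTI
#'
#' Writes one volume per coefficient (45 for `lmax = 8`) in the documented
#' `(l, m)` ordering, so the result can be visualised in standard MRI viewers
#' and passed to SH-based tractography. A JSON sidecar records the basis
#' convention and ordering.
#'
#' @param sh An `sh_coeffs` with voxel coordinates.
#' @param grid_dims Output grid dimensions (length 3).
#' @param voxel_size Voxel edge lengths in mm.
#' @param out_path Output `.nii` or `.nii.gz` path.
#' @return Invisibly, the NIfTI path and the sidecar path.
#' @export
export_sh_image <- function(sh, grid_dims, voxel_size, out_path) {
  stopifnot(inherits(sh, "sh_coeffs"))
  if (is.null(sh$voxels)) stop("sh_coeffs carries no voxel coordinates")
  nc <- ncol(sh$coeffs)
  img <- array(0, dim = c(grid_dims, nc))
  for (r in seq_len(nrow(sh$coeffs))) {
    v <- sh$voxels[r, ]
    if (any(v < 1) || any(v > grid_dims)) next
    img[v[1], v[2], v[3], ] <- sh$coeffs[r, ]
  }
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- c(voxel_size, 1)
  RNifti::writeNifti(nii, out_path)
  side <- sub("\\.nii(\\.gz)?$", ".json", out_path)
  jsonlite::write_json(list(
    basis = "real symmetric spherical harmonics, even degrees only",
    convention = "m<0: sqrt(2) Im(Y_l^|m|); m=0: Y_l^0; m>0: sqrt(2) Re(Y_l^m); Condon-Shortley phase included",
    lmax = sh$lmax,
    ordering = sh$lm), side, digits = NA, auto_unbox = TRUE)
  invisible(c(out_path, side))
}
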