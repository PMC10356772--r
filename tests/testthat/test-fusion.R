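# Plane projection, 2D/3D FODs, regression, hybrid matching and spherical
# harmonics.

xy_frame <- function(dims = c(20, 20), pixel_size = 50, voxel_size = c(1, 1, 1)) {
  plane_frame(origin = c(pixel_size / 2000, pixel_size / 2000, 0.5),
              e1 = c(1, 0, 0), e2 = c(0, 1, 0),
              pixel_size = pixel_size, dims = dims, voxel_size = voxel_size)
}

test_that("plane projection decomposes axes as stated", {
  fr <- xy_frame()
  p1 <- project_to_plane(c(1, 0, 0), fr)
  expect_equal(p1$angle, 0)
  expect_equal(p1$magnitude, 1)
  pn <- project_to_plane(c(0, 0, 1), fr)
  expect_false(pn$valid)
  expect_true(is.na(pn$angle))
  pd <- project_to_plane(c(1, 0, 1) / sqrt(2), fr)
  expect_equal(pd$angle, 0)
  expect_equal(pd$magnitude, sqrt(0.5), tolerance = 1e-12)
})

test_that("plane operations are equivariant under in-plane basis rotation", {
  fr <- xy_frame()
  th <- 25 * pi / 180
  fr_rot <- plane_frame(fr$origin,
                        e1 = c(cos(th), sin(th), 0), e2 = c(-sin(th), cos(th), 0),
                        pixel_size = fr$pixel_size, dims = fr$dims)
  ax <- t(sapply(seq(0, 150, by = 30), function(a) fibrefuse:::axis_from_angles(a, 20)))
  p0 <- project_to_plane(ax, fr)
  p1 <- project_to_plane(ax, fr_rot)
  expect_equal(p1$magnitude, p0$magnitude, tolerance = 1e-12)
  expect_lt(max(axial_diff(wrap_axial(p0$angle - 25 * 1), p1$angle)), 1e-9)
})

test_that("2D FODs: delta, wrap-around and uniform flatness", {
  fd <- build_fod2d(45.5)
  expect_equal(sum(fd$weights > 0), 1)
  expect_equal(sum(fd$weights), 1)
  expect_equal(which(fd$weights > 0), 23)  # 44-46 degree bin

  fw <- build_fod2d(181)  # wraps into the 0-2 degree bin
  expect_equal(which(fw$weights > 0), 1)

  set.seed(11)
  fu <- build_fod2d(runif(2e5, 0, 180))
  expect_lt(max(fu$weights) / min(fu$weights), 1.3)

  fe <- build_fod2d(numeric(0))
  expect_false(fe$valid)
  expect_error(odi_of_fod2d(fe), "invalid")
})

test_that("2D FOD dispersion matches the closed-form ODI and the raw-angle estimator", {
  f1 <- build_fod2d(rep(90, 10))
  expect_lt(odi_of_fod2d(f1), 0.02)
  flat <- structure(list(weights = rep(1 / 90, 90), valid = TRUE), class = "fod2d")
  attr(flat, "centres") <- seq(1, 179, by = 2)
  expect_gt(odi_of_fod2d(flat), 0.98)

  set.seed(12)
  a <- fibrefuse:::r_axial_vonmises(50000, 60, 3)
  fod <- build_fod2d(a)
  expect_equal(odi_of_fod2d(fod), 2 / pi * atan(1 / 3), tolerance = 0.03)
  # binned and raw-angle estimates agree
  expect_equal(odi_of_fod2d(fod),
               odi_from_kappa(fit_axial_concentration(a)), tolerance = 0.01)
})

test_that("OLS with F-test matches hand computation and behaves under the null", {
  r <- linreg_ftest(1:10, 2 * (1:10))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-12)

  # hand-computed 5-point dataset
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  n <- 5
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx; intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * sum((y - mean(y))^2))
  fstat <- (n - 2) * r2 / (1 - r2)
  fit <- linreg_ftest(x, y)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$f_stat, fstat, tolerance = 1e-10)
  expect_equal(fit$p_value, pf(fstat, 1, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(all(fit$bands$lwr <= fit$bands$fit & fit$bands$fit <= fit$bands$upr))

  # permutation null: p-values are uniform
  set.seed(13)
  x0 <- rnorm(40); y0 <- rnorm(40)
  pvals <- replicate(1000, linreg_ftest(x0, sample(y0))$p_value)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  expect_error(linreg_ftest(rep(1, 5), 1:5), "variance")
})

test_that("hybrid matching follows the axially closest projected sample", {
  # one MRI voxel, samples laid out by hand
  fr <- xy_frame(dims = c(2, 2), pixel_size = 400)
  mk_bas <- function(axes_list, fracs) {
    npop <- length(axes_list); ns <- nrow(axes_list[[1]])
    fA <- array(NA_real_, c(1, 1, 1, 3)); smp <- array(NA_real_, c(1, 1, 1, 3, ns, 3))
    axA <- array(NA_real_, c(1, 1, 1, 3, 3))
    for (p in seq_len(npop)) {
      fA[1, 1, 1, p] <- fracs[p]
      axA[1, 1, 1, p, ] <- axes_list[[p]][1, ]
      for (s in seq_len(ns)) smp[1, 1, 1, p, s, ] <- axes_list[[p]][s, ]
    }
    structure(list(f = fA, axes = axA, n_pop = array(npop, c(1, 1, 1)),
                   d = array(0.1, c(1, 1, 1)), s0 = array(1, c(1, 1, 1)),
                   samples = smp, f_threshold = 0.05), class = "bas_fit")
  }
  mk_maps <- function(phi) {
    m <- matrix(phi, 2, 2)
    structure(list(transmittance = matrix(1, 2, 2), retardance = matrix(0.5, 2, 2),
                   angle = m, inclination = NULL, valid = matrix(TRUE, 2, 2)),
              class = "pli_maps")
  }

  # exact agreement: a single in-plane stick along the PLI angle
  ax30 <- matrix(rep(fibrefuse:::axis_from_angles(30, 0), 2), 2, 3, byrow = TRUE)
  hy <- match_hybrid_orientations(mk_maps(30), mk_bas(list(ax30), 0.8), fr)
  expect_true(all(hy$valid))
  expect_equal(hy$ang_diff[1, 1], 0, tolerance = 1e-9)
  expect_lt(axial_angle(hy$axes[1, 1, ], ax30[1, ]), 1e-6)

  # worked example: projections at 85 and 28 degrees, PLI at 30 -> the 28-degree
  # stick contributes its through-plane angle
  axA <- matrix(rep(fibrefuse:::axis_from_angles(85, 0), 2), 2, 3, byrow = TRUE)
  axB <- matrix(rep(fibrefuse:::axis_from_angles(28, 40), 2), 2, 3, byrow = TRUE)
  hy2 <- match_hybrid_orientations(mk_maps(30), mk_bas(list(axA, axB), c(0.5, 0.3)), fr)
  expect_equal(hy2$population[1, 1], 2L)
  expect_equal(hy2$ang_diff[1, 1], 2, tolerance = 1e-9)
  # hybrid keeps PLI in-plane angle (30) and the matched inclination (40)
  expected <- fibrefuse:::axis_from_angles(30, 40)
  expect_lt(axial_angle(hy2$axes[1, 1, ], expected), 1e-6)

  # fraction threshold: population at 0.04 is ignored
  hy3 <- match_hybrid_orientations(mk_maps(80), mk_bas(list(axA, axB), c(0.9, 0.04)), fr)
  expect_equal(hy3$population[1, 1], 1L)
  # all populations below threshold -> invalid
  hy4 <- match_hybrid_orientations(mk_maps(80), mk_bas(list(axA, axB), c(0.04, 0.03)), fr)
  expect_false(any(hy4$valid))
})

test_that("3D orientation histograms are axially symmetric and well spread", {
  fr <- xy_frame(dims = c(10, 10), pixel_size = 100)
  mk_hybrid <- function(axes) {
    H <- 10; W <- 10
    A <- array(NA_real_, c(H, W, 3)); val <- matrix(TRUE, H, W)
    k <- 1
    for (i in 1:H) for (j in 1:W) {
      A[i, j, ] <- axes[(k - 1) %% nrow(axes) + 1, ]; k <- k + 1
    }
    structure(list(axes = A, population = matrix(1L, H, W),
                   ang_diff = matrix(0, H, W), valid = val, frame = fr),
              class = "hybrid_orientation_map")
  }
  one <- matrix(c(0, 0, 1), 1, 3)
  fod <- build_fod3d(mk_hybrid(one))
  expect_equal(sum(fod$weights[1, ] > 0), 2)  # the antipodal pair
  expect_equal(sum(fod$weights[1, ]), 1)

  # negated axes give the identical FOD
  fodn <- build_fod3d(mk_hybrid(-one))
  expect_equal(fod$weights, fodn$weights)

  set.seed(14)
  V <- matrix(rnorm(3 * 10000), ncol = 3); V <- V / sqrt(rowSums(V^2))
  fr1 <- xy_frame(dims = c(100, 100), pixel_size = 10)
  A <- array(NA_real_, c(100, 100, 3))
  for (i in 1:100) for (j in 1:100) A[i, j, ] <- V[(i - 1) * 100 + j, ]
  hyu <- structure(list(axes = A, population = matrix(1L, 100, 100),
                        ang_diff = matrix(0, 100, 100),
                        valid = matrix(TRUE, 100, 100), frame = fr1),
                   class = "hybrid_orientation_map")
  fodu <- build_fod3d(hyu)
  expect_lt(max(fodu$weights), 3 * mean(fodu$weights))
})

test_that("spherical harmonics: orthonormality, projection identity and quadrature oracle", {
  pts <- fod_sphere_grid(256)
  B <- sh_basis(pts, 8)
  expect_equal(ncol(B), 45)
  expect_true(all(attr(B, "lm")$l %% 2 == 0))

  # uniform weights excite only l = 0
  w_uni <- matrix(1 / 256, 1, 256)
  sh_u <- fit_sh(structure(list(weights = w_uni, points = pts,
                                voxels = matrix(1, 1, 3)), class = "fod3d"))
  expect_equal(sh_u$coeffs[1, 1], (1 / 256) * sqrt(4 * pi), tolerance = 1e-10)
  expect_lt(max(abs(sh_u$coeffs[1, -1])), 1e-10)

  # band-limited round trip is exact
  set.seed(15)
  cf <- rnorm(45)
  w <- matrix(as.vector(B %*% cf), 1)
  sh <- fit_sh(structure(list(weights = w, points = pts,
                              voxels = matrix(1, 1, 3)), class = "fod3d"))
  expect_lt(max(abs(sh$coeffs[1, ] - cf)), 1e-8)
  expect_lt(max(abs(sh_eval(sh) - w)), 1e-8)

  # dense Monte-Carlo quadrature oracle recovers the same coefficients
  set.seed(16)
  Vd <- matrix(rnorm(3 * 3e5), ncol = 3); Vd <- Vd / sqrt(rowSums(Vd^2))
  Bd <- sh_basis(Vd, 8)
  f_dense <- as.vector(Bd %*% cf)
  cf_quad <- crossprod(Bd, f_dense) / nrow(Bd) * 4 * pi
  expect_lt(max(abs(cf_quad - cf)), 0.05)
})

test_that("SH export writes a readable 45-volume NIfTI with correct metadata", {
  pts <- fod_sphere_grid(256)
  w <- matrix(1 / 256, 2, 256, byrow = TRUE)
  sh <- fit_sh(structure(list(weights = w, points = pts,
                              voxels = rbind(c(1, 1, 1), c(2, 2, 1))),
                         class = "fod3d"))
  path <- file.path(tempdir(), "sh_test.nii.gz")
  export_sh_image(sh, grid_dims = c(2, 2, 1), voxel_size = c(1, 1, 0.35),
                  out_path = path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), c(2, 2, 1, 45))
  expect_equal(RNifti::pixdim(img)[1:3], c(1, 1, 0.35), tolerance = 1e-6)
  # isotropic field: first volume constant over covered voxels, rest ~ 0
  expect_equal(img[1, 1, 1, 1], img[2, 2, 1, 1], tolerance = 1e-6)
  expect_lt(max(abs(img[, , , 2:45])), 1e-6)
  side <- jsonlite::read_json(file.path(tempdir(), "sh_test.json"))
  expect_equal(side$lmax, 8)
})
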