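# Preprocessing, DTI, DIVIDE, T1 and the orientation-precision statistic.

make_b0_dwi <- function(means, n_extra = 2) {
  # volumes: the b~0 series plus a few diffusion-weighted ones
  nb0 <- length(means)
  dirs <- generate_directions(n_extra, seed = 1)
  sch <- gradient_scheme(rbind(matrix(0, nb0, 3), dirs),
                         c(rep(0, nb0), rep(4, n_extra)))
  data <- array(NA_real_, c(2, 2, 1, nb0 + n_extra))
  for (v in seq_len(nb0)) data[, , , v] <- means[v]
  for (v in seq_len(n_extra)) data[, , , nb0 + v] <- means[1] * 0.5
  dwi_volume(data, sch, s0_times = seq_len(nb0) - 1)
}

test_that("drift correction: identity, hand-computed line, and round trip", {
  d0 <- make_b0_dwi(c(100, 100, 100))
  out0 <- correct_drift(d0, times = c(0, 1, 2, 3, 4))
  expect_equal(out0$data, d0$data, tolerance = 1e-12)

  d1 <- make_b0_dwi(c(100, 98, 96))
  out1 <- correct_drift(d1, times = c(0, 1, 2, 3, 4))
  expect_equal(unname(attr(out1, "drift")["c1"]), -2, tolerance = 1e-9)
  expect_equal(fibrefuse:::b0_means(out1), c(100, 100, 100), tolerance = 1e-9)

  # apply a 5% linear drift to clean data, then correct it away
  set.seed(6)
  clean <- make_b0_dwi(c(80, 80, 80, 80))
  times <- seq_len(dim(clean$data)[4]) - 1
  drifted <- clean
  for (v in seq_along(times))
    drifted$data[, , , v] <- clean$data[, , , v] * (1 - 0.05 * times[v] / max(times))
  drifted$s0_times <- times[drifted$b0_indices]
  rec <- correct_drift(drifted, times = times)
  expect_lt(max(abs(rec$data - clean$data) / clean$data), 1e-6)
  expect_error(correct_drift(make_b0_dwi(100)), ">= 2")
})

test_that("S0 normalisation maps the reference to one and masks zeros", {
  d <- make_b0_dwi(c(50, 50))
  out <- normalise_s0(d)
  expect_equal(out$data[, , , 1], matrix(1, 2, 2), tolerance = 1e-12)
  expect_equal(out$data[, , , 3], matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(attr(out, "n_masked"), 0)

  d2 <- d
  ref <- apply(d2$data[, , , d2$b0_indices, drop = FALSE], 1:3, mean)
  ref[1, 1, 1] <- 0
  out2 <- normalise_s0(d2, reference = ref)
  expect_equal(attr(out2, "n_masked"), 1)
  expect_false(out2$mask[1, 1, 1])
})

test_that("DTI: isotropic, prolate, and exact round trip of a random SPD tensor", {
  sch <- shell_scheme(30, 1, seed = 2)
  b <- sch$bvals; G <- sch$directions
  iso <- exp(-b * 0.5) * 3
  dwi <- dwi_volume(array(iso, c(1, 1, 1, 31)), sch)
  tm <- fit_dti(dwi)
  expect_equal(tm$fa[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(tm$md[1, 1, 1], 0.5, tolerance = 1e-9)

  D1 <- diag(c(1, 0, 0))  # rank-1 tensor: FA = 1
  S1 <- exp(-b * rowSums((G %*% D1) * G))
  tm1 <- fit_dti(dwi_volume(array(S1, c(1, 1, 1, 31)), sch))
  expect_equal(tm1$fa[1, 1, 1], 1, tolerance = 1e-6)
  expect_equal(abs(tm1$v1[1, 1, 1, 1]), 1, tolerance = 1e-6)

  set.seed(7)
  A <- matrix(rnorm(9), 3, 3); D <- crossprod(A) / 3
  S <- 2.2 * exp(-b * rowSums((G %*% D) * G))
  tm2 <- fit_dti(dwi_volume(array(S, c(1, 1, 1, 31)), sch))
  Dhat <- tm2$tensor[1, 1, 1, ]
  expect_equal(Dhat, c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]),
               tolerance = 1e-8)
  expect_equal(tm2$s0[1, 1, 1], 2.2, tolerance = 1e-8)
})

test_that("orientation precision: degenerate, isotropic and Watson-sampled axes", {
  same <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  expect_equal(orientation_precision(same), 0)
  set.seed(8)
  V <- matrix(rnorm(3 * 20000), ncol = 3); V <- V / sqrt(rowSums(V^2))
  expect_equal(orientation_precision(V), acos(sqrt(1 / 3)) * 180 / pi,
               tolerance = 1)
  expect_error(orientation_precision(same[1, , drop = FALSE]), ">= 2")

  # Monte-Carlo oracle at a known Watson concentration
  kap <- 10
  set.seed(9)
  oracle <- median(replicate(40, orientation_precision(
    fibrefuse:::r_watson(50, c(0, 0, 1), kap))))
  set.seed(10)
  got <- median(replicate(40, orientation_precision(
    fibrefuse:::r_watson(50, c(1, 1, 1) / sqrt(3), kap))))
  expect_equal(got, oracle, tolerance = 0.05 * oracle)
})

test_that("DIVIDE: gamma self-consistency and the isotropic system", {
  bsh <- c(0.2, 0.5, 1, 1.5, 2)
  # gamma-form powder signals at known (mu1, mu2) recovered exactly
  mu1 <- 0.9; m2l <- 0.18; m2s <- 0.05
  dirs <- generate_directions(10, seed = 3)
  bv_l <- c(0, rep(bsh, each = 10))
  gv_l <- rbind(c(0, 0, 1), dirs[rep(1:10, times = length(bsh)), ])
  Sl <- c(1, fibrefuse:::gamma_decay(rep(bsh, each = 10), mu1, m2l))
  dwl <- dwi_volume(array(Sl, c(1, 1, 1, length(Sl))),
                    gradient_scheme(gv_l, bv_l))
  bv_s <- c(0, bsh)
  Ss <- c(1, fibrefuse:::gamma_decay(bsh, mu1, m2s))
  dws <- dwi_volume(array(Ss, c(1, 1, 1, length(Ss))),
                    gradient_scheme(matrix(0, length(bv_s), 3), bv_s,
                                    encoding = "spherical"))
  dm <- fit_divide(dwl, dws)
  expect_equal(dm$mu1, mu1, tolerance = 1e-6)
  expect_equal(dm$mu2_linear, m2l, tolerance = 1e-5)
  expect_equal(dm$mu2_spherical, m2s, tolerance = 1e-5)
  expect_true(dm$ufa >= 0 && dm$ufa <= 1)

  # identical isotropic microtensors: no microscopic anisotropy
  S_iso_l <- c(1, exp(-rep(bsh, each = 10) * 0.7))
  S_iso_s <- c(1, exp(-bsh * 0.7))
  dm_iso <- fit_divide(
    dwi_volume(array(S_iso_l, c(1, 1, 1, length(S_iso_l))),
               gradient_scheme(gv_l, bv_l)),
    dwi_volume(array(S_iso_s, c(1, 1, 1, length(S_iso_s))),
               gradient_scheme(matrix(0, length(bv_s), 3), bv_s,
                               encoding = "spherical")))
  expect_lt(dm_iso$ufa, 0.02)
})

test_that("DIVIDE is invariant to direction relabelling", {
  bsh <- c(0.5, 1, 2)
  dirs <- generate_directions(12, seed = 4)
  bv <- c(0, rep(bsh, each = 12))
  gv <- rbind(c(0, 0, 1), dirs[rep(1:12, 3), ])
  D <- diag(c(1.5, 0.3, 0.3))
  S <- c(2, 2 * exp(-bv[-1] * rowSums((gv[-1, ] %*% D) * gv[-1, ])))
  sch1 <- gradient_scheme(gv, bv)
  perm <- c(1, 1 + sample(length(bv) - 1))
  sch2 <- gradient_scheme(gv[perm, ], bv[perm])
  sph <- dwi_volume(array(exp(-c(0, bsh) * 0.7), c(1, 1, 1, 4)),
                    gradient_scheme(matrix(0, 4, 3), c(0, bsh), encoding = "spherical"))
  d1 <- fit_divide(dwi_volume(array(S, c(1, 1, 1, length(S))), sch1), sph)
  d2 <- fit_divide(dwi_volume(array(S[perm], c(1, 1, 1, length(S))), sch2), sph)
  expect_equal(d1$ufa, d2$ufa, tolerance = 1e-9)
})

test_that("Barral T1 fit: closed forms and exact recovery", {
  tis <- exp(seq(log(10), log(6000), length.out = 12))
  y <- 1 - 2 * exp(-tis / 500)
  fit <- fit_t1(y, tis)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, -2, tolerance = 1e-6)
  expect_equal(fit$t1, 500, tolerance = 500 * 1e-6)
  # S(0) = a + b and the null crossing sits at T1 log 2
  expect_equal(fit$a + fit$b, -1, tolerance = 1e-6)
  ti_null <- -fit$t1 * log(-fit$a / fit$b)
  expect_equal(ti_null, 500 * log(2), tolerance = 1e-3)
  # TI -> infinity asymptote equals a
  expect_equal(fit$a + fit$b * exp(-1e9 / fit$t1), fit$a)

  # matrix interface, different parameters per voxel
  pars <- cbind(a = c(2, 1.5), b = c(-4, -2.8), t1 = c(300, 1200))
  Y <- t(apply(pars, 1, function(p) p[1] + p[2] * exp(-tis / p[3])))
  fits <- fit_t1(Y, tis)
  expect_equal(fits$t1, pars[, "t1"], tolerance = 1e-4)
  expect_true(all(fits$converged))
  expect_error(fit_t1(y[1:2], tis[1:2]), ">= 3")
})

test_that("fits are invariant to global signal rescaling", {
  sch <- shell_scheme(30, 4, seed = 5)
  f <- build_fibre_field("single", shape = c(1, 1, 1), phi = 40, f = 0.6, d = 0.1)
  dwi <- simulate_dwi(f, sch)
  dwi10 <- dwi; dwi10$data <- dwi$data * 10
  t1 <- fit_dti(dwi); t2 <- fit_dti(dwi10)
  expect_equal(t1$fa, t2$fa, tolerance = 1e-9)
  expect_equal(t1$md, t2$md, tolerance = 1e-9)
  b1 <- fit_ball_and_stick(dwi, n_samples = 0, seed = 1)
  b2 <- fit_ball_and_stick(dwi10, n_samples = 0, seed = 1)
  expect_equal(b1$f, b2$f, tolerance = 1e-6)
  expect_equal(b2$s0[1, 1, 1], 10 * b1$s0[1, 1, 1], tolerance = 1e-4)
})
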