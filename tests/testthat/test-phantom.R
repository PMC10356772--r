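# Phantom generators: fibre fields, forward dMRI, PLI and histology
# rendering, and the on-disk bundle.

test_that("fibre field recipes build the stated geometries", {
  f1 <- build_fibre_field("single", shape = c(4, 4, 2), phi = 0, f = 0.7)
  expect_equal(f1$f[1, 1, 1, ], c(0.7, 0, 0))
  expect_equal(f1$axes[2, 3, 1, 1, ], c(1, 0, 0))
  expect_equal(1 - sum(f1$f[1, 1, 1, ]), 0.3)

  f2 <- build_fibre_field("crossing", shape = c(3, 3, 1), phi = 10, angle = 90,
                          f = 0.35, f2 = 0.35)
  dots <- sum(f2$axes[1, 1, 1, 1, ] * f2$axes[1, 1, 1, 2, ])
  expect_equal(dots, 0, tolerance = 1e-12)

  # linear ramp: column k at 60*(k-1)/9 degrees
  ff <- build_fibre_field("fanning", shape = c(10, 4, 1), phi = 0, max_angle = 60)
  for (k in 1:10) {
    expected <- 60 * (k - 1) / 9
    got <- atan2(ff$axes[k, 1, 1, 1, 2], ff$axes[k, 1, 1, 1, 1]) * 180 / pi
    expect_equal(got, expected, tolerance = 1e-9)
  }

  expect_error(build_fibre_field("crossing", f = 0.6, f2 = 0.6), "more than 1")
  expect_error(build_fibre_field("vortex"), "arg")
})

test_that("noiseless forward dMRI matches the ball-and-stick closed forms", {
  f <- build_fibre_field("single", shape = c(2, 2, 1), phi = 0, f = 0.5, d = 0.1)
  sch <- gradient_scheme(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)), c(4, 4, 0))
  dwi <- simulate_dwi(f, sch)
  # g perpendicular to the stick: S/s0 = 0.5 exp(-0.4) + 0.5
  expect_equal(dwi$data[1, 1, 1, 1], 0.5 * exp(-0.4) + 0.5, tolerance = 1e-12)
  expect_equal(dwi$data[1, 1, 1, 3], 1, tolerance = 1e-12)  # b = 0 -> s0

  fs <- build_fibre_field("single", shape = c(1, 1, 1), phi = 0, f = 1, d = 0.1)
  schp <- gradient_scheme(matrix(c(1, 0, 0), 1, 3), 4)
  expect_equal(simulate_dwi(fs, schp)$data[1, 1, 1, 1], exp(-0.4),
               tolerance = 1e-12)  # g parallel, pure stick
})

test_that("forward dMRI is invariant to population relabelling and axis sign flips", {
  sch <- shell_scheme(20, 4, seed = 3)
  fa <- build_fibre_field("crossing", shape = c(1, 1, 1), phi = 15, angle = 70,
                          f = 0.4, f2 = 0.25)
  fb <- fa
  fb$f[1, 1, 1, 1:2] <- fa$f[1, 1, 1, 2:1]
  fb$axes[1, 1, 1, 1:2, ] <- fa$axes[1, 1, 1, 2:1, ]
  expect_equal(simulate_dwi(fa, sch)$data, simulate_dwi(fb, sch)$data,
               tolerance = 1e-12)
  fc <- fa
  fc$axes[1, 1, 1, 1, ] <- -fa$axes[1, 1, 1, 1, ]
  expect_equal(simulate_dwi(fa, sch)$data, simulate_dwi(fc, sch)$data,
               tolerance = 1e-12)
})

test_that("powder mean of the stick signal matches the analytic orientational average", {
  f <- build_fibre_field("single", shape = c(1, 1, 1), phi = 33, incl = 21,
                         f = 1, d = 0.1)
  dirs <- generate_directions(250, seed = 4)
  sch <- gradient_scheme(dirs, 10)
  S <- simulate_dwi(f, sch)$data[1, 1, 1, ]
  expect_equal(mean(S), powder_stick_analytic(10 * 0.1), tolerance = 1e-3)
})

test_that("dispersed sticks attenuate less along the axis than pure sticks", {
  sch <- gradient_scheme(rbind(c(1, 0, 0), c(0, 0, 1)), 4)
  fi <- build_fibre_field("single", shape = c(1, 1, 1), phi = 0, f = 1, d = 0.1)
  fk <- build_fibre_field("single", shape = c(1, 1, 1), phi = 0, f = 1, d = 0.1,
                          kappa = 10)
  Si <- simulate_dwi(fi, sch)$data[1, 1, 1, ]
  Sk <- simulate_dwi(fk, sch)$data[1, 1, 1, ]
  expect_gt(Sk[1], Si[1])  # along the axis: dispersion spares some signal
  expect_lt(Sk[2], Si[2])  # perpendicular: dispersion attenuates
})

test_that("simulators are bit-reproducible for a fixed seed", {
  f <- build_fibre_field("undulation", shape = c(8, 4, 2), f = 0.6)
  sch <- shell_scheme(15, 4, seed = 5)
  a <- simulate_dwi(f, sch, noise_sigma = 0.05, seed = 11)
  b <- simulate_dwi(f, sch, noise_sigma = 0.05, seed = 11)
  expect_identical(a$data, b$data)
  scene <- phantom_scene(f, noise_sigma = 0.02, seed = 3)
  expect_identical(simulate_pli_stack(scene)$frames, simulate_pli_stack(scene)$frames)
  expect_identical(simulate_histology_image(scene, fibre_density = 0.001),
                   simulate_histology_image(scene, fibre_density = 0.001))
})

test_that("PLI rendering: through-plane fibres are flat, perpendicular crossings cancel", {
  f90 <- build_fibre_field("single", shape = c(2, 2, 1), phi = 0, incl = 90, f = 1)
  st <- simulate_pli_stack(phantom_scene(f90, seed = 1))
  expect_equal(max(st$frames) - min(st$frames), 0, tolerance = 1e-12)

  fx <- build_fibre_field("crossing", shape = c(2, 2, 1), phi = 0, angle = 90,
                          f = 0.4, f2 = 0.4)
  stx <- simulate_pli_stack(phantom_scene(fx, seed = 1))
  expect_equal(max(stx$frames) - min(stx$frames), 0, tolerance = 1e-12)

  f30 <- build_fibre_field("single", shape = c(2, 2, 1), phi = 30, f = 1)
  st30 <- simulate_pli_stack(phantom_scene(f30, seed = 1))
  expect_gt(max(st30$frames) - min(st30$frames), 0.5)
  expect_error(simulate_pli_stack(phantom_scene(f30, seed = 1), delta_max = 2),
               "delta_max")
})

test_that("the fitted sinusoid reproduces the generated frames (pi-periodic model)", {
  f <- build_fibre_field("single", shape = c(2, 2, 1), phi = 72, incl = 30, f = 0.8)
  st <- simulate_pli_stack(phantom_scene(f, seed = 1))
  maps <- fit_pli_sinusoid(st)
  rho <- st$analyser_angles * pi / 180
  m <- maps$transmittance[5, 5] / 2
  r <- maps$retardance[5, 5]; phi <- maps$angle[5, 5] * pi / 180
  recon <- m * (1 + r * sin(2 * rho - 2 * phi))
  expect_equal(recon, st$frames[5, 5, ], tolerance = 1e-10)
  # pi-periodicity of the model in the analyser angle
  expect_equal(m * (1 + r * sin(2 * (rho + pi) - 2 * phi)), recon,
               tolerance = 1e-12)
})

test_that("histology rendering follows the ground-truth orientation and density", {
  f <- build_fibre_field("single", shape = c(2, 2, 1), phi = 30, f = 1)
  scene <- phantom_scene(f, seed = 2)
  scene$section_planes[[1]] <- mid_plane_frame(f, pixels_per_voxel = 100L)
  img0 <- simulate_histology_image(scene, fibre_density = 0)
  expect_equal(max(img0) - min(img0), 0)

  img <- simulate_histology_image(scene)
  ot <- structure_tensor(img)
  tab <- aggregate_superpixels(ot, img, window = 100L)
  expect_true(all(axial_diff(tab$circ_mean[tab$valid], 30) < 2))

  # darker (more ink) with larger stick fraction
  f_lo <- build_fibre_field("single", shape = c(2, 2, 1), phi = 30, f = 0.3)
  scene_lo <- phantom_scene(f_lo, seed = 2)
  scene_lo$section_planes[[1]] <- scene$section_planes[[1]]
  img_lo <- simulate_histology_image(scene_lo)
  expect_gt(mean(img_lo), mean(img))
  expect_error(simulate_histology_image(scene, fibre_density = -1), "density")
})

test_that("phantom bundles are complete, deterministic and carry a usable affine", {
  f <- build_fibre_field("single", shape = c(4, 4, 2), phi = 20, f = 0.6)
  scene <- phantom_scene(f, seed = 9)
  scene$section_planes[[1]] <- mid_plane_frame(f, pixels_per_voxel = 5L)
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  sch <- shell_scheme(6, 4, seed = 2)
  m1 <- write_phantom_bundle(scene, d1, scheme = sch)
  m2 <- write_phantom_bundle(scene, d2, scheme = sch)
  expect_gte(sum(grepl("\\.nii", m1$file)), 1)
  expect_gte(sum(grepl("\\.tif$", m1$file)), 1)
  expect_gte(sum(grepl("\\.json$", m1$file)), 1)
  expect_equal(m1$md5, m2$md5)

  side <- jsonlite::read_json(file.path(d1, "pli_plane01.json"), simplifyVector = TRUE)
  A <- side$pixel_to_voxel_affine
  vox <- floor(A %*% c(1, 1, 1)) + 1  # pixel (col 1, row 1)
  frame <- scene$section_planes[[1]]
  expected <- floor(fibrefuse:::pixel_to_world(frame, 1, 1) / f$voxel_size) + 1
  expect_equal(as.vector(vox), as.vector(expected))
})
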