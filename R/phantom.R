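# Synthetic phantom: ground-truth fibre fields rendered as co-registered
# diffusion MRI, PLI stacks and histology-like oriented textures. Every
# downstream stage of the package is testable against these generators
# without any acquired data.

#' Build a ground-truth fibre field
#'
#' Constructs a voxel grid of fibre populations following one of four
#' canonical white-matter geometries: a coherent bundle (`single`), two
#' interdigitated bundles at a fixed angle (`crossing`), a fan whose axis
#' rotates linearly across one grid dimension (`fanning`), or a sinusoidally
#' undulating bundle (`undulation`).
#'
#' Each voxel holds up to 3 populations of (unit axis, signal fraction `f`,
#' Bingham-type concentration `kappa`; `Inf` means no dispersion). The
#' remaining signal fraction `1 - sum(f)` is an isotropic "ball".
#'
#' @param recipe One of `"single"`, `"crossing"`, `"fanning"`, `"undulation"`.
#' @param shape Grid dimensions (length 3).
#' @param voxel_size Voxel edge lengths in mm.
#' @param phi,incl In-plane angle and inclination (degrees) of the (first)
#'   population axis.
#' @param f,f2 Signal fractions of the first and (crossing) second population.
#' @param angle Crossing angle in degrees (between in-plane angles).
#' @param incl2 Inclination of the second (crossing) population.
#' @param kappa Dispersion concentration; `Inf` = perfectly coherent.
#' @param max_angle Fanning: in-plane angle ramps linearly from `phi` at the
#'   first column to `phi + max_angle` at the last.
#' @param wavelength,amplitude Undulation: axis angle
#'   `phi + amplitude * sin(2 pi x / wavelength)` (x in voxels).
#' @param d Ball/stick diffusivity in um^2/ms.
#' @param s0 Baseline (b = 0) signal.
#' @return A `fibre_field` object.
#' @export
build_fibre_field <- function(recipe = c("single", "crossing", "fanning", "undulation"),
                              shape = c(8, 8, 4), voxel_size = c(1, 1, 1),
                              phi = 0, incl = 0, f = 0.7,
                              angle = 90, f2 = NULL, incl2 = 0,
                              kappa = Inf,
                              max_angle = 60, wavelength = 8, amplitude = 30,
                              d = 0.1, s0 = 1) {
  recipe <- match.arg(recipe)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), d > 0)
  fr <- array(0, dim = c(shape, 3))
  ax <- array(0, dim = c(shape, 3, 3))
  kp <- array(Inf, dim = c(shape, 3))

  set_pop <- function(pop, axis, frac, conc, cols = NULL) {
    if (frac < 0) stop("negative fraction")
    idx_cols <- if (is.null(cols)) seq_len(shape[1]) else cols
    for (x in idx_cols) {
      a <- if (is.matrix(axis)) axis[x, ] else axis
      fr[x, , , pop] <<- frac
      for (cc in 1:3) ax[x, , , pop, cc] <<- a[cc]
      kp[x, , , pop] <<- conc
    }
  }

  if (recipe == "single") {
    set_pop(1, unit(axis_from_angles(phi, incl)), f, kappa)
  } else if (recipe == "crossing") {
    if (is.null(f2)) f2 <- f
    set_pop(1, unit(axis_from_angles(phi, incl)), f, kappa)
    set_pop(2, unit(axis_from_angles(phi + angle, incl2)), f2, kappa)
  } else if (recipe == "fanning") {
    nx <- shape[1]
    phis <- if (nx == 1) phi else phi + max_angle * (seq_len(nx) - 1) / (nx - 1)
    A <- t(vapply(phis, function(p) axis_from_angles(p, incl), numeric(3)))
    set_pop(1, A, f, kappa)
  } else {
    nx <- shape[1]
    phis <- phi + amplitude * sin(2 * pi * (seq_len(nx) - 1) / wavelength)
    A <- t(vapply(phis, function(p) axis_from_angles(p, incl), numeric(3)))
    set_pop(1, A, f, kappa)
  }
  if (max(apply(fr, 1:3, sum)) > 1 + 1e-12) stop("fractions sum to more than 1")
  structure(list(shape = shape, voxel_size = voxel_size,
                 f = fr, axes = ax, kappa = kp, d = d, s0 = s0),
            class = "fibre_field")
}

#' @export
print.fibre_field <- function(x, ...) {
  cat("Fibre field:", paste(x$shape, collapse = " x "), "voxels,",
      "voxel size", paste(x$voxel_size, collapse = " x "), "mm\n")
  cat("  d =", x$d, "um^2/ms, s0 =", x$s0, "\n")
  npop <- sum(x$f[1, 1, 1, ] > 0)
  cat("  populations in voxel (1,1,1):", npop,
      " ball fraction:", 1 - sum(x$f[1, 1, 1, ]), "\n")
  invisible(x)
}

# Fraction/axis/kappa of one voxel as a list of populations.
voxel_populations <- function(field, i, j, k) {
  pops <- list()
  for (p in 1:3) {
    fp <- field$f[i, j, k, p]
    if (fp > 0) {
      pops[[length(pops) + 1]] <- list(f = fp,
                                       axis = field$axes[i, j, k, p, ],
                                       kappa = field$kappa[i, j, k, p])
    }
  }
  pops
}

#' Bundle a fibre field with section planes for microscopy simulation
#'
#' @param field A `fibre_field`.
#' @param section_planes List of `plane_frame` objects (see [plane_frame()]);
#'   defaults to one mid-depth axial plane sampled at 20 pixels per voxel
#'   (in-plane pixel size `voxel_size/20`).
#' @param noise_sigma Additive noise level in `s0` units (Rician for dMRI,
#'   Gaussian for microscopy).
#' @param seed Integer seed controlling all randomness of the scene.
#' @return A `phantom_scene` object.
#' @export
phantom_scene <- function(field, section_planes = NULL, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(field, "fibre_field"))
  if (is.null(section_planes)) {
    section_planes <- list(mid_plane_frame(field, pixels_per_voxel = 20L))
  }
  for (pl in section_planes) stopifnot(inherits(pl, "plane_frame"), pl$pixel_size > 0)
  structure(list(field = field, section_planes = section_planes,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_scene")
}

#' Mid-depth coronal-style section plane through a fibre field
#'
#' Convenience constructor for a plane normal to the z axis cutting the field
#' at mid depth, with pixels aligned to the voxel grid.
#'
#' @param field A `fibre_field`.
#' @param pixels_per_voxel In-plane sampling density.
#' @param section_thickness Section thickness in um.
#' @return A `plane_frame`.
#' @export
mid_plane_frame <- function(field, pixels_per_voxel = 20L, section_thickness = 50) {
  vs <- field$voxel_size
  px_um <- vs[1] * 1000 / pixels_per_voxel
  z_mid <- (field$shape[3] / 2 - 0.5 + 0.5) * vs[3]  # centre of mid voxel layer
  dims <- c(field$shape[2] * pixels_per_voxel, field$shape[1] * pixels_per_voxel)
  plane_frame(origin = c(px_um / 2000, px_um / 2000, z_mid - vs[3] / 2),
              e1 = c(1, 0, 0), e2 = c(0, 1, 0),
              pixel_size = px_um, dims = dims,
              voxel_size = vs, section_thickness = section_thickness)
}

# Map all pixel centres of a plane to voxel indices of the field; returns a
# data.frame with pixel rows/cols and voxel ijk (NA outside the field).
plane_pixel_voxels <- function(frame, field) {
  H <- frame$dims[1]; W <- frame$dims[2]
  px <- expand.grid(row = seq_len(H), col = seq_len(W))
  world <- pixel_to_world(frame, px$col, px$row)
  vx <- floor(sweep(world, 2, field$voxel_size, "/")) + 1
  ok <- vx[, 1] >= 1 & vx[, 1] <= field$shape[1] &
        vx[, 2] >= 1 & vx[, 2] <= field$shape[2] &
        vx[, 3] >= 1 & vx[, 3] <= field$shape[3]
  vx[!ok, ] <- NA
  cbind(px, i = vx[, 1], j = vx[, 2], k = vx[, 3])
}

#' Simulate a diffusion-weighted volume from a fibre field
#'
#' Forward ball-and-stick(s) model with optional Bingham-type dispersion.
#' For linear tensor encoding the signal is
#' `S(g,b) = s0 * [(1 - sum f_i) exp(-b d) + sum_i f_i <exp(-b d (g.n)^2)>]`,
#' where `< >` averages the stick response over the population's axial
#' (Watson) orientation distribution by quadrature on the shared sphere grid;
#' `kappa = Inf` collapses to a pure stick. Spherical tensor encoding
#' attenuates each compartment by `exp(-b * d_mean)` with `d_mean = d` for the
#' ball and `d/3` for sticks. Noise is Rician with scale `noise_sigma` in
#' `s0` units.
#'
#' @param field A `fibre_field`.
#' @param scheme A `gradient_scheme` (b in ms/um^2).
#' @param noise_sigma Rician noise sigma (0 = noiseless closed form).
#' @param seed Integer seed.
#' @return A `dwi_volume` (see [dwi_volume()]).
#' @export
simulate_dwi <- function(field, scheme, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(field, "fibre_field"), inherits(scheme, "gradient_scheme"))
  b <- scheme$bvals
  G <- scheme$directions
  sph <- scheme$encoding == "spherical"
  nvol <- length(b)
  d <- field$d; s0 <- field$s0
  sh <- field$shape
  data <- array(0, dim = c(sh, nvol))
  Q <- fod_sphere_grid(256L)[1:128, ]  # half set: Watson weights are axial

  ball <- exp(-b * d)  # same for linear & spherical encodings
  stick_sph <- exp(-b * d / 3)

  # cache attenuation profiles per unique (axis, kappa) population
  att_cache <- new.env(parent = emptyenv())
  pop_att <- function(axis, kappa) {
    key <- paste(signif(axis, 12), signif(kappa, 12), collapse = "_")
    if (!is.null(att_cache[[key]])) return(att_cache[[key]])
    if (!is.finite(kappa)) {
      ga2 <- (G %*% axis)^2
      att <- exp(-b * d * ga2)
    } else {
      w <- exp(kappa * (Q %*% axis)^2)
      w <- w / sum(w)
      M <- (G %*% t(Q))^2                # nvol x 128
      att <- as.vector(exp(-(b * d) * M) %*% w)
    }
    att[sph] <- stick_sph[sph]
    att_cache[[key]] <- att
    att
  }

  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) for (k in seq_len(sh[3])) {
    pops <- voxel_populations(field, i, j, k)
    fsum <- sum(vapply(pops, `[[`, numeric(1), "f"))
    S <- (1 - fsum) * ball
    for (p in pops) S <- S + p$f * pop_att(p$axis, p$kappa)
    data[i, j, k, ] <- s0 * S
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    n1 <- array(stats::rnorm(length(data), 0, noise_sigma * s0), dim = dim(data))
    n2 <- array(stats::rnorm(length(data), 0, noise_sigma * s0), dim = dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  dwi_volume(data, scheme)
}

#' Simulate a polarimetric (PLI) image stack
#'
#' Renders the forward polarimetric signal of the fibre content under each
#' pixel: frame `k` at analyser angle `rho_k = k * 180/n_frames` has
#' `I(rho_k) = (I_T/2) * [1 + sum_i w_i sin(delta_max cos^2 alpha_i)
#' sin(2 rho_k - 2 phi_i)]`, with per-population weights `w_i = f_i`
#' (intensity-level linear mixing), in-plane angle `phi_i` and inclination
#' `alpha_i` relative to the section plane. Through-plane fibres
#' (`alpha = 90` degrees) contribute no modulation; two equal perpendicular
#' in-plane populations cancel, producing the characteristic dark bands
#' between crossing tracts.
#'
#' @param scene A `phantom_scene`.
#' @param plane_index Which section plane to render.
#' @param n_frames Number of analyser steps over [0, 180) degrees.
#' @param delta_max Peak retardation (radians, in (0, pi/2]).
#' @param i_t Transmittance level (intensity units).
#' @return A `pli_stack`.
#' @export
simulate_pli_stack <- function(scene, plane_index = 1L, n_frames = 9L,
                               delta_max = pi / 2, i_t = 1) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (delta_max <= 0 || delta_max > pi / 2) stop("delta_max outside (0, pi/2]")
  frame <- scene$section_planes[[plane_index]]
  field <- scene$field
  map <- plane_pixel_voxels(frame, field)
  if (all(is.na(map$i))) stop("section plane does not intersect the field")
  H <- frame$dims[1]; W <- frame$dims[2]
  rho <- (seq_len(n_frames) - 1) * 180 / n_frames

  # complex modulation per pixel: sum_i w_i sin(delta_max cos^2 a_i) e^{-2i phi_i}
  zmod <- complex(real = rep(0, H * W), imaginary = rep(0, H * W))
  ok <- !is.na(map$i)
  vox_key <- paste(map$i, map$j, map$k)
  for (key in unique(vox_key[ok])) {
    sel <- which(vox_key == key & ok)
    ijk <- c(map$i[sel[1]], map$j[sel[1]], map$k[sel[1]])
    z <- 0
    for (p in voxel_populations(field, ijk[1], ijk[2], ijk[3])) {
      pr <- project_axis_to_frame(p$axis, frame)
      a <- pr$inclination_rad
      z <- z + p$f * sin(delta_max * cos(a)^2) * exp(2i * deg2rad(pr$angle))
    }
    zmod[sel] <- z
  }
  frames <- array(0, dim = c(H, W, n_frames))
  amp <- Mod(zmod); ph <- Arg(zmod)
  for (k in seq_len(n_frames)) {
    modk <- amp * sin(2 * deg2rad(rho[k]) - ph)
    frames[, , k] <- matrix((i_t / 2) * (1 + modk), H, W)
  }
  if (scene$noise_sigma > 0) {
    set.seed(scene$seed + 1000L * plane_index)
    frames <- frames + array(stats::rnorm(length(frames), 0, scene$noise_sigma),
                             dim = dim(frames))
    frames[frames < 0] <- 0
  }
  pli_stack(frames, analyser_angles = rho, pixel_size = frame$pixel_size,
            section_thickness = frame$section_thickness)
}

# In-plane angle (deg) and inclination (rad, in [0, pi/2]) of an axis
# relative to a plane frame.
project_axis_to_frame <- function(axis, frame) {
  x1 <- sum(axis * frame$e1); x2 <- sum(axis * frame$e2); xn <- sum(axis * frame$normal)
  list(angle = wrap_axial(rad2deg(atan2(x2, x1))),
       inclination_rad = asin(pmin(1, abs(xn))))
}

#' Simulate a myelin-stain-like oriented texture
#'
#' Renders randomly placed dark line segments on a bright background, each
#' aligned with the local ground-truth in-plane orientation, with angular
#' jitter drawn from the voxel population's dispersion (axial von Mises with
#' the population's `kappa`). Segment density scales with the local total
#' stick fraction.
#'
#' @param scene A `phantom_scene`.
#' @param plane_index Which section plane to render.
#' @param fibre_density Expected segment-centre count per pixel at
#'   `sum(f) = 1` (before fraction scaling).
#' @param seed Integer seed (defaults to the scene seed).
#' @param segment_length,segment_value Segment length in pixels and grey-level
#'   decrement per pass.
#' @param orientation_cell_px Spatial correlation scale (pixels) of the
#'   angular jitter: segments within one cell share a dispersion draw, so the
#'   orientation field varies on a scale resolvable by the structure-tensor
#'   integration window, as in real fibre bundles (jitter uncorrelated below
#'   the kernel scale is indistinguishable from a coherent texture).
#' @return A grey-level matrix in [0, 1] with attributes `pixel_size` (um)
#'   and `frame`.
#' @export
simulate_histology_image <- function(scene, plane_index = 1L, fibre_density = 0.002,
                                     seed = NULL, segment_length = 60,
                                     segment_value = 0.45,
                                     orientation_cell_px = 20L) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (fibre_density < 0) stop("density < 0")
  if (is.null(seed)) seed <- scene$seed + 2000L * plane_index
  frame <- scene$section_planes[[plane_index]]
  field <- scene$field
  H <- frame$dims[1]; W <- frame$dims[2]
  ink <- matrix(0, H, W)
  if (fibre_density > 0) {
    set.seed(seed)
    n_cand <- stats::rpois(1, fibre_density * H * W)
    if (n_cand > 0) {
      cx <- stats::runif(n_cand, 0.5, W + 0.5)
      cy <- stats::runif(n_cand, 0.5, H + 0.5)
      world <- pixel_to_world(frame, cx, cy)
      vx <- floor(sweep(world, 2, field$voxel_size, "/")) + 1
      u <- stats::runif(n_cand)
      # per-cell dispersion draws (shared within a correlation cell)
      n_cx <- ceiling(W / orientation_cell_px); n_cy <- ceiling(H / orientation_cell_px)
      cell_jitter <- new.env(parent = emptyenv())
      jitter_for <- function(cell_id, pop_id, kappa) {
        key <- paste(cell_id, pop_id)
        if (is.null(cell_jitter[[key]])) {
          dj <- if (is.finite(kappa)) {
            d0 <- r_axial_vonmises(1, 0, kappa)
            if (d0 > 90) d0 - 180 else d0
          } else 0
          cell_jitter[[key]] <- dj
        }
        cell_jitter[[key]]
      }
      vs_mm <- field$voxel_size
      # cache of per-voxel population angles/kappas projected into the plane
      vox_cache <- new.env(parent = emptyenv())
      vox_info <- function(vi) {
        key <- paste(vi, collapse = " ")
        if (is.null(vox_cache[[key]])) {
          pl <- voxel_populations(field, vi[1], vi[2], vi[3])
          vox_cache[[key]] <- lapply(pl, function(p) {
            pr <- project_axis_to_frame(p$axis, frame)
            list(angle = pr$angle, kappa = p$kappa, f = p$f)
          })
        }
        vox_cache[[key]]
      }
      for (s in seq_len(n_cand)) {
        i <- vx[s, 1]; j <- vx[s, 2]; k <- vx[s, 3]
        if (is.na(i) || i < 1 || i > field$shape[1] || j < 1 || j > field$shape[2] ||
            k < 1 || k > field$shape[3]) next
        pops <- voxel_populations(field, i, j, k)
        if (length(pops) == 0) next
        fs <- vapply(pops, `[[`, numeric(1), "f")
        if (u[s] > sum(fs)) next  # thin by stick fraction
        pop_id <- sample.int(length(fs), 1, prob = fs)
        # trace a curved stroke whose local tangent follows the dispersion
        # draw of the correlation cell it is passing through
        step_px <- 0.5
        for (dir_sign in c(1, -1)) {
          x <- cx[s]; y <- cy[s]
          prev_th <- NA_real_
          for (step in seq_len(round(segment_length / step_px))) {
            xi <- round(x); yi <- round(y)
            if (xi < 1 || xi > W || yi < 1 || yi > H) break
            vi <- floor(c(pixel_to_world(frame, x, y)) / vs_mm) + 1
            if (any(vi < 1) || any(vi > field$shape)) break
            pl <- vox_info(vi)
            if (length(pl) < pop_id) break
            p <- pl[[pop_id]]
            cell_id <- (ceiling(y / orientation_cell_px) - 1) * n_cx +
              ceiling(x / orientation_cell_px)
            th <- p$angle + jitter_for(cell_id, pop_id, p$kappa)
            # axial continuity of the heading along the stroke
            if (!is.na(prev_th) && axial_diff(th, prev_th) > 60) break
            if (!is.na(prev_th)) {
              if (cos(deg2rad(th - prev_th)) < 0) th <- th + 180
            }
            prev_th <- th
            # anti-aliased deposition: bilinear splat onto the ink canvas so
            # oblique strokes do not leave staircase edges (which would add
            # spurious off-orientation gradient energy)
            x0 <- floor(x); y0 <- floor(y)
            fx <- x - x0; fy <- y - y0
            for (oy in 0:1) for (ox in 0:1) {
              yy <- y0 + oy; xx <- x0 + ox
              if (xx >= 1 && xx <= W && yy >= 1 && yy <= H) {
                wgt <- (if (ox == 0) 1 - fx else fx) * (if (oy == 0) 1 - fy else fy)
                ink[yy, xx] <- ink[yy, xx] + wgt
              }
            }
            x <- x + dir_sign * step_px * cos(deg2rad(th))
            y <- y + dir_sign * step_px * sin(deg2rad(th))
          }
        }
      }
    }
  }
  # slight blur plus smooth saturation: even ink coverage along each stroke
  # (no longitudinal intensity ripple) and soft stroke edges
  kb <- gauss_kernel_1d(0.8)
  ink <- conv2_replicate(ink, outer(kb$g, kb$g))
  img <- 0.9 - (0.9 - 0.05) * (1 - exp(-0.9 * ink)) * (segment_value / 0.45)
  if (scene$noise_sigma > 0) {
    set.seed(seed + 1L)
    img <- pmin(pmax(img + matrix(stats::rnorm(H * W, 0, scene$noise_sigma), H, W), 0), 1)
  }
  attr(img, "pixel_size") <- frame$pixel_size
  attr(img, "frame") <- frame
  img
}

#' Write a simulated phantom bundle to disk
#'
#' Simulates dMRI, PLI and histology for a scene and writes: a 4D NIfTI with
#' bvals/bvecs, one multi-page TIFF per PLI stack (plus a JSON sidecar with
#' the analyser angles), one TIFF per histology image, the ground-truth fibre
#' table as TSV, a JSON sidecar with the pixel-to-voxel affine and units, and
#' a manifest TSV listing every file with its MD5 checksum. Re-running with
#' the same scene and seed reproduces identical checksums.
#'
#' @param scene A `phantom_scene`.
#' @param out_dir Output directory (created if missing).
#' @param scheme Gradient scheme for the dMRI simulation (default: 30
#'   electrostatic directions at b = 4 ms/um^2 plus one b = 0).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_phantom_bundle <- function(scene, out_dir, scheme = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable directory: ", out_dir)
  field <- scene$field
  if (is.null(scheme)) {
    dirs <- generate_directions(30, seed = scene$seed)
    scheme <- gradient_scheme(rbind(c(0, 0, 0), dirs), c(0, rep(4, 30)))
  }
  files <- character(0)

  dwi <- simulate_dwi(field, scheme, noise_sigma = scene$noise_sigma, seed = scene$seed)
  nii <- file.path(out_dir, "dwi.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dwi$data, pixdim = c(field$voxel_size, 1)), nii)
  files <- c(files, nii)
  files <- c(files, write_bvalbvec(scheme, file.path(out_dir, "dwi")))

  for (pi in seq_along(scene$section_planes)) {
    st <- simulate_pli_stack(scene, pi)
    tif <- file.path(out_dir, sprintf("pli_plane%02d.tif", pi))
    pages <- lapply(seq_len(dim(st$frames)[3]), function(k) st$frames[, , k])
    tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
    files <- c(files, tif)
    side <- file.path(out_dir, sprintf("pli_plane%02d.json", pi))
    fr <- scene$section_planes[[pi]]
    jsonlite::write_json(list(analyser_angles_deg = st$analyser_angles,
                              pixel_size_um = st$pixel_size,
                              section_thickness_um = st$section_thickness,
                              pixel_to_voxel_affine = pixel_to_voxel_affine(fr, field$voxel_size),
                              units = list(b = "ms/um^2", diffusivity = "um^2/ms",
                                           angle = "deg")),
                         side, digits = NA, auto_unbox = TRUE)
    files <- c(files, side)

    hist_img <- simulate_histology_image(scene, pi)
    htif <- file.path(out_dir, sprintf("histology_plane%02d.tif", pi))
    tiff::writeTIFF(hist_img, htif, bits.per.sample = 32L)
    files <- c(files, htif)
  }

  gt <- ground_truth_table(field)
  gt_path <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(gt, gt_path, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, gt_path)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# Long-format per-population ground-truth table.
ground_truth_table <- function(field) {
  rows <- list()
  sh <- field$shape
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) for (k in seq_len(sh[3])) {
    pops <- voxel_populations(field, i, j, k)
    for (p in seq_along(pops)) {
      pp <- pops[[p]]
      rows[[length(rows) + 1]] <- data.frame(i = i, j = j, k = k, population = p,
                                             f = pp$f, ax = pp$axis[1], ay = pp$axis[2],
                                             az = pp$axis[3], kappa = pp$kappa)
    }
  }
  do.call(rbind, rows)
}
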