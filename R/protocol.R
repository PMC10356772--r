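# Acquisition-protocol constants and small geometry helpers shared by the
# examples and the documentation.

#' Reference acquisition protocol
#'
#' The default geometry and sampling constants the package's simulators and
#' examples mirror: 4 um/pixel PLI of 50 um sections (9 analyser steps over
#' 0-180 degrees), 0.28 um/pixel myelin-stained histology analysed with a
#' 10-pixel structure-tensor kernel and 150-pixel (~40 um) superpixels with
#' 2-degree FOD bins, multi-shell diffusion MRI at b = 4/7/10 ms/um^2 with
#' 250 or 1000 directions per shell acquired in batches of 1 b~0 + 25
#' diffusion-weighted volumes, ball-and-stick fitting with up to 3
#' populations x 50 samples and a 0.05 fraction threshold, a 12-point
#' inversion-recovery series from 10 to 6000 ms, and 256-point orientation
#' histograms fitted with order-8 spherical harmonics.
#'
#' @return A named list of protocol constants.
#' @export
default_protocol <- function() {
  list(
    pli_pixel_um = 4,
    pli_section_um = 50,
    pli_n_frames = 9L,
    hist_pixel_um = 0.28,
    st_sigma_px = 10,
    superpixel_px = 150L,
    fod_bin_deg = 2,
    bvals = c(4, 7, 10),
    n_dirs = c(250L, 1000L, 1000L),
    batch_size = 25L,
    bas_max_populations = 3L,
    bas_n_samples = 50L,
    f_threshold = 0.05,
    n_ti = 12L,
    ti_range_ms = c(10, 6000),
    sphere_points = 256L,
    sh_lmax = 8L
  )
}

#' Pixel volume of a section-imaging modality
#'
#' @param pixel_size_um In-plane pixel edge in um.
#' @param section_thickness_um Section thickness in um.
#' @return Volume in um^3.
#' @export
pixel_volume <- function(pixel_size_um, section_thickness_um) {
  if (pixel_size_um <= 0 || section_thickness_um <= 0) stop("sizes must be positive")
  pixel_size_um^2 * section_thickness_um
}

#' Physical extent of a pixel-specified Gaussian kernel
#'
#' @param sigma_px Kernel sigma in pixels.
#' @param pixel_size_um Pixel edge in um.
#' @return Sigma in um.
#' @export
kernel_extent_um <- function(sigma_px, pixel_size_um) sigma_px * pixel_size_um
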