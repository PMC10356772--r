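# Axial-angle helpers shared across modules. Orientations are axial
# (v == -v, angles modulo 180 degrees) everywhere; degrees at the interface,
# radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the axial range [0, 180)
#'
#' @param x Angles in degrees.
#' @return Angles wrapped modulo 180 degrees.
#' @export
wrap_axial <- function(x) x %% 180

#' Axial difference between in-plane angles
#'
#' Smallest angle between two orientations defined modulo 180 degrees.
#'
#' @param a,b Angles in degrees (recycled).
#' @return Differences in degrees, in [0, 90].
#' @export
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Axial angle between 3D axes
#'
#' Angle between two axes (sign-invariant), `acos(|u . v|)`.
#'
#' @param u,v Unit 3-vectors, or matrices with one axis per row.
#' @return Angle(s) in degrees, in [0, 90].
#' @export
axial_angle <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  d <- abs(rowSums(u * matrix(v, nrow = nrow(u), ncol = 3, byrow = nrow(v) == 1)))
  rad2deg(acos(pmin(1, d)))
}

# Circular mean of axial angles (degrees in [0,180)), via doubled angles.
circ_mean_axial <- function(theta_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  z <- sum(weights * exp(2i * deg2rad(theta_deg)))
  wrap_axial(rad2deg(Arg(z) / 2))
}

# Mean resultant length of doubled axial angles; the sufficient statistic of
# the axial von Mises (in-plane Bingham) density.
resultant_axial <- function(theta_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  sw <- sum(weights)
  if (sw <= 0) stop("all weights are zero")
  Mod(sum(weights * exp(2i * deg2rad(theta_deg)))) / sw
}

# von Mises sampler (Best & Fisher 1979). mu in radians, on the full circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return((mu + stats::runif(n, -pi, pi)) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    m <- n - i
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(pmin(1, pmax(-1, f[ok])))
    k <- length(th)
    if (k > 0) {
      out[(i + 1):(i + k)] <- th
      i <- i + k
    }
  }
  (mu + out) %% (2 * pi)
}

# Axial von Mises sample: angles in degrees in [0,180) concentrated around
# mu_deg with concentration kappa on the doubled circle.
r_axial_vonmises <- function(n, mu_deg, kappa) {
  if (!is.finite(kappa)) return(rep(wrap_axial(mu_deg), n))
  th2 <- rvonmises(n, deg2rad(2 * mu_deg), kappa)
  wrap_axial(rad2deg(th2 / 2))
}

# Axis from in-plane angle phi (deg, from +x towards +y) and inclination
# alpha (deg, out of the xy-plane towards +z).
axis_from_angles <- function(phi_deg, incl_deg = 0) {
  p <- deg2rad(phi_deg); a <- deg2rad(incl_deg)
  c(cos(a) * cos(p), cos(a) * sin(p), sin(a))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector cannot be normalised")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
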