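# Ball-and-stick model: staged nonlinear fitting of up to three stick
# populations per voxel with residual-bootstrap orientation samples, and the
# dyadic-tensor precision statistic used to study angular-resolution effects.

sph2cart <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}
cart2sph_axis <- function(v) {
  v <- unit(v)
  if (v[3] < 0) v <- -v
  c(theta = acos(pmin(1, max(-1, v[3]))), phi = atan2(v[2], v[1]))
}

# Signal attenuation predicted from a parameter vector.
# p = (log s0, log d, z_1..z_k, theta_1, phi_1, ..., theta_k, phi_k)
bas_model <- function(p, k, b, G, sph) {
  s0 <- exp(p[1]); d <- exp(p[2])
  if (k > 0) {
    ez <- exp(p[3:(2 + k)])
    denom <- 1 + sum(ez)
    fb <- 1 / denom; fj <- ez / denom
  } else {
    fb <- 1; fj <- numeric(0)
  }
  ball <- exp(-b * d)
  att <- fb * ball
  stick_sph <- exp(-b * d / 3)
  for (j in seq_len(k)) {
    th <- p[2 + k + 2 * j - 1]; ph <- p[2 + k + 2 * j]
    v <- sph2cart(th, ph)
    a <- exp(-b * d * as.vector(G %*% v)^2)
    if (any(sph)) a[sph] <- stick_sph[sph]
    att <- att + fj[j] * a
  }
  s0 * att
}

bas_unpack <- function(p, k) {
  s0 <- exp(p[1]); d <- exp(p[2])
  if (k == 0) return(list(s0 = s0, d = d, f = numeric(0), axes = matrix(0, 0, 3)))
  ez <- exp(p[3:(2 + k)])
  denom <- 1 + sum(ez)
  f <- ez / denom
  axes <- t(vapply(seq_len(k), function(j)
    sph2cart(p[2 + k + 2 * j - 1], p[2 + k + 2 * j]), numeric(3)))
  list(s0 = s0, d = d, f = f, axes = axes)
}

# Analytic Jacobian of bas_model with respect to the parameter vector.
bas_jac <- function(p, k, b, G, sph) {
  s0 <- exp(p[1]); d <- exp(p[2])
  n <- length(b)
  if (k > 0) {
    ez <- exp(p[3:(2 + k)])
    denom <- 1 + sum(ez)
    fb <- 1 / denom; fj <- ez / denom
  } else {
    fb <- 1; fj <- numeric(0)
  }
  ball <- exp(-b * d)
  stick_sph <- exp(-b * d / 3)
  A <- matrix(0, n, max(k, 1))
  U <- matrix(0, n, max(k, 1))
  V <- matrix(0, 3, max(k, 1))
  for (j in seq_len(k)) {
    th <- p[2 + k + 2 * j - 1]; ph <- p[2 + k + 2 * j]
    v <- sph2cart(th, ph)
    V[, j] <- v
    u <- as.vector(G %*% v)
    a <- exp(-b * d * u^2)
    if (any(sph)) { a[sph] <- stick_sph[sph]; u[sph] <- 0 }
    A[, j] <- a; U[, j] <- u
  }
  att <- fb * ball + if (k > 0) as.vector(A[, seq_len(k), drop = FALSE] %*% fj) else 0
  J <- matrix(0, n, length(p))
  J[, 1] <- s0 * att                                   # d/d log s0
  cj <- U^2; if (any(sph)) cj[sph, ] <- 1 / 3          # compartment b-d factor
  dd <- fb * ball * b
  for (j in seq_len(k)) dd <- dd + fj[j] * cj[, j] * b * A[, j]
  J[, 2] <- -s0 * d * dd                               # d/d log d
  for (m in seq_len(k)) J[, 2 + m] <- s0 * fj[m] * (A[, m] - att)  # d/dz_m
  for (j in seq_len(k)) {
    th <- p[2 + k + 2 * j - 1]; ph <- p[2 + k + 2 * j]
    dvth <- c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
    dvph <- c(-sin(th) * sin(ph), sin(th) * cos(ph), 0)
    gth <- as.vector(G %*% dvth); gph <- as.vector(G %*% dvph)
    if (any(sph)) { gth[sph] <- 0; gph[sph] <- 0 }
    base <- -2 * b * d * U[, j] * A[, j] * s0 * fj[j]
    J[, 2 + k + 2 * j - 1] <- base * gth
    J[, 2 + k + 2 * j] <- base * gph
  }
  J
}

# Fit k sticks by Levenberg-Marquardt from a given start. Iteration-cap
# warnings are silenced; convergence is judged by the residual sum of squares.
bas_lm <- function(p0, k, S, b, G, sph, maxiter = 50L) {
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) bas_model(p, k, b, G, sph) - S,
                       jac = function(p) bas_jac(p, k, b, G, sph),
                       control = minpack.lm::nls.lm.control(maxiter = maxiter)))
  list(par = fit$par, rss = sum(fit$fvec^2))
}

#' Fit the ball-and-stick model with bootstrap orientation samples
#'
#' Staged nonlinear least squares per voxel: sticks are added one at a time
#' (multi-start initialisation from the DTI primary eigenvector plus fixed and
#' seeded random directions) and population `k` is kept only if it improves
#' the Bayesian information criterion and carries a signal fraction of at
#' least `f_threshold`. Orientation uncertainty is characterised by
#' `n_samples` residual-bootstrap refits per voxel, giving `n_samples` sample
#' axes per accepted population (matched to the point-estimate populations by
#' axial proximity). Populations are sorted by descending fraction.
#'
#' @param dwi A `dwi_volume`.
#' @param max_populations Maximum number of stick populations (<= 3).
#' @param n_samples Bootstrap orientation samples per population (0 = none).
#' @param f_threshold Minimum signal fraction for an accepted population.
#' @param seed Integer seed (multi-start directions and bootstrap resampling).
#' @param maxiter LM iteration cap for the main fits.
#' @return A `bas_fit`: arrays `f` (x,y,z,3), `axes` (x,y,z,3,3), `n_pop`,
#'   `d`, `s0`, and `samples` (x,y,z,3,n_samples,3; NA where absent).
#' @export
fit_ball_and_stick <- function(dwi, max_populations = 3L, n_samples = 50L,
                               f_threshold = 0.05, seed = 1L, maxiter = 50L) {
  stopifnot(inherits(dwi, "dwi_volume"), max_populations >= 1, max_populations <= 3)
  sch <- dwi$scheme
  b <- sch$bvals; G <- sch$directions; sph <- sch$encoding == "spherical"
  n <- length(b)
  if (n < 2 * max_populations + max_populations + 2)
    stop("fewer volumes than parameters")
  dims <- dim(dwi$data)[1:3]
  fA <- array(NA_real_, c(dims, 3)); axA <- array(NA_real_, c(dims, 3, 3))
  npA <- array(0L, dims); dA <- array(NA_real_, dims); s0A <- array(NA_real_, dims)
  smp <- if (n_samples > 0) array(NA_real_, c(dims, 3, n_samples, 3)) else NULL

  # DTI design pseudo-inverse for initialisation
  lin <- !sph & b > 1e-8
  Xd <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
              -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
              -2 * b * G[, 2] * G[, 3])
  # fixed extra-start directions spread over the half sphere
  extra_dirs <- generate_directions(6, seed = 7L)

  set.seed(seed)
  idx <- which(dwi$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k3 <- idx[r, 3]
    S <- dwi$data[i, j, k3, ]
    ok <- S > 0
    # DTI init
    cf <- tryCatch(stats::lm.fit(Xd[ok, , drop = FALSE], log(S[ok]))$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    D <- matrix(c(cf[2], cf[5], cf[6], cf[5], cf[3], cf[7], cf[6], cf[7], cf[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    v1 <- e$vectors[, 1]
    d0 <- max(mean(e$values), 1e-4)
    s00 <- exp(cf[1])

    # k = 0 (ball only)
    p_ball <- c(log(s00), log(d0))
    fit0 <- bas_lm(p_ball, 0L, S, b, G, sph, maxiter = maxiter)
    bic <- bas_bic(fit0$rss, n, 2)
    best <- list(k = 0L, par = fit0$par, rss = fit0$rss)

    prev <- best
    for (kk in seq_len(max_populations)) {
      # candidate axes for the new stick: DTI V1 for the first; afterwards the
      # gradient direction where the current model most over-predicts the
      # signal (a missing stick depresses the signal along its own axis),
      # plus one fixed and one seeded random restart
      resid_cur <- bas_model(prev$par, prev$k, b, G, sph) - S
      dw <- b > 1e-8 & !sph
      top <- which(dw)[order(resid_cur[dw], decreasing = TRUE)[1:2]]
      starts <- if (kk == 1) {
        list(v1, G[top[1], ], extra_dirs[sample.int(6, 1), ])
      } else {
        list(G[top[1], ], G[top[2], ], extra_dirs[sample.int(6, 1), ],
             unit(stats::rnorm(3)))
      }
      up_prev <- bas_unpack(prev$par, prev$k)
      cand_best <- NULL
      for (vstart in starts) {
        zs <- if (prev$k > 0) prev$par[3:(2 + prev$k)] else numeric(0)
        f_prev <- if (prev$k > 0) sum(up_prev$f) else 0
        f_new <- max(0.1, min(0.3, 1 - f_prev - 0.1))
        # z for the new stick given existing z's: solve softmax approximately
        z_new <- log(f_new / (1 - f_new)) # coarse init; LM refines
        ang_prev <- if (prev$k > 0)
          unlist(lapply(seq_len(prev$k), function(jj)
            prev$par[2 + prev$k + 2 * jj - c(1, 0)])) else numeric(0)
        sp <- cart2sph_axis(vstart)
        p0 <- c(prev$par[1:2], zs, z_new, ang_prev, sp[1], sp[2])
        fitk <- bas_lm(p0, kk, S, b, G, sph, maxiter = 10L)
        if (is.null(cand_best) || fitk$rss < cand_best$rss) cand_best <- fitk
      }
      cand_best <- bas_lm(cand_best$par, kk, S, b, G, sph, maxiter = maxiter)
      bick <- bas_bic(cand_best$rss, n, 2 + 3 * kk)
      upk <- bas_unpack(cand_best$par, kk)
      if (bick < bic && min(upk$f) >= f_threshold) {
        bic <- bick
        prev <- list(k = kk, par = cand_best$par, rss = cand_best$rss)
      } else break
    }

    up <- bas_unpack(prev$par, prev$k)
    ord <- order(up$f, decreasing = TRUE)
    npA[i, j, k3] <- prev$k
    dA[i, j, k3] <- up$d; s0A[i, j, k3] <- up$s0
    if (prev$k > 0) {
      for (p in seq_len(prev$k)) {
        fA[i, j, k3, p] <- up$f[ord[p]]
        ax <- up$axes[ord[p], ]
        if (ax[3] < 0) ax <- -ax
        axA[i, j, k3, p, ] <- ax
      }
      if (n_samples > 0) {
        Shat <- bas_model(prev$par, prev$k, b, G, sph)
        resid <- S - Shat
        # refits start at the point estimate: Gauss-Newton with the Jacobian
        # frozen at the optimum converges in a few steps there
        J <- bas_jac(prev$par, prev$k, b, G, sph)
        JtJ <- crossprod(J) + diag(1e-10, ncol(J))
        for (s in seq_len(n_samples)) {
          Sb <- Shat + sample(resid, n, replace = TRUE)
          fb <- bas_refit_gn(prev$par, prev$k, Sb, b, G, sph, J, JtJ)
          ub <- bas_unpack(fb$par, prev$k)
          # match bootstrap populations to point-estimate populations
          used <- rep(FALSE, prev$k)
          for (p in seq_len(prev$k)) {
            ref <- axA[i, j, k3, p, ]
            angs <- axial_angle(ub$axes, ref)
            angs[used] <- Inf
            m <- which.min(angs)
            used[m] <- TRUE
            ax <- ub$axes[m, ]
            if (sum(ax * ref) < 0) ax <- -ax
            smp[i, j, k3, p, s, ] <- ax
          }
        }
      }
    }
  }
  structure(list(f = fA, axes = axA, n_pop = npA, d = dA, s0 = s0A,
                 samples = smp, f_threshold = f_threshold),
            class = "bas_fit")
}

bas_bic <- function(rss, n, p) n * log(rss / n) + p * log(n)

# Bootstrap refit: damped Gauss-Newton from the point estimate with the
# Jacobian frozen at the optimum; falls back to a short LM run if the step
# fails to reduce the residual.
bas_refit_gn <- function(p0, k, S, b, G, sph, J, JtJ, iters = 3L) {
  p <- p0
  r <- bas_model(p, k, b, G, sph) - S
  rss <- sum(r^2)
  for (it in seq_len(iters)) {
    step <- tryCatch(solve(JtJ, crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    for (h in 1:4) {
      pn <- p - lambda * as.vector(step)
      rn <- bas_model(pn, k, b, G, sph) - S
      rssn <- sum(rn^2)
      if (rssn < rss) break
      lambda <- lambda / 2
    }
    if (rssn >= rss) break
    p <- pn; r <- rn; rss <- rssn
  }
  if (sum((bas_model(p0, k, b, G, sph) - S)^2) < rss)
    return(bas_lm(p0, k, S, b, G, sph, maxiter = 10L))
  list(par = p, rss = rss)
}

#' @export
print.bas_fit <- function(x, ...) {
  cat("Ball-and-stick fit:", sum(!is.na(x$d)), "voxels;",
      "population counts:", paste(names(table(x$n_pop)), table(x$n_pop),
                                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Orientation precision of a sample of axes
#'
#' Cone half-angle of the concentration of sample axes about their mean:
#' from the mean dyadic tensor `<v v^T>` over samples, the precision is
#' `acos(sqrt(lambda_max))` in degrees. Identical samples give 0; axes
#' uniform on the sphere give `acos(sqrt(1/3)) ~ 54.7` degrees.
#'
#' @param samples `m x 3` matrix of unit axes (m >= 2).
#' @return Dispersion angle in degrees.
#' @export
orientation_precision <- function(samples) {
  if (is.null(dim(samples)) || nrow(samples) < 2) stop("need >= 2 sample axes")
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (nrow(samples) < 2) stop("need >= 2 sample axes")
  M <- crossprod(samples) / nrow(samples)
  lmax <- max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  rad2deg(acos(sqrt(pmin(1, lmax))))
}

# Watson-distributed axes (rejection sampling); used as a sampling oracle.
r_watson <- function(n, mu, kappa) {
  mu <- unit(mu)
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 4L
    V <- matrix(stats::rnorm(3 * m), m, 3)
    V <- V / sqrt(rowSums(V^2))
    c2 <- (V %*% mu)^2
    acc <- stats::runif(m) < exp(kappa * (c2 - 1))
    V <- V[acc, , drop = FALSE]
    take <- min(nrow(V), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- V[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}
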