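# Gradient-direction schemes: electrostatic generation, incremental ordering,
# batch interleaving, and the bvals/bvecs text dialect.

.ff_cache <- new.env(parent = emptyenv())

#' Generate evenly distributed gradient directions
#'
#' Minimises the antipodally symmetric electrostatic energy
#' `sum_{i<j} 1/|g_i - g_j| + 1/|g_i + g_j|` by projected gradient descent
#' with backtracking, so directions spread evenly over the sphere while
#' treating `g` and `-g` as equivalent.
#'
#' @param n Number of directions (>= 1).
#' @param seed Integer seed for the random initial configuration.
#' @param iters Maximum repulsion iterations.
#' @return An `n x 3` matrix of unit row vectors with attributes
#'   `energy` (final energy) and `energy_trace` (per-iteration energies,
#'   non-increasing).
#' @export
generate_directions <- function(n, seed = 1L, iters = 300L) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1) {
    g <- matrix(c(0, 0, 1), 1, 3)
    attr(g, "energy") <- 0
    return(g)
  }
  set.seed(seed)
  G <- matrix(stats::rnorm(3 * n), n, 3)
  G <- G / sqrt(rowSums(G^2))

  energy_of <- function(G) {
    D <- tcrossprod(G)
    dm <- sqrt(pmax(2 - 2 * D, 0)); dp <- sqrt(pmax(2 + 2 * D, 0))
    iu <- upper.tri(D)
    sum(1 / dm[iu]) + sum(1 / dp[iu])
  }
  grad_of <- function(G) {
    D <- tcrossprod(G)
    dm2 <- pmax(2 - 2 * D, .Machine$double.eps)
    dp2 <- pmax(2 + 2 * D, .Machine$double.eps)
    am <- dm2^(-1.5); ap <- dp2^(-1.5)
    diag(am) <- 0; diag(ap) <- 0
    # dE/dg_i = -sum_j [(g_i - g_j) * am_ij + (g_i + g_j) * ap_ij]
    -(G * rowSums(am + ap) - (am - ap) %*% G)
  }

  e <- energy_of(G)
  trace <- numeric(0)
  step <- 0.1 / n
  for (it in seq_len(iters)) {
    gr <- grad_of(G)
    # project onto tangent planes
    gr <- gr - G * rowSums(gr * G)
    improved <- FALSE
    for (k in 1:30) {
      Gn <- G - step * gr
      Gn <- Gn / sqrt(rowSums(Gn^2))
      en <- energy_of(Gn)
      if (en < e) {
        G <- Gn; e <- en; improved <- TRUE
        step <- step * 1.5
        break
      }
      step <- step / 2
    }
    trace <- c(trace, e)
    if (!improved) break
  }
  attr(G, "energy") <- e
  attr(G, "energy_trace") <- trace
  G
}

#' Minimal pairwise axial angle of a direction set
#'
#' Coverage metric for gradient schemes: the smallest axial angle between any
#' pair of directions, in degrees. Larger values mean better spherical
#' coverage.
#'
#' @param directions Matrix of unit row vectors (>= 2 rows).
#' @return Scalar angle in degrees.
#' @export
coverage_metric <- function(directions) {
  if (is.null(dim(directions)) || nrow(directions) < 2)
    stop("need at least 2 directions")
  D <- abs(tcrossprod(directions))
  diag(D) <- 0
  rad2deg(acos(pmin(1, max(D[upper.tri(D)] , D[lower.tri(D)]))))
}

#' Order directions so every prefix covers the sphere well
#'
#' Reorders a direction set so that any consecutive leading subset retains
#' good angular coverage, preserving usable data if an acquisition is
#' interrupted. A hierarchy of nested subsets (each roughly 80% of the next)
#' is built by greedy maximin selection with pairwise exchange polishing, and
#' the permutation lists each level's additions in greedy maximin order, so
#' every prefix is close to an independently optimised subset of that size.
#'
#' @param directions Matrix of unit row vectors.
#' @return An integer permutation of `1:nrow(directions)`.
#' @export
order_incremental <- function(directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  n <- nrow(directions)
  if (n < 1) stop("need at least 1 direction")
  if (n == 1) return(1L)
  C <- abs(tcrossprod(directions))
  C[C > 1] <- 1
  if (any(C[upper.tri(C)] > 1 - 1e-12))
    warning("duplicate (axially colinear) directions; ties broken by input order")
  diag(C) <- 0

  # greedy maximin selection of m elements of `pool`, seeded by `seed_ids`
  greedy_select <- function(pool, m, seed_ids = integer(0)) {
    sel <- seed_ids
    if (length(sel) == 0) {
      # start from the best-separated pair in the pool
      Cp <- C[pool, pool, drop = FALSE]
      diag(Cp) <- Inf
      ij <- which(Cp == min(Cp), arr.ind = TRUE)[1, ]
      sel <- pool[ij]
    }
    best_dot <- apply(C[, sel, drop = FALSE], 1, max)
    while (length(sel) < m) {
      cand <- setdiff(pool, sel)
      nxt <- cand[which.min(best_dot[cand])]
      sel <- c(sel, nxt)
      best_dot <- pmax(best_dot, C[, nxt])
    }
    sel
  }

  # pairwise exchange polish: swap a member for an outsider while the
  # subset's worst pair improves
  polish <- function(sel, pool, sweeps = 20L) {
    out <- setdiff(pool, sel)
    if (length(out) == 0) return(sel)
    for (sw in seq_len(sweeps)) {
      Cs <- C[sel, sel, drop = FALSE]
      worst <- max(Cs)
      improved <- FALSE
      # try replacing each member of the worst pair
      wp <- which(Cs == worst, arr.ind = TRUE)[1, ]
      for (victim_pos in wp) {
        keep <- sel[-victim_pos]
        # best replacement: outsider minimising its max |dot| to the kept set
        md <- apply(C[out, keep, drop = FALSE], 1, max)
        cand <- out[which.min(md)]
        new_worst <- max(max(C[keep, keep]), min(md))
        if (new_worst < worst - 1e-12) {
          out <- c(out[out != cand], sel[victim_pos])
          sel <- c(keep, cand)
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    sel
  }

  # annealed exchange refinement for small subsets, where the greedy gap to
  # the best achievable subset is largest
  anneal <- function(sel, pool, iters = 4000L) {
    out <- setdiff(pool, sel)
    if (length(out) == 0) return(sel)
    cov_of <- function(s) max(C[s, s][upper.tri(diag(length(s)))])
    cur <- cov_of(sel); best <- sel; best_cov <- cur
    temp <- 0.05
    for (it in seq_len(iters)) {
      pos <- sample.int(length(sel), 1)
      swap_in <- out[sample.int(length(out), 1)]
      cand <- sel; cand[pos] <- swap_in
      cc <- cov_of(cand)
      if (cc < cur || stats::runif(1) < exp((cur - cc) / temp)) {
        out[out == swap_in] <- sel[pos]
        sel <- cand; cur <- cc
        if (cur < best_cov) { best <- sel; best_cov <- cur }
      }
      temp <- temp * 0.999
    }
    best
  }

  # nested subset hierarchy (largest to smallest)
  sizes <- n
  while (sizes[length(sizes)] > 2) {
    sizes <- c(sizes, max(2, floor(sizes[length(sizes)] * 0.8)))
  }
  levels <- list(seq_len(n))
  for (li in seq_along(sizes)[-1]) {
    pool <- levels[[li - 1]]
    sel <- greedy_select(pool, sizes[li])
    if (sizes[li] <= 128) sel <- polish(sel, pool)
    if (sizes[li] <= 64) {
      # deterministic refinement, leaving the caller's RNG state untouched
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(sizes[li])
      sel <- anneal(sel, pool)
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }
    levels[[li]] <- sel
  }

  # emit: smallest set first, then each level's additions in greedy order
  perm <- integer(0)
  for (li in rev(seq_along(levels))) {
    add <- setdiff(levels[[li]], perm)
    if (length(perm) == 0) {
      perm <- greedy_select(add, length(add))
    } else {
      best_dot <- apply(C[, perm, drop = FALSE], 1, max)
      while (length(add) > 0) {
        nxt <- add[which.min(best_dot[add])]
        perm <- c(perm, nxt)
        best_dot <- pmax(best_dot, C[, nxt])
        add <- add[add != nxt]
      }
    }
  }
  perm
}

#' Construct a gradient scheme
#'
#' @param directions `n x 3` matrix of unit vectors (axial: `g == -g`).
#' @param bvals b-values in ms/um^2, recycled to `n`.
#' @param encoding `"linear"` or `"spherical"` per entry, recycled.
#' @return A `gradient_scheme` object.
#' @export
gradient_scheme <- function(directions, bvals, encoding = "linear") {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  n <- nrow(directions)
  bvals <- rep_len(bvals, n)
  encoding <- rep_len(encoding, n)
  if (any(bvals < 0)) stop("negative b-values")
  nrm <- sqrt(rowSums(directions^2))
  dw <- bvals > 1e-8 & encoding == "linear"
  if (any(abs(nrm[dw] - 1) > 1e-8)) stop("non-unit gradient directions")
  structure(list(directions = directions, bvals = bvals, encoding = encoding,
                 acquisition_index = seq_len(n)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", length(x$bvals), "volumes\n")
  tb <- table(b = round(x$bvals, 3), encoding = x$encoding)
  print(tb)
  invisible(x)
}

#' Interleave b=0 volumes and de-colinearise batches
#'
#' Splits an incrementally ordered scheme into acquisition batches, inserting
#' one `b ~ 0` volume before each batch of diffusion-weighted volumes, and
#' permutes each batch so consecutive diffusion directions are at least
#' `min_succ_angle` apart (gradient-heating constraint). When the requested
#' separation is infeasible the permutation maximising the minimum consecutive
#' angle greedily is returned with a warning.
#'
#' @param scheme A `gradient_scheme` (already ordered).
#' @param batch_size Diffusion-weighted volumes per batch.
#' @param min_succ_angle Minimum axial angle (degrees) between consecutive
#'   diffusion directions.
#' @return A new `gradient_scheme` including the inserted b=0 entries.
#' @export
interleave_batches <- function(scheme, batch_size = 25L, min_succ_angle = 10) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (batch_size < 1) stop("batch_size must be >= 1")
  n <- nrow(scheme$directions)
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  dirs <- list(); bv <- c(); enc <- c()
  infeasible <- FALSE
  for (idx in batches) {
    D <- scheme$directions[idx, , drop = FALSE]
    m <- nrow(D)
    A <- abs(tcrossprod(D))
    A[A > 1] <- 1
    A <- rad2deg(acos(A))
    diag(A) <- 0
    ord <- 1L
    left <- setdiff(seq_len(m), ord)
    while (length(left) > 0) {
      # prefer the candidate clearing the threshold whose own worst remaining
      # neighbour is closest (keep well-separated options for the batch tail)
      prev <- ord[length(ord)]
      ang <- A[left, prev]
      ok <- ang >= min_succ_angle
      nxt <- if (any(ok)) left[ok][which.max(ang[ok])] else left[which.max(ang)]
      ord <- c(ord, nxt)
      left <- setdiff(left, nxt)
    }
    # repair pass: swap later elements into violating positions when both
    # affected links then clear the threshold
    if (m > 2) {
      for (pass in 1:3) {
        fixed_all <- TRUE
        for (pos in 2:m) {
          if (A[ord[pos - 1], ord[pos]] >= min_succ_angle) next
          fixed <- FALSE
          for (q in setdiff(2:m, pos)) {
            o2 <- ord
            o2[c(pos, q)] <- o2[c(q, pos)]
            links <- unique(pmax(2, pmin(m, c(pos - 1, pos, pos + 1, q - 1, q, q + 1))))
            if (all(A[cbind(o2[links - 1], o2[links])] >= min_succ_angle)) {
              ord <- o2; fixed <- TRUE; break
            }
          }
          if (!fixed) fixed_all <- FALSE
        }
        if (fixed_all) break
      }
      if (any(A[cbind(ord[-m], ord[-1])] < min_succ_angle)) infeasible <- TRUE
    }
    dirs[[length(dirs) + 1L]] <- rbind(c(0, 0, 0), D[ord, , drop = FALSE])
    bv <- c(bv, 0, scheme$bvals[idx][ord])
    enc <- c(enc, "linear", scheme$encoding[idx][ord])
  }
  if (infeasible)
    warning("min_succ_angle infeasible in a batch; minimum consecutive angle maximised instead")
  gradient_scheme(do.call(rbind, dirs), bv, enc)
}

# Minimum consecutive axial angle among diffusion-weighted entries of a batch
# layout (used by tests; b=0 entries reset the chain).
min_consecutive_angle <- function(scheme) {
  dw <- scheme$bvals > 1e-8
  ang <- c()
  idx <- which(dw)
  for (k in seq_along(idx)[-1]) {
    if (idx[k] == idx[k - 1] + 1) {
      a <- axial_angle(scheme$directions[idx[k - 1], ], scheme$directions[idx[k], ])
      ang <- c(ang, a)
    }
  }
  min(ang)
}

#' Write a scheme in the bvals/bvecs text dialect
#'
#' One-row `.bval` (space-separated b-values) and three-row `.bvec`
#' (x, y, z components).
#'
#' @param scheme A `gradient_scheme`.
#' @param prefix Output path prefix; writes `<prefix>.bval`, `<prefix>.bvec`.
#' @return Invisibly, the two file paths.
#' @export
write_bvalbvec <- function(scheme, prefix) {
  bval <- paste(format(scheme$bvals, trim = TRUE), collapse = " ")
  writeLines(bval, paste0(prefix, ".bval"))
  bv <- apply(t(scheme$directions), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(bv, paste0(prefix, ".bvec"))
  invisible(c(paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}

#' Read a bvals/bvecs pair
#'
#' @param prefix Path prefix as used by [write_bvalbvec()].
#' @param encoding Encoding label(s) for the entries.
#' @return A `gradient_scheme`.
#' @export
read_bvalbvec <- function(prefix, encoding = "linear") {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  rows <- lapply(readLines(paste0(prefix, ".bvec")), function(l) scan(text = l, quiet = TRUE))
  if (length(rows) != 3) stop("bvec file must have three rows")
  gradient_scheme(t(do.call(rbind, rows)), bvals, encoding)
}

#' Antipodally paired sphere point set
#'
#' The shared orientation-histogram support: `n` points evenly spaced on the
#' sphere by electrostatic repulsion, stored so that point `i + n/2` is the
#' antipode of point `i`. Memoised per `n`.
#'
#' @param n Total number of points (even; default 256).
#' @return An `n x 3` matrix of unit row vectors.
#' @export
fod_sphere_grid <- function(n = 256L) {
  if (n %% 2 != 0) stop("n must be even (antipodal pairing)")
  key <- paste0("grid", n)
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  half <- generate_directions(n / 2, seed = 20260921L, iters = 400L)
  attr(half, "energy") <- NULL; attr(half, "energy_trace") <- NULL
  pts <- rbind(half, -half)
  .ff_cache[[key]] <- pts
  pts
}
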