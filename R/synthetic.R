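## Ground-truth network and expression generators used by the benchmark
## experiments. All randomness comes from R's global RNG: set.seed() before
## calling for reproducibility.

#' Generate error terms with controllable gaussianity
#'
#' Error terms are `e = sign(z) * s * |z|^alpha` with `z ~ N(0, 1)` i.i.d.
#' `alpha = 1` is exactly Gaussian; larger `alpha` gives heavier tails.
#' The scale `s` is solved analytically so that `Var(e) = sigma2`, using
#' `E|z|^(2 alpha) = 2^alpha Gamma(alpha + 1/2) / sqrt(pi)` (the transformed
#' variable has mean 0 by sign symmetry).
#'
#' @param count number of series (columns).
#' @param m number of time points (rows).
#' @param sigma2 target variance (> 0).
#' @param alpha gaussianity exponent (> 0).
#' @return `m x count` numeric matrix.
#' @export
gen_error_series <- function(count, m, sigma2, alpha = 1) {
  stopifnot(sigma2 > 0, alpha > 0)
  s <- error_scale(sigma2, alpha)
  z <- matrix(stats::rnorm(m * count), m, count)
  sign(z) * s * abs(z)^alpha
}

error_scale <- function(sigma2, alpha) {
  e2a <- 2^alpha * gamma(alpha + 0.5) / sqrt(pi)   # E|z|^(2 alpha)
  sqrt(sigma2 / e2a)
}

rand_coef <- function(k) sample(c(-1, 1), k, replace = TRUE) *
  stats::runif(k, 0.5, 1.5)
rand_delay <- function(k, max_delay) sample.int(max_delay, k, replace = TRUE)

permute_observed <- function(grn) {
  n <- grn$n_observed
  perm <- sample.int(n)
  remap <- c(perm, n + seq_len(grn$n_hidden))
  e <- grn$edges
  e$src <- remap[e$src]; e$dst <- remap[e$dst]
  delayed_grn(e, n_observed = n, n_hidden = grn$n_hidden, labels = grn$labels)
}

#' Generate a small star network with one hidden hub
#'
#' `p` observed parents feed one hidden node, which feeds `c` observed
#' children; delays are uniform on `{1..max_delay}` and each coefficient is
#' `rho * z` with `rho` uniform on `{-1, 1}` and `z` uniform on (0.5, 1.5).
#' Observed indices are randomly permuted.
#'
#' @param p number of observed parents (>= 0).
#' @param c number of observed children (>= 2).
#' @param max_delay maximum delay (default 4).
#' @return a [delayed_grn] with `p + c` observed genes and 1 hidden node.
#' @export
gen_small_hidden_grn <- function(p, c, max_delay = 4L) {
  stopifnot(c >= 2L, p >= 0L)
  n <- p + c
  h <- n + 1L
  src <- c(seq_len(p), rep(h, c))
  dst <- c(rep(h, p), p + seq_len(c))
  k <- length(src)
  g <- delayed_grn(data.frame(src = src, dst = dst,
                              delay = rand_delay(k, max_delay),
                              effect = rand_coef(k)),
                   n_observed = n, n_hidden = 1L)
  permute_observed(g)
}

#' Generate a large random network with several hidden hubs
#'
#' For `n` observed genes and `n_h` hidden nodes: per-hidden parent counts
#' are drawn from `{0,1,2,3}` and child counts from `{2,3,4,5}`, with
#' `floor(n_h/4)` hidden nodes quota-assigned to each count and the rest
#' drawn uniformly. The observed genes are partitioned into others /
#' parents-of-hidden / children-of-hidden; others draw up to `M0` parents
#' from all observed genes, parents-of-hidden draw up to `M0` parents
#' excluding children-of-hidden as sources, hidden nodes are wired to
#' disjoint parent and child sets, children-of-hidden get no other parent.
#' Coefficients and delays are as in [gen_small_hidden_grn()]; the network
#' is rescaled for stability ([stabilize_grn()]) and observed indices are
#' permuted.
#'
#' @param n observed genes (large enough that some genes are left over
#'   after the hidden nodes' parents and children are assigned).
#' @param n_h hidden nodes (default `ceiling(n / 10)`).
#' @param M0 maximum parents for an observed gene (default 4).
#' @param max_delay maximum delay (default 4).
#' @return a [delayed_grn].
#' @export
gen_large_grn <- function(n, n_h = ceiling(n / 10), M0 = 4L, max_delay = 4L) {
  quota <- function(vals, k) {
    base <- rep(vals, each = k %/% 4L)
    extra <- if (k - length(base) > 0L)
      sample(vals, k - length(base), replace = TRUE) else integer()
    c(base, extra)
  }
  cnt_p <- quota(0:3, n_h)
  cnt_c <- quota(2:5, n_h)
  Np <- sum(cnt_p); Nc <- sum(cnt_c)
  No <- n - Np - Nc
  if (No <= 0L)
    stop("n = ", n, " too small for ", n_h, " hidden nodes (needs > ",
         Np + Nc, " observed genes)")
  src <- integer(); dst <- integer()
  for (i in seq_len(No)) {                        # others
    pi <- sample(0:M0, 1L)
    if (pi > 0L) {
      pars <- sample.int(n, pi)
      src <- c(src, pars); dst <- c(dst, rep(i, pi))
    }
  }
  for (i in No + seq_len(Np)) {                   # parents of hidden nodes
    pi <- sample(0:M0, 1L)
    if (pi > 0L) {
      pars <- sample.int(n - Nc, pi)
      src <- c(src, pars); dst <- c(dst, rep(i, pi))
    }
  }
  ppool <- No + seq_len(Np); cpool <- No + Np + seq_len(Nc)
  poff <- 0L; coff <- 0L
  for (j in seq_len(n_h)) {                       # hidden wiring
    hid <- n + j
    if (cnt_p[j] > 0L) {
      pars <- ppool[poff + seq_len(cnt_p[j])]; poff <- poff + cnt_p[j]
      src <- c(src, pars); dst <- c(dst, rep(hid, cnt_p[j]))
    }
    kids <- cpool[coff + seq_len(cnt_c[j])]; coff <- coff + cnt_c[j]
    src <- c(src, rep(hid, cnt_c[j])); dst <- c(dst, kids)
  }
  keep <- !duplicated(cbind(src, dst))
  src <- src[keep]; dst <- dst[keep]
  k <- length(src)
  g <- delayed_grn(data.frame(src = src, dst = dst,
                              delay = rand_delay(k, max_delay),
                              effect = rand_coef(k)),
                   n_observed = n, n_hidden = n_h)
  permute_observed(stabilize_grn(g))
}

companion_radius <- function(grn) {
  if (nrow(grn$edges) == 0L) return(0)
  ntot <- grn$n_observed + grn$n_hidden
  tau <- max(grn$edges$delay)
  C <- matrix(0, ntot * tau, ntot * tau)
  for (i in seq_len(nrow(grn$edges))) {
    e <- grn$edges[i, ]
    C[e$dst, (e$delay - 1L) * ntot + e$src] <-
      C[e$dst, (e$delay - 1L) * ntot + e$src] + e$effect
  }
  if (tau > 1L) {
    idx <- seq_len(ntot * (tau - 1L))
    C[cbind(ntot + idx, idx)] <- 1
  }
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Rescale a network's coefficients for simulation stability
#'
#' Builds the companion matrix of the linear recurrence the network defines
#' and, if its spectral radius is at least 0.95, multiplies all
#' coefficients by a common factor until the radius is at most 0.9 (an
#' acyclic network has radius 0 and is left untouched). Signs and delays
#' are unchanged.
#'
#' @param grn a [delayed_grn] with delays >= 1.
#' @return the rescaled [delayed_grn].
#' @export
stabilize_grn <- function(grn) {
  r <- companion_radius(grn)
  if (r < 0.95) return(grn)
  while (r > 0.9) {
    grn$edges$effect <- grn$edges$effect * min(0.9 / r, 0.95)
    r <- companion_radius(grn)
  }
  grn
}

#' Simulate one segment of expression data from a network
#'
#' Initialises a burn-in of `max_delay` time points with `N(0, 1)` draws,
#' then iterates `x_j(t) = sum_i a_ij x_i(t - tau_ij) + e_j(t)` for
#' `t = 1..m` over all nodes (observed and hidden), with error terms from
#' [gen_error_series()]. In heterogeneous mode each gene gets its own error
#' variance `sigma_i^2 = max(0.1, z_i)`, `z_i ~ N(2, delta2)`, replacing
#' `sigma2`.
#'
#' @param grn a (stabilised) [delayed_grn].
#' @param m number of emitted time points.
#' @param sigma2 error variance.
#' @param alpha gaussianity exponent.
#' @param observed_only emit only the observed genes' columns (the
#'   "incomplete" data); otherwise hidden columns are appended last.
#' @param hetero_delta2 optional `delta^2` for heterogeneous error
#'   variances.
#' @param max_delay burn-in length (default 4).
#' @return an [expression_segments] object with one segment.
#' @export
simulate_expression <- function(grn, m, sigma2, alpha = 1,
                                observed_only = TRUE, hetero_delta2 = NULL,
                                max_delay = 4L) {
  ntot <- grn$n_observed + grn$n_hidden
  tau <- max_delay
  A <- vector("list", tau)
  for (d in seq_len(tau)) A[[d]] <- matrix(0, ntot, ntot)
  for (i in seq_len(nrow(grn$edges))) {
    e <- grn$edges[i, ]
    A[[e$delay]][e$src, e$dst] <- A[[e$delay]][e$src, e$dst] + e$effect
  }
  if (is.null(hetero_delta2)) {
    err <- gen_error_series(ntot, m, sigma2, alpha)
  } else {
    s2 <- pmax(0.1, stats::rnorm(ntot, mean = 2, sd = sqrt(hetero_delta2)))
    z <- matrix(stats::rnorm(m * ntot), m, ntot)
    err <- sign(z) * abs(z)^alpha *
      matrix(error_scale(1, alpha) * sqrt(s2), m, ntot, byrow = TRUE)
  }
  x <- matrix(0, m + tau, ntot)
  x[seq_len(tau), ] <- stats::rnorm(tau * ntot)
  for (t in seq_len(m)) {
    row <- err[t, ]
    for (d in seq_len(tau))
      row <- row + x[t + tau - d, ] %*% A[[d]]
    x[t + tau, ] <- row
  }
  out <- x[tau + seq_len(m), , drop = FALSE]
  cols <- if (observed_only) seq_len(grn$n_observed) else seq_len(ntot)
  expression_segments(out[, cols, drop = FALSE], grn$labels[cols])
}

#' Simulate multiple short segments from a network
#'
#' Generates `K` independent segments, each with a fresh burn-in and an
#' independent uniform length between 20 and 30 time points (inclusive),
#' emulating replicate short time-course experiments.
#'
#' @inheritParams simulate_expression
#' @param K number of segments (>= 1).
#' @param len_range inclusive segment-length range.
#' @return an [expression_segments] object with `K` segments.
#' @export
simulate_segments <- function(grn, K, sigma2, alpha = 1,
                              observed_only = TRUE, hetero_delta2 = NULL,
                              max_delay = 4L, len_range = c(20L, 30L)) {
  stopifnot(K >= 1L)
  lens <- sample(seq.int(len_range[1L], len_range[2L]), K, replace = TRUE)
  segs <- lapply(lens, function(m)
    simulate_expression(grn, m, sigma2, alpha, observed_only,
                        hetero_delta2, max_delay)[[1L]])
  genes <- grn$labels[if (observed_only) seq_len(grn$n_observed)
                      else seq_len(grn$n_observed + grn$n_hidden)]
  expression_segments(segs, genes)
}

#' Generate a "confusing" control network with no hidden node
#'
#' Control case for false hidden-node detection: starting from data
#' simulated from a hidden-hub star where the hub is unobserved, the
#' two-stage engine is run on the incomplete data (score threshold 2); the
#' inferred network — which wrongly links the hub's relatives — is used as
#' a fully observed ground truth if non-empty. If the inference is empty, a
#' fallback star with one middle node, `p` parents and `c - 1` children
#' (all observed) is generated instead. The returned network is rescaled
#' for simulation stability.
#'
#' @param p,c parameters of the matching hidden-hub case.
#' @param data incomplete [expression_segments] simulated from a matching
#'   hidden-hub replicate; when `NULL` one is generated (`m = 200` points,
#'   `sigma2 = 2`, `alpha = 0.5`).
#' @param max_delay maximum delay.
#' @return a [delayed_grn] with `n_hidden = 0`.
#' @export
gen_confusing_nonhidden_grn <- function(p, c, data = NULL, max_delay = 4L) {
  if (is.null(data)) {
    g <- gen_small_hidden_grn(p, c, max_delay)
    data <- simulate_expression(g, m = 200L, sigma2 = 2, alpha = 0.5,
                                observed_only = TRUE, max_delay = max_delay)
  }
  inferred <- infer_initial_grn(data, st = 2, max_delay = max_delay)
  if (nrow(inferred$edges) > 0L) return(stabilize_grn(inferred))
  n <- p + c
  mid <- p + 1L
  src <- c(seq_len(p), rep(mid, c - 1L))
  dst <- c(rep(mid, p), p + 1L + seq_len(c - 1L))
  k <- length(src)
  g <- delayed_grn(data.frame(src = src, dst = dst,
                              delay = rand_delay(k, max_delay),
                              effect = rand_coef(k)),
                   n_observed = n, n_hidden = 0L)
  permute_observed(g)
}
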