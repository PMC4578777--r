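## Detection and reconstruction of hidden common causes. A gene whose
## parents in the initial network leave excess residual variance
## (Var(e) > (1+rho) sigma^2) is a candidate for having a hidden parent:
## when the true parent is hidden, the initial network substitutes the
## hidden node's other relatives, and the fitted error inherits the hidden
## node's own error variance on top of the gene's.

#' Residual variance of each gene given its network parents
#'
#' Regresses each gene's series on its parents' series lagged by the edge
#' delays (lag-aligned and concatenated across segments, intercept
#' included), and returns the residual variance with the sample size as
#' denominator. Parent-free genes get the raw variance of their series.
#' A gene whose aligned sample is smaller than its parent count + 2 also
#' falls back to the raw variance, with a warning.
#'
#' @param grn a [delayed_grn] over the observed genes.
#' @param data an [expression_segments] object.
#' @return numeric vector of per-gene residual variances.
#' @export
residual_variances <- function(grn, data) {
  n <- n_genes(data)
  out <- numeric(n)
  all_rows <- do.call(rbind, unclass(data))
  for (j in seq_len(n)) {
    par <- grn_parents(grn, j)
    par <- par[par$src <= n, , drop = FALSE]
    if (nrow(par) == 0L) {
      xj <- all_rows[, j]
      out[j] <- mean((xj - mean(xj))^2)
      next
    }
    s <- shift_and_concat(data, c(j, par$src), c(0L, par$delay))
    if (nrow(s) < nrow(par) + 2L) {
      warning("gene ", j, ": aligned sample too small for regression; ",
              "using raw variance")
      xj <- all_rows[, j]
      out[j] <- mean((xj - mean(xj))^2)
      next
    }
    X <- cbind(1, s[, -1L, drop = FALSE])
    fit <- stats::lm.fit(X, s[, 1L])
    out[j] <- mean(fit$residuals^2)
  }
  names(out) <- attr(data, "genes")
  out
}

#' Estimate the expected error variance
#'
#' When the error variance is unknown, it is estimated as the median of the
#' per-gene residual variances, relying on hidden nodes being few relative
#' to the observed genes.
#'
#' @param variances per-gene residual variances ([residual_variances()]).
#' @return scalar estimate of the error variance.
#' @export
estimate_sigma2 <- function(variances) {
  stopifnot(length(variances) >= 1L)
  stats::median(variances)
}

#' Flag genes suspected of having a hidden parent
#'
#' A gene is a candidate iff its residual variance strictly exceeds
#' `(1 + rho) * sigma2`.
#'
#' @param variances per-gene residual variances.
#' @param sigma2 expected error variance (> 0), known or estimated.
#' @param rho tolerance (>= 0, default 0.1).
#' @return list with `candidates` (integer indices, in gene order),
#'   `variances`, `sigma2`, `rho` and the `threshold` used.
#' @export
detect_candidates <- function(variances, sigma2, rho = 0.1) {
  stopifnot(sigma2 > 0, rho >= 0)
  thr <- (1 + rho) * sigma2
  list(candidates = which(variances > thr), variances = variances,
       sigma2 = sigma2, rho = rho, threshold = thr)
}

#' Maximum absolute shifted correlation between two series
#'
#' Similarity used by the candidate clustering: the maximum over shifts in
#' `-max_delay..max_delay` of the absolute correlation between gene `x` and
#' gene `y` shifted, on the lag-aligned multi-segment sample. Ties prefer
#' the smallest absolute shift, negative first.
#'
#' A positive shift `s` means `y` precedes `x` in time (`y(t) ~ x(t + s)`,
#' equivalently `y(t - s)` aligns with `x(t)`); this is the shift
#' convention the latent-series estimation consumes directly as
#' `x'(t - tau)`.
#'
#' @param x,y gene indices.
#' @param data an [expression_segments] object.
#' @param max_delay maximum shift magnitude.
#' @return list with `d` (similarity in \[0, 1\]) and `shift` (the
#'   maximising shift of `y` relative to `x`). Degenerate variance gives
#'   `d = 0`.
#' @export
max_abs_shifted_corr <- function(x, y, data, max_delay = 4L) {
  shifts <- seq.int(-max_delay, max_delay)
  shifts <- shifts[order(abs(shifts), shifts)]   # 0, -1, 1, -2, 2, ...
  best <- 0; best_shift <- 0L
  for (sh in shifts) {
    s <- shift_and_concat(data, c(x, y), c(0L, sh))
    if (nrow(s) < 3L) next
    if (stats::sd(s[, 1L]) < 1e-12 || stats::sd(s[, 2L]) < 1e-12) next
    r <- abs(stats::cor(s[, 1L], s[, 2L]))
    if (is.finite(r) && r > best + 1e-15) { best <- r; best_shift <- sh }
  }
  list(d = best, shift = best_shift)
}

## lower correlation threshold for merging two candidate genes whose error
## variances sit at the detection threshold rho0 = (1+rho) sigma^2:
## sqrt((1 - rho0/Var(x)) (1 - rho0/Var(y))); non-mergeable when either
## factor is non-positive (variance at or below the noise floor)
cluster_merge_threshold <- function(var_x, var_y, rho0) {
  fx <- 1 - rho0 / var_x
  fy <- 1 - rho0 / var_y
  if (fx <= 0 || fy <= 0) return(NA_real_)
  sqrt(fx * fy)
}

#' Greedily cluster candidate genes by shared hidden cause
#'
#' Single greedy pass in candidate (gene-index) order: the first candidate
#' seeds cluster 1 with shift 0; each following candidate joins the cluster
#' whose center (first member, never updated) is most similar by
#' [max_abs_shifted_corr()], provided the similarity reaches the derived
#' threshold `sqrt((1 - rho0/Var(center)) (1 - rho0/Var(g)))` with
#' `rho0 = (1 + rho) * sigma2`; otherwise it seeds a new cluster. Shifts are
#' recorded relative to the cluster center and capped at `max_delay` in
#' magnitude.
#'
#' @param candidates integer vector of candidate gene indices.
#' @param data an [expression_segments] object.
#' @param sigma2 expected error variance.
#' @param rho tolerance.
#' @param max_delay maximum shift searched.
#' @return list of clusters, each a list with `members` (gene indices) and
#'   `shifts` (integer, first member 0).
#' @export
cluster_candidates <- function(candidates, data, sigma2, rho = 0.1,
                               max_delay = 4L) {
  if (length(candidates) == 0L) return(list())
  rho0 <- (1 + rho) * sigma2
  all_rows <- do.call(rbind, unclass(data))
  raw_var <- apply(all_rows, 2L, function(v) mean((v - mean(v))^2))
  clusters <- list(list(members = candidates[1L], shifts = 0L))
  for (g in candidates[-1L]) {
    best_j <- 0L; best_d <- -Inf; best_shift <- 0L
    for (j in seq_along(clusters)) {
      cen <- clusters[[j]]$members[1L]
      mc <- max_abs_shifted_corr(cen, g, data, max_delay)
      if (mc$d > best_d) { best_d <- mc$d; best_j <- j; best_shift <- mc$shift }
    }
    cen <- clusters[[best_j]]$members[1L]
    thr <- cluster_merge_threshold(raw_var[cen], raw_var[g], rho0)
    if (!is.na(thr) && best_d >= thr) {
      clusters[[best_j]]$members <- c(clusters[[best_j]]$members, g)
      clusters[[best_j]]$shifts <- c(clusters[[best_j]]$shifts, best_shift)
    } else {
      clusters[[length(clusters) + 1L]] <- list(members = g, shifts = 0L)
    }
  }
  clusters
}

#' Reconstruct the latent series of a candidate cluster
#'
#' Centers each member series per segment, aligns members by their shifts
#' relative to the cluster center, and factorises the stacked overlap matrix
#' `Y` (members x time) by its leading singular triplet: `a = sigma * u`
#' holds the member coefficients and `h = v` the latent series over the
#' overlap, minimising the Frobenius residual among rank-1 fits. The
#' coefficients are estimated once from all segments' overlaps stacked
#' together; the non-overlapping prefix and suffix of each segment are then
#' filled by the least-squares value `h(t) = sum_k a_k x'_k(t - tau_k) /
#' sum_k a_k^2` over the members in range. Finally the series is shifted
#' forward so that it precedes all members in time:
#' `h'(t) = h(t + max(tau) + 1)` for `t = 1..m-1` and `h'(m) = 0`.
#'
#' The scale and sign of `(a, h)` are inherently undetermined; the sign is
#' fixed so the largest-magnitude coefficient is positive.
#'
#' @param cluster list with `members` and `shifts` ([cluster_candidates()]).
#' @param data an [expression_segments] object.
#' @param max_delay maximum delay (used only for sanity checks).
#' @return the cluster augmented with `coef` (one per member) and `latent`
#'   (list of per-segment numeric vectors, same lengths as the segments).
#' @export
estimate_hidden_series <- function(cluster, data, max_delay = 4L) {
  members <- cluster$members
  shifts <- as.integer(cluster$shifts)
  stopifnot(length(members) > 1L, length(shifts) == length(members))
  segs <- unclass(data)
  tmax <- max(shifts); tmin <- min(shifts)
  centred <- lapply(segs, function(s) {
    x <- s[, members, drop = FALSE]
    sweep(x, 2L, colMeans(x))
  })
  ## overlap of segment k: ts = 1 + max(tau) .. te = m + min(tau)
  ys <- lapply(centred, function(x) {
    m <- nrow(x)
    ts <- 1L + tmax; te <- m + tmin
    if (te - ts + 1L < 2L)
      stop("cluster overlap shorter than 2 points in a segment")
    tt <- ts:te
    y <- matrix(0, length(members), length(tt))
    for (k in seq_along(members)) y[k, ] <- x[tt - shifts[k], k]
    y
  })
  Y <- do.call(cbind, ys)
  sv <- svd(Y, nu = 1L, nv = 1L)
  a <- sv$d[1L] * sv$u[, 1L]
  ## sign convention: largest-|a| coefficient positive
  if (a[which.max(abs(a))] < 0) { a <- -a; sv$v <- -sv$v }
  hseg <- split(sv$v[, 1L],
                rep(seq_along(ys), vapply(ys, ncol, 0L)))
  a2 <- sum(a^2)
  latent <- vector("list", length(segs))
  for (si in seq_along(segs)) {
    x <- centred[[si]]
    m <- nrow(x)
    ts <- 1L + tmax; te <- m + tmin
    ## h(t) defined wherever some member is in range: 1+tmin .. m+tmax
    toff <- tmin                      # h stored at index t - tmin
    h <- rep(NA_real_, m + tmax - tmin)
    h[(ts:te) - toff] <- hseg[[si]]
    for (t in seq.int(1L + tmin, m + tmax)) {
      if (t >= ts && t <= te) next
      num <- 0; den <- 0
      for (k in seq_along(members)) {
        tk <- t - shifts[k]
        if (tk >= 1L && tk <= m) {
          num <- num + a[k] * x[tk, k]
          den <- den + a[k]^2
        }
      }
      h[t - toff] <- if (den > 0) num / den else 0
    }
    ## shift so the latent series precedes its children: h'(t) = h(t+tmax+1)
    hp <- numeric(m)
    for (t in seq_len(m - 1L)) hp[t] <- h[t + tmax + 1L - toff]
    hp[m] <- 0
    latent[[si]] <- hp
  }
  cluster$coef <- a
  cluster$latent <- latent
  cluster
}
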