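## Two-stage delayed conditional-independence engine:
## stage 1 scans all ordered gene pairs over all delays with correlation
## tests; stage 2 prunes indirect edges by partial correlation conditioned on
## time-shifted neighbours. Scores are -log10(p); an edge needs score > st.

corr_pvals <- function(r, n) {
  ## two-sided p-value of Pearson r via the t transform, df = n - 2
  df <- n - 2
  if (df < 1) return(rep(1, length(r)))
  r2 <- pmin(r * r, 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  2 * stats::pt(tt, df, lower.tail = FALSE)
}

#' Delayed correlation test between two genes
#'
#' Tests whether gene `x` lagged by `d` correlates with gene `y`, on the
#' lag-aligned sample concatenated across segments. The score is the
#' -log10 p-value of the two-sided Pearson test; the edge `x -> y` at delay
#' `d` is significant when the score exceeds the threshold `st`.
#'
#' @param x,y gene indices.
#' @param d integer lag in `0..max_delay`.
#' @param data an [expression_segments] object.
#' @param st score threshold.
#' @return list with `significant`, `score`, `effect` (the correlation; its
#'   sign is the estimated regulation direction) and `n` (effective sample
#'   size). Degenerate (near-constant) series give score 0, not significant.
#' @export
delayed_corr_test <- function(x, y, d, data, st = 2) {
  s <- shift_and_concat(data, c(x, y), c(d, 0L))
  n <- nrow(s)
  if (n < 4L || stats::sd(s[, 1L]) < 1e-12 || stats::sd(s[, 2L]) < 1e-12)
    return(list(significant = FALSE, score = 0, effect = 0, n = n))
  r <- stats::cor(s[, 1L], s[, 2L])
  score <- -log10(corr_pvals(r, n))
  list(significant = is.finite(r) && score > st, score = score,
       effect = r, n = n)
}

#' Stage 1: delayed correlation scan over all ordered pairs
#'
#' For every ordered pair of genes and every delay in `0..max_delay`
#' (self-pairs only for delay >= 1), keeps the edge when the delayed
#' correlation test is significant. Several delays may be retained for the
#' same pair. Delay-0 edges are kept at this stage (they inform the
#' conditioning sets) and discarded by [infer_initial_grn()].
#'
#' @param data an [expression_segments] object.
#' @param st score threshold on -log10(p).
#' @param max_delay maximum delay scanned.
#' @param allowed optional logical matrix (src x dst over the data's
#'   columns); pairs marked `FALSE` are never tested. Used by the restricted
#'   re-inference around hidden causes.
#' @return edge data.frame (`src`, `dst`, `delay`, `effect`, `score`).
#' @export
stage1_scan <- function(data, st = 2, max_delay = 4L, allowed = NULL) {
  n <- n_genes(data)
  out <- vector("list", max_delay + 1L)
  segs <- unclass(data)
  for (d in 0:max_delay) {
    lagged <- lapply(segs, function(s) {
      m <- nrow(s)
      if (m - d < 1L) return(NULL)
      list(a = s[seq_len(m - d), , drop = FALSE],
           b = s[(1L + d):m, , drop = FALSE])
    })
    lagged <- lagged[!vapply(lagged, is.null, TRUE)]
    if (length(lagged) == 0L) next
    A <- do.call(rbind, lapply(lagged, `[[`, "a"))
    B <- do.call(rbind, lapply(lagged, `[[`, "b"))
    neff <- nrow(A)
    if (neff < 4L) next
    sda <- apply(A, 2L, stats::sd); sdb <- apply(B, 2L, stats::sd)
    ok <- outer(sda > 1e-12, sdb > 1e-12, "&")
    r <- suppressWarnings(stats::cor(A, B))
    r[!ok | !is.finite(r)] <- 0
    score <- matrix(-log10(corr_pvals(as.vector(r), neff)), n, n)
    keep <- ok & score > st
    if (d == 0L) diag(keep) <- FALSE
    if (!is.null(allowed)) keep <- keep & allowed
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx) > 0L)
      out[[d + 1L]] <- data.frame(src = idx[, 1L], dst = idx[, 2L],
                                  delay = d, effect = r[idx],
                                  score = score[idx])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(src = integer(), dst = integer(), delay = integer(),
                      effect = double(), score = double()))
  e <- do.call(rbind, out)
  e <- e[order(e$src, e$dst, e$delay), , drop = FALSE]
  rownames(e) <- NULL
  e
}

## conditioning lag of neighbour z relative to the tested edge x -> y (delay d)
cond_lag <- function(relation, d, dz) {
  switch(relation,
         parent_of_y = dz,
         parent_of_x = d + dz,
         child_of_x  = d - dz,
         child_of_y  = -dz)
}

## one conditioning variable per neighbour gene: the lag of its
## highest-scoring incident edge (paper does not restate CLINDE's pool)
neighbour_pool <- function(edges, x, y, d) {
  inc <- which(edges$src %in% c(x, y) | edges$dst %in% c(x, y))
  if (length(inc) == 0L) return(NULL)
  e <- edges[inc, , drop = FALSE]
  rel <- character(nrow(e)); z <- integer(nrow(e))
  for (k in seq_len(nrow(e))) {
    if (e$dst[k] == y && e$src[k] != x) { rel[k] <- "parent_of_y"; z[k] <- e$src[k] }
    else if (e$dst[k] == x) { rel[k] <- "parent_of_x"; z[k] <- e$src[k] }
    else if (e$src[k] == x && e$dst[k] != y) { rel[k] <- "child_of_x"; z[k] <- e$dst[k] }
    else if (e$src[k] == y) { rel[k] <- "child_of_y"; z[k] <- e$dst[k] }
  }
  ok <- nzchar(rel) & !(z %in% c(x, y))
  if (!any(ok)) return(NULL)
  e <- e[ok, , drop = FALSE]; rel <- rel[ok]; z <- z[ok]
  keep <- !duplicated(z[order(z, -e$score)])
  ord <- order(z, -e$score)[keep]
  data.frame(z = z[ord],
             lag = mapply(cond_lag, rel[ord], d, e$delay[ord]))
}

partial_corr_score <- function(data, x, y, d, zs, zlags) {
  s <- shift_and_concat(data, c(x, y, zs), c(d, 0L, zlags))
  n <- nrow(s); h <- length(zs)
  if (n < h + 3L) return(NULL)   # too few rows: test skipped
  cv <- stats::cov(s)
  pr <- tryCatch(solve(cv), error = function(e) NULL)
  if (is.null(pr)) return(NULL)
  r <- -pr[1L, 2L] / sqrt(pr[1L, 1L] * pr[2L, 2L])
  if (!is.finite(r)) return(NULL)
  df <- n - 2L - h
  if (df < 1L) return(NULL)
  tt <- abs(r) * sqrt(df / max(1 - r * r, .Machine$double.eps))
  -log10(2 * stats::pt(tt, df, lower.tail = FALSE))
}

#' Stage 2: prune indirect edges by partial correlation
#'
#' For `h = 1..n0`, every surviving edge `x -> y` is re-tested by the
#' partial correlation of `x(t-d)` and `y(t)` given each size-`h` subset of
#' its conditioning neighbours (current parents/children of `x` and `y`,
#' each lagged by its own stage-1 delay). The edge is removed as soon as one
#' conditional test is not significant; survivors keep their stage-1 delays
#' and effect signs. Tests whose aligned sample has fewer than `h + 3` rows
#' are skipped. With sufficient data only indirect effects are removed, so
#' genuine cycles survive.
#'
#' @param edges stage-1 edge data.frame.
#' @param data an [expression_segments] object.
#' @param st score threshold.
#' @param n0 maximum conditioning-set size (0 = no pruning).
#' @return pruned edge data.frame (subset of `edges`).
#' @export
stage2_prune <- function(edges, data, st = 2, n0 = 2L) {
  if (n0 < 1L || nrow(edges) == 0L) return(edges)
  for (h in seq_len(n0)) {
    keep <- rep(TRUE, nrow(edges))
    for (i in seq_len(nrow(edges))) {
      x <- edges$src[i]; y <- edges$dst[i]; d <- edges$delay[i]
      pool <- neighbour_pool_current(edges, keep, i, x, y, d)
      if (is.null(pool) || nrow(pool) < h) next
      subs <- utils::combn(nrow(pool), h)
      for (ci in seq_len(ncol(subs))) {
        sel <- subs[, ci]
        sc <- partial_corr_score(data, x, y, d, pool$z[sel], pool$lag[sel])
        if (!is.null(sc) && sc <= st) { keep[i] <- FALSE; break }
      }
    }
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) == 0L) break
  }
  rownames(edges) <- NULL
  edges
}

neighbour_pool_current <- function(edges, keep, i, x, y, d) {
  cur <- keep; cur[i] <- FALSE
  sub <- edges[cur, , drop = FALSE]
  if (nrow(sub) == 0L) return(NULL)
  neighbour_pool(sub, x, y, d)
}

#' Infer the initial delayed network among observed genes
#'
#' Runs the stage-1 delayed correlation scan, the stage-2 partial-correlation
#' pruning, and finally discards delay-0 edges (the model assumes positive
#' delays), yielding a network over the observed genes only.
#'
#' @param data an [expression_segments] object.
#' @param st score threshold on -log10(p).
#' @param max_delay maximum delay scanned (default 4).
#' @param n0 maximum conditioning-set size for pruning (default 2).
#' @param normalize centre and scale each gene to unit variance (pooled
#'   across segments) before inference; correlations are unaffected, but
#'   residual-variance semantics downstream change accordingly.
#' @return a [delayed_grn] with `n_hidden = 0`.
#' @export
infer_initial_grn <- function(data, st = 2, max_delay = 4L, n0 = 2L,
                              normalize = FALSE) {
  if (normalize) data <- normalize_segments(data)
  e1 <- stage1_scan(data, st = st, max_delay = max_delay)
  e2 <- stage2_prune(e1, data, st = st, n0 = n0)
  e2 <- e2[e2$delay >= 1L, , drop = FALSE]
  delayed_grn(e2, n_observed = n_genes(data), n_hidden = 0L,
              labels = c(attr(data, "genes")))
}

normalize_segments <- function(data) {
  genes <- attr(data, "genes")
  all <- do.call(rbind, unclass(data))
  mu <- colMeans(all)
  sd <- apply(all, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  expression_segments(lapply(unclass(data), function(s)
    sweep(sweep(s, 2L, mu), 2L, sd, "/")), genes)
}
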