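#' Re-infer the subnetwork around estimated hidden causes
#'
#' Runs the two-stage engine on the reduced variable set {candidates of
#' emitted clusters} U {their initial-network parents} U {estimated latent
#' series}, with stage 1 restricted so the only admissible link types are
#' parent -> hidden, parent -> candidate and hidden -> candidate. Links
#' between candidates and links into parents are never considered: a
#' candidate's real parent is taken to be its hidden cause, and children of
#' a hidden node are assumed unlinked to each other.
#'
#' @param clusters clusters with `|members| > 1` and latent series filled
#'   ([estimate_hidden_series()]).
#' @param initial the initial [delayed_grn] over observed genes.
#' @param data an [expression_segments] object.
#' @param st,max_delay,n0 engine parameters, as in [infer_initial_grn()].
#' @return a [delayed_grn] fragment: `n_observed` as in `initial`,
#'   `n_hidden` = number of clusters, and only the admissible links. Hidden
#'   node `n_observed + i` is the cause of cluster `i`.
#' @export
infer_hidden_subnetwork <- function(clusters, initial, data, st = 2,
                                    max_delay = 4L, n0 = 2L) {
  stopifnot(length(clusters) >= 1L)
  n <- initial$n_observed
  cand <- sort(unique(unlist(lapply(clusters, `[[`, "members"))))
  par <- initial$edges$src[initial$edges$dst %in% cand]
  par <- sort(setdiff(unique(par), cand))
  vars <- c(par, cand)
  nh <- length(clusters)
  labels <- c(attr(data, "genes")[vars], paste0("hidden", seq_len(nh)))
  segs <- unclass(data)
  local <- lapply(seq_along(segs), function(si) {
    s <- cbind(segs[[si]][, vars, drop = FALSE],
               vapply(clusters, function(cl) cl$latent[[si]],
                      numeric(nrow(segs[[si]]))))
    colnames(s) <- labels
    s
  })
  ldata <- expression_segments(local, labels)
  np <- length(par); nc <- length(cand); ntot <- np + nc + nh
  allowed <- matrix(FALSE, ntot, ntot)
  if (np > 0L) {
    allowed[seq_len(np), np + nc + seq_len(nh)] <- TRUE      # parent -> hidden
    allowed[seq_len(np), np + seq_len(nc)] <- TRUE           # parent -> candidate
  }
  allowed[np + nc + seq_len(nh), np + seq_len(nc)] <- TRUE   # hidden -> candidate
  e1 <- stage1_scan(ldata, st = st, max_delay = max_delay, allowed = allowed)
  e2 <- stage2_prune(e1, ldata, st = st, n0 = n0)
  e2 <- e2[e2$delay >= 1L, , drop = FALSE]
  ## map local indices back: observed vars -> global gene index,
  ## hidden i -> n_observed + i
  remap <- c(vars, n + seq_len(nh))
  e2$src <- remap[e2$src]; e2$dst <- remap[e2$dst]
  delayed_grn(e2, n_observed = n, n_hidden = nh,
              labels = c(attr(data, "genes"),
                         paste0("hidden", seq_len(nh))))
}

#' Merge the re-inferred hidden subnetwork into the initial network
#'
#' Removes from the initial network every link into a candidate (the
#' candidates' real parents are taken to be the hidden causes) and unions
#' the remaining links with the subnetwork fragment. Hidden nodes are
#' appended after the observed genes.
#'
#' @param initial the initial [delayed_grn] (observed genes only).
#' @param fragment the fragment from [infer_hidden_subnetwork()].
#' @param candidates gene indices whose in-links are replaced (the members
#'   of emitted clusters; candidates left in singleton clusters keep their
#'   initial in-links).
#' @return the final [delayed_grn].
#' @export
merge_networks <- function(initial, fragment, candidates) {
  kept <- initial$edges[!(initial$edges$dst %in% candidates), , drop = FALSE]
  edges <- rbind(kept, fragment$edges)
  edges <- edges[!duplicated(edges[, c("src", "dst", "delay")]), , drop = FALSE]
  delayed_grn(edges, n_observed = initial$n_observed,
              n_hidden = fragment$n_hidden, labels = fragment$labels)
}

#' Infer a delayed GRN with hidden common-cause recovery
#'
#' The full pipeline: (1) infer the initial network among observed genes by
#' the two-stage delayed conditional-independence engine; (2) regress each
#' gene on its inferred parents and flag genes whose residual variance
#' exceeds `(1 + rho) * sigma2` as candidates for a hidden parent (with
#' `sigma2` given, or estimated as the median residual variance); (3)
#' greedily cluster the candidates by maximum absolute shifted correlation
#' and reconstruct one latent series per multi-member cluster by a rank-1
#' SVD; (4) re-infer the restricted subnetwork around the latent causes and
#' merge it into the initial network. When no candidates are found, or all
#' clusters are singletons, the initial network is returned unchanged.
#'
#' @param data an [expression_segments] object (or a single time x gene
#'   matrix) holding the observed genes only.
#' @param st score threshold on -log10(p) of the correlation tests
#'   (typical values 2-4; higher is more stringent).
#' @param max_delay maximum regulatory delay considered, in time steps.
#' @param n0 maximum conditioning-set size in the pruning stage.
#' @param rho tolerance of the excess-variance test (default 0.1).
#' @param sigma2 expected variance of the error terms, or `"estimate"` to
#'   use the median per-gene residual variance.
#' @param normalize centre/scale genes to unit variance before inference.
#' @return an object of class `hcc_clinde` with components `grn` (final
#'   [delayed_grn]), `initial` (pre-merge network, the no-hidden-recovery
#'   baseline), `variances`, `sigma2`, `candidates`, `clusters` (with
#'   latent series for emitted clusters), `exit` (reason for any early
#'   exit) and `params`.
#' @examples
#' set.seed(1)
#' g <- gen_small_hidden_grn(p = 0, c = 2)
#' d <- simulate_expression(g, m = 200, sigma2 = 2, alpha = 0.5,
#'                          observed_only = TRUE)
#' fit <- hcc_clinde(d, st = 2, sigma2 = 2)
#' fit
#' evaluate_grn(g, fit$grn)$Effects
#' @export
hcc_clinde <- function(data, st = 2, max_delay = 4L, n0 = 2L, rho = 0.1,
                       sigma2 = "estimate", normalize = FALSE) {
  if (!inherits(data, "expression_segments")) data <- expression_segments(data)
  if (normalize) data <- normalize_segments(data)
  cl <- match.call()
  params <- list(st = st, max_delay = max_delay, n0 = n0, rho = rho,
                 sigma2 = sigma2, normalize = normalize)
  initial <- infer_initial_grn(data, st = st, max_delay = max_delay, n0 = n0)
  vars <- residual_variances(initial, data)
  s2 <- if (identical(sigma2, "estimate")) estimate_sigma2(vars) else sigma2
  cand <- detect_candidates(vars, s2, rho)
  res <- list(grn = initial, initial = initial, variances = vars,
              sigma2 = s2, candidates = cand$candidates, clusters = list(),
              exit = NULL, params = params, call = cl)
  class(res) <- "hcc_clinde"
  if (length(cand$candidates) == 0L) {
    res$exit <- "no candidate genes: initial network returned"
    return(res)
  }
  clusters <- cluster_candidates(cand$candidates, data, s2, rho, max_delay)
  res$clusters <- clusters
  emitted <- which(vapply(clusters, function(x) length(x$members), 0L) > 1L)
  if (length(emitted) == 0L) {
    res$exit <- "all candidate clusters are singletons: initial network returned"
    return(res)
  }
  est <- lapply(clusters[emitted], estimate_hidden_series, data = data,
                max_delay = max_delay)
  res$clusters[emitted] <- est
  fragment <- infer_hidden_subnetwork(est, initial, data, st = st,
                                      max_delay = max_delay, n0 = n0)
  members <- sort(unique(unlist(lapply(est, `[[`, "members"))))
  res$fragment <- fragment
  res$grn <- merge_networks(initial, fragment, members)
  res
}

#' @export
print.hcc_clinde <- function(x, ...) {
  cat("Delayed GRN inference with hidden common-cause recovery\n")
  cat(sprintf("  genes: %d observed; hidden causes recovered: %d\n",
              x$grn$n_observed, x$grn$n_hidden))
  cat(sprintf("  edges: %d (initial network: %d)\n",
              nrow(x$grn$edges), nrow(x$initial$edges)))
  cat(sprintf("  error variance sigma^2: %.4g (%s); candidates: %d\n",
              x$sigma2,
              if (identical(x$params$sigma2, "estimate")) "estimated" else "given",
              length(x$candidates)))
  if (!is.null(x$exit)) cat("  note:", x$exit, "\n")
  invisible(x)
}

#' @export
summary.hcc_clinde <- function(object, ...) {
  print(object)
  if (length(object$clusters) > 0L) {
    cat("  candidate clusters:\n")
    for (i in seq_along(object$clusters)) {
      cl <- object$clusters[[i]]
      cat(sprintf("    %d: members {%s}, shifts {%s}%s\n", i,
                  paste(object$grn$labels[cl$members], collapse = ", "),
                  paste(cl$shifts, collapse = ", "),
                  if (length(cl$members) > 1L) " [hidden cause emitted]" else ""))
    }
  }
  cat("Edges:\n")
  print(coef(object), row.names = FALSE)
  invisible(object)
}

#' @export
coef.hcc_clinde <- function(object, ...) {
  e <- object$grn$edges
  e$src <- object$grn$labels[e$src]
  e$dst <- object$grn$labels[e$dst]
  e
}

#' @export
residuals.hcc_clinde <- function(object, ...) {
  ## per-gene residual variances given the initial network's parents --
  ## the quantity the candidate detection thresholds
  object$variances
}

#' @export
plot.hcc_clinde <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting needs the 'igraph' package")
  g <- x$grn
  ig <- igraph::make_empty_graph(n = g$n_observed + g$n_hidden)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$labels)
  if (nrow(g$edges) > 0L)
    ig <- igraph::add_edges(ig, rbind(g$edges$src, g$edges$dst))
  cols <- c(rep("lightsteelblue", g$n_observed), rep("salmon", g$n_hidden))
  ecol <- if (nrow(g$edges) > 0L)
    ifelse(g$edges$effect >= 0, "darkgreen", "firebrick") else NULL
  igraph::plot.igraph(ig, vertex.color = cols, edge.color = ecol,
                      edge.label = if (nrow(g$edges) > 0L) g$edges$delay,
                      ...)
  invisible(x)
}
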