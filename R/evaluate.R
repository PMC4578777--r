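## Scoring of predicted networks against ground truth. Because a hidden
## node is never observed, its links are only identified up to a joint
## transformation: flipping the sign of the node flips the signs of all its
## links, and delaying the node by d adds d to its parent-link delays while
## subtracting d from its child-link delays. Predicted hidden nodes are
## therefore aligned to true hidden nodes over these equivalence classes
## before counting.

## collapse multi-delay duplicates: one edge per ordered pair, keeping the
## highest score (ties: smallest delay)
collapse_pairs <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  sc <- ifelse(is.na(edges$score), Inf, edges$score)
  o <- order(edges$src, edges$dst, -sc, edges$delay)
  e <- edges[o, , drop = FALSE]
  e[!duplicated(e[, c("src", "dst")]), , drop = FALSE]
}

prf <- function(tp, fp, fn) {
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (tp > 0) 2 * r * p / (r + p) else 0
  c(TP = tp, FP = fp, FN = fn, Recall = r, Precision = p, F = f)
}

#' Count edge matches between truth and prediction for one aspect
#'
#' `Links`: a predicted edge is correct iff the ordered gene pair matches a
#' true edge. `Delays`: additionally the delay must be equal. `Effects`:
#' additionally the sign of the effect must be equal. Duplicate predictions
#' for the same pair are collapsed to one. Hidden nodes, if any, must
#' already be aligned to the truth's labelling.
#'
#' @param truth,pred [delayed_grn] objects on the same node set.
#' @param aspect one of `"Links"`, `"Delays"`, `"Effects"`.
#' @return named vector `TP`, `FP`, `FN`, `Recall`, `Precision`, `F`.
#' @export
match_edges <- function(truth, pred, aspect = c("Links", "Delays", "Effects")) {
  aspect <- match.arg(aspect)
  te <- collapse_pairs(truth$edges)
  pe <- collapse_pairs(pred$edges)
  tk <- paste(te$src, te$dst)
  pk <- paste(pe$src, pe$dst)
  hit <- match(pk, tk)
  link_tp <- !is.na(hit)
  ok <- switch(aspect,
               Links = link_tp,
               Delays = link_tp & pe$delay == te$delay[hit],
               Effects = link_tp & sign(pe$effect) == sign(te$effect[hit]))
  ok[is.na(ok)] <- FALSE
  tp <- sum(ok)
  prf(tp, nrow(pe) - tp, nrow(te) - tp)
}

## links of hidden node h to/from observed genes, as a normal form:
## (other endpoint, direction, delay, sign)
hidden_links <- function(grn, h) {
  e <- grn$edges
  obs <- function(i) i <= grn$n_observed
  par <- e[e$dst == h & obs(e$src), , drop = FALSE]
  kid <- e[e$src == h & obs(e$dst), , drop = FALSE]
  list(parents = data.frame(gene = par$src, delay = par$delay,
                            sgn = sign(par$effect)),
       children = data.frame(gene = kid$dst, delay = kid$delay,
                             sgn = sign(kid$effect)))
}

align_score <- function(plinks, tlinks, d, flip) {
  s <- 0L
  f <- if (flip) -1 else 1
  pm <- match(plinks$parents$gene, tlinks$parents$gene)
  cm <- match(plinks$children$gene, tlinks$children$gene)
  links <- sum(!is.na(pm)) + sum(!is.na(cm))
  delays <- sum(plinks$parents$delay + d ==
                  tlinks$parents$delay[pm], na.rm = TRUE) +
    sum(plinks$children$delay - d ==
          tlinks$children$delay[cm], na.rm = TRUE)
  signs <- sum(f * plinks$parents$sgn == tlinks$parents$sgn[pm], na.rm = TRUE) +
    sum(f * plinks$children$sgn == tlinks$children$sgn[cm], na.rm = TRUE)
  c(links = links, delays = delays, signs = signs)
}

#' Align predicted hidden nodes to true hidden nodes
#'
#' Each predicted hidden node is aligned independently: over every true
#' hidden node, every delay shift `d` (parent-link delays increased by `d`,
#' child-link delays decreased by `d`, all shifted delays constrained to
#' `[1, 2 * max_delay]`) and both sign flips, the alignment quality is the
#' number of matched links plus matched shifted delays against the true
#' node's links to/from observed genes. The best is chosen; ties go to the
#' most matched signs, then the lowest true node index, the smallest
#' absolute shift (negative first), and no-flip. A predicted hidden node
#' with no feasible alignment stays unmatched and all its links count as
#' false positives.
#'
#' @param truth,pred [delayed_grn] objects with the same observed genes.
#' @param max_delay maximum delay of the inference (bounds the shifts).
#' @return data.frame with one row per predicted hidden node: `pred`
#'   (node index in `pred`), `true` (matched node index in `truth` or NA),
#'   `shift`, `flip`.
#' @export
align_hidden <- function(truth, pred, max_delay = 4L) {
  no <- pred$n_observed
  ph <- no + seq_len(pred$n_hidden)
  th <- truth$n_observed + seq_len(truth$n_hidden)
  out <- data.frame(pred = ph, true = rep(NA_integer_, length(ph)),
                    shift = rep(0L, length(ph)),
                    flip = rep(FALSE, length(ph)))
  if (length(ph) == 0L || length(th) == 0L) return(out)
  dmax <- 2L * max_delay
  for (i in seq_along(ph)) {
    pl <- hidden_links(pred, ph[i])
    if (nrow(pl$parents) + nrow(pl$children) == 0L) next
    best <- NULL
    for (tj in seq_along(th)) {
      tl <- hidden_links(truth, th[tj])
      for (d in seq.int(-dmax, dmax)) {
        pd <- pl$parents$delay + d
        cd <- pl$children$delay - d
        if (any(pd < 1L | pd > dmax) || any(cd < 1L | cd > dmax)) next
        for (flip in c(FALSE, TRUE)) {
          sc <- align_score(pl, tl, d, flip)
          key <- c(sc[["links"]] + sc[["delays"]], sc[["signs"]],
                   -tj, -abs(d), -(d < 0), -flip)
          if (is.null(best) || lex_greater(key, best$key)) {
            best <- list(key = key, tj = tj, d = d, flip = flip,
                         quality = sc[["links"]] + sc[["delays"]])
          }
        }
      }
    }
    if (!is.null(best)) {
      out$true[i] <- th[best$tj]
      out$shift[i] <- best$d
      out$flip[i] <- best$flip
    }
  }
  out
}

lex_greater <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

## rewrite predicted hidden links per the alignment: relabel nodes into the
## truth's hidden index space, shift delays, flip signs
apply_alignment <- function(truth, pred, alignment) {
  e <- pred$edges
  no <- pred$n_observed
  n_extra <- 0L
  remap <- integer(pred$n_hidden)
  for (i in seq_len(nrow(alignment))) {
    ph <- alignment$pred[i]
    if (!is.na(alignment$true[i])) {
      newid <- alignment$true[i]
      d <- alignment$shift[i]; f <- alignment$flip[i]
      par <- e$dst == ph; kid <- e$src == ph
      e$delay[par] <- e$delay[par] + d
      e$delay[kid] <- e$delay[kid] - d
      if (f) e$effect[par | kid] <- -e$effect[par | kid]
    } else {
      n_extra <- n_extra + 1L
      newid <- no + truth$n_hidden + n_extra
    }
    remap[ph - no] <- newid
  }
  hid <- e$src > no
  e$src[hid] <- remap[e$src[hid] - no]
  hid <- e$dst > no
  e$dst[hid] <- remap[e$dst[hid] - no]
  delayed_grn(e[!duplicated(e[, c("src", "dst", "delay")]), , drop = FALSE],
              n_observed = no, n_hidden = truth$n_hidden + n_extra,
              check = FALSE)
}

#' Evaluate a predicted network against the truth
#'
#' Aligns the predicted hidden nodes ([align_hidden()]), rewrites their
#' links accordingly, then scores the three aspects `Links`, `Delays` and
#' `Effects` ([match_edges()]). F is defined as 0 when TP = 0.
#'
#' @param truth ground-truth [delayed_grn] (hidden nodes labelled).
#' @param pred predicted [delayed_grn] over the same observed genes.
#' @param max_delay maximum delay of the inference.
#' @return object of class `grn_eval`: list with one `TP/FP/FN/Recall/
#'   Precision/F` vector per aspect and the `alignment` table.
#' @export
evaluate_grn <- function(truth, pred, max_delay = 4L) {
  stopifnot(truth$n_observed == pred$n_observed)
  al <- align_hidden(truth, pred, max_delay)
  pred2 <- if (pred$n_hidden > 0L) apply_alignment(truth, pred, al) else pred
  out <- lapply(c(Links = "Links", Delays = "Delays", Effects = "Effects"),
                function(a) match_edges(truth, pred2, a))
  out$alignment <- al
  class(out) <- "grn_eval"
  out
}

#' @export
print.grn_eval <- function(x, ...) {
  tab <- do.call(rbind, x[c("Links", "Delays", "Effects")])
  print(round(tab, 4))
  invisible(x)
}
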