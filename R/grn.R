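#' Delayed gene regulatory network
#'
#' A signed, delay-labelled directed (multi)graph over `n_observed` observed
#' genes and `n_hidden` hidden nodes. Nodes are indexed 1..n_observed for the
#' observed genes and n_observed+1 .. n_observed+n_hidden for hidden nodes.
#' Edges carry an integer delay (in time steps), a signed real effect
#' (positive = activation, negative = repression) and, for inferred networks,
#' a score (-log10 p-value of the test that admitted the edge; NA for ground
#' truth). Several edges between the same ordered pair are representable when
#' they have distinct delays.
#'
#' @param edges data.frame with columns `src`, `dst`, `delay`, `effect` and
#'   optionally `score`; zero-row for an empty network.
#' @param n_observed number of observed genes.
#' @param n_hidden number of hidden nodes (default 0).
#' @param labels node labels; defaults to `g1..gn` for observed and
#'   `hidden1..` for hidden nodes. Hidden labels carry the reserved
#'   `"hidden"` prefix used by the file format.
#' @param check validate structural invariants on the final network (delays
#'   >= 1, finite non-zero effects, indices in range).
#' @return an object of class `delayed_grn`.
#' @seealso [validate_hidden_structure()] for the hidden-node structural
#'   assumptions checked on ground-truth networks.
#' @export
delayed_grn <- function(edges = NULL, n_observed, n_hidden = 0L,
                        labels = NULL, check = TRUE) {
  n_observed <- as.integer(n_observed); n_hidden <- as.integer(n_hidden)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(src = integer(), dst = integer(), delay = integer(),
                        effect = double(), score = double())
  } else {
    edges <- as.data.frame(edges)
    if (is.null(edges$score)) edges$score <- NA_real_
    edges <- edges[, c("src", "dst", "delay", "effect", "score")]
    edges$src <- as.integer(edges$src)
    edges$dst <- as.integer(edges$dst)
    edges$delay <- as.integer(edges$delay)
  }
  ntot <- n_observed + n_hidden
  if (is.null(labels))
    labels <- c(paste0("g", seq_len(n_observed)),
                if (n_hidden > 0L) paste0("hidden", seq_len(n_hidden)))
  if (check && nrow(edges) > 0L) {
    if (any(edges$src < 1L | edges$src > ntot | edges$dst < 1L | edges$dst > ntot))
      stop("edge endpoints out of range 1..", ntot)
    if (any(edges$delay < 1L))
      stop("all delays must be >= 1 in a final network")
    if (any(!is.finite(edges$effect) | edges$effect == 0))
      stop("edge effects must be finite and non-zero")
    if (anyDuplicated(edges[, c("src", "dst", "delay")]))
      stop("duplicate (src, dst, delay) edge")
  }
  rownames(edges) <- NULL
  structure(list(n_observed = n_observed, n_hidden = n_hidden,
                 edges = edges, labels = labels),
            class = "delayed_grn")
}

#' @export
print.delayed_grn <- function(x, ...) {
  cat("Delayed GRN:", x$n_observed, "observed gene(s),",
      x$n_hidden, "hidden node(s),", nrow(x$edges), "edge(s)\n")
  if (nrow(x$edges) > 0L) {
    e <- x$edges
    e$src <- x$labels[e$src]; e$dst <- x$labels[e$dst]
    print(utils::head(e, 20L), row.names = FALSE)
    if (nrow(e) > 20L) cat("  ... and", nrow(e) - 20L, "more\n")
  }
  invisible(x)
}

is_hidden_node <- function(grn, idx) idx > grn$n_observed

#' Write a delayed GRN to a TSV edge list
#'
#' One edge per line with columns `src dst delay effect score`, nodes
#' referred to by label; comment lines start with `#`. Hidden nodes are
#' recognised on re-reading by their reserved `"hidden"` label prefix.
#'
#' @param grn a [delayed_grn].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# delayed GRN: %d observed, %d hidden",
                     grn$n_observed, grn$n_hidden), con)
  writeLines(paste("# nodes:", paste(grn$labels, collapse = "\t")), con)
  writeLines(paste("src", "dst", "delay", "effect", "score", sep = "\t"), con)
  if (nrow(grn$edges) > 0L) {
    e <- grn$edges
    writeLines(paste(grn$labels[e$src], grn$labels[e$dst], e$delay,
                     formatC(e$effect, digits = 17, format = "g"),
                     ifelse(is.na(e$score), "NA",
                            formatC(e$score, digits = 17, format = "g")),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a delayed GRN from a TSV edge list
#'
#' Inverse of [write_grn()]; the round trip is lossless for delays, effects
#' and scores to full printed precision. Hidden nodes are ordered after
#' observed nodes. Delay-0 lines are rejected, as final networks only carry
#' positive delays.
#'
#' @param path file written by [write_grn()].
#' @return a [delayed_grn].
#' @export
read_grn <- function(path) {
  raw <- readLines(path)
  node_line <- grep("^# nodes:", raw, value = TRUE)
  lines <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (length(lines) == 0L) stop("no header line in '", path, "'")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:4], c("src", "dst", "delay", "effect")))
    stop("unrecognised GRN header in '", path, "'")
  known <- if (length(node_line) > 0L)
    strsplit(sub("^# nodes: ", "", node_line[[1L]]), "\t", fixed = TRUE)[[1L]]
  else character()
  body <- lines[-1L]
  if (length(body) == 0L) {
    hid <- grepl("^hidden", known)
    return(delayed_grn(NULL, n_observed = sum(!hid), n_hidden = sum(hid),
                       labels = if (length(known)) known))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad) > 0L)
    stop("malformed GRN line ", bad[1L] + 2L, " in '", path, "'")
  src_lab <- vapply(parts, `[[`, "", 1L)
  dst_lab <- vapply(parts, `[[`, "", 2L)
  labs <- union(known, unique(c(src_lab, dst_lab)))
  hid <- grepl("^hidden", labs)
  labels <- if (length(known)) labs else c(sort(labs[!hid]), sort(labs[hid]))
  hid <- grepl("^hidden", labels)
  idx <- function(v) match(v, labels)
  delay <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  effect <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  bad <- which(is.na(delay) | is.na(effect))
  if (length(bad) > 0L)
    stop("non-numeric delay/effect on GRN line ", bad[1L] + 2L, " in '", path, "'")
  if (any(delay < 1L))
    stop("delay 0 edge on line ", which(delay < 1L)[1L] + 2L,
         ": final networks carry positive delays only")
  delayed_grn(data.frame(src = idx(src_lab), dst = idx(dst_lab),
                         delay = delay, effect = effect, score = score),
              n_observed = sum(!hid), n_hidden = sum(hid), labels = labels)
}

grn_parents <- function(grn, j) grn$edges[grn$edges$dst == j, , drop = FALSE]
grn_children <- function(grn, j) grn$edges[grn$edges$src == j, , drop = FALSE]

#' Check the hidden-node structural assumptions of a network
#'
#' The model restricts how hidden nodes may be wired: no hidden-hidden
#' edges; every hidden node has at least two observed children; a gene with
#' a hidden parent has no other parent; children of a hidden node are not
#' linked to each other; and 0 <= n_hidden < n_observed. These hold for all
#' ground-truth networks produced by the generators; inferred networks are
#' not required to satisfy them.
#'
#' @param grn a [delayed_grn].
#' @return character vector of violation messages; empty when all
#'   assumptions hold. Never throws.
#' @export
validate_hidden_structure <- function(grn) {
  v <- character()
  e <- grn$edges
  no <- grn$n_observed; nh <- grn$n_hidden
  if (!(nh >= 0L && nh < no))
    v <- c(v, sprintf("need 0 <= n_hidden (%d) < n_observed (%d)", nh, no))
  hid <- function(i) i > no
  if (any(hid(e$src) & hid(e$dst)))
    v <- c(v, "edge between two hidden nodes")
  for (h in seq_len(nh) + no) {
    kids <- e$dst[e$src == h]
    if (sum(!hid(kids)) < 2L)
      v <- c(v, sprintf("hidden node %d has %d observed children (need >= 2)",
                        h, sum(!hid(kids))))
    kids <- kids[!hid(kids)]
    within <- e$src %in% kids & e$dst %in% kids
    if (any(within))
      v <- c(v, sprintf("children of hidden node %d are linked to each other", h))
  }
  hidden_children <- unique(e$dst[hid(e$src)])
  for (j in hidden_children) {
    other <- e$src[e$dst == j & !hid(e$src)]
    nh_par <- unique(e$src[e$dst == j & hid(e$src)])
    if (length(other) > 0L || length(nh_par) > 1L)
      v <- c(v, sprintf("gene %d has a hidden parent and other parent(s)", j))
  }
  v
}
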