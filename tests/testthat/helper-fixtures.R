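# in-code fixtures shared across test files

# hand-built 6-gene acyclic network with delays (no hidden nodes)
chain6_grn <- function() {
  delayed_grn(data.frame(src = c(1L, 2L, 4L, 5L),
                         dst = c(2L, 3L, 5L, 6L),
                         delay = c(1L, 2L, 1L, 3L),
                         effect = c(0.8, -0.9, 1.0, 0.7)),
              n_observed = 6L, n_hidden = 0L)
}

# the hidden-node motif: X, Y independent; H = X + Y + e_h (hidden);
# Z = c * H + e_z; W = d * H + e_w; all link delays 1
motif_grn <- function(c_coef = 1, d_coef = 1) {
  # nodes: 1 = X, 2 = Y, 3 = Z, 4 = W, 5 = H (hidden)
  delayed_grn(data.frame(src = c(1L, 2L, 5L, 5L),
                         dst = c(5L, 5L, 3L, 4L),
                         delay = c(1L, 1L, 1L, 1L),
                         effect = c(1, 1, c_coef, d_coef)),
              n_observed = 4L, n_hidden = 1L)
}

edge_key <- function(edges) paste(edges$src, edges$dst, edges$delay)
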