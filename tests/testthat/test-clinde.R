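test_that("delayed correlation test finds the true lag with the right sign", {
  set.seed(42)
  m <- 200L
  x <- rnorm(m + 2)
  y <- 0.8 * x[1:m] + rnorm(m, sd = 0.05)   # y(t) = 0.8 x(t-2) + tiny noise
  data <- expression_segments(cbind(x = x[3:(m + 2)], y = y))
  res <- delayed_corr_test(1L, 2L, 2L, data, st = 2)
  expect_true(res$significant)
  expect_gt(res$effect, 0)
  # oracle: direct correlation at every lag on the same shifted sample
  for (d in c(0L, 1L, 3L, 4L)) {
    s <- shift_and_concat(data, c(1L, 2L), c(d, 0L))
    r_direct <- cor(s[, 1], s[, 2])
    other <- delayed_corr_test(1L, 2L, d, data, st = 2)
    expect_equal(other$effect, r_direct)
    expect_lt(other$score, res$score)
  }
})

test_that("perfect anticorrelation at lag 1 is detected with negative sign", {
  x <- as.numeric(1:50 %% 7) + sin(1:50)
  y <- c(0, -x[1:49])
  data <- expression_segments(cbind(x, y))
  res <- delayed_corr_test(1L, 2L, 1L, data, st = 2)
  expect_true(res$significant)
  expect_equal(res$effect, -1, tolerance = 1e-10)

  # degenerate variance: not significant, score 0
  const <- expression_segments(cbind(rep(1, 50), rnorm(50)))
  res <- delayed_corr_test(1L, 2L, 1L, const, st = 2)
  expect_false(res$significant)
  expect_equal(res$score, 0)
})

test_that("type-I rate of the delayed test matches the score cutoff", {
  set.seed(99)
  m <- 200L; trials <- 2000L
  hits <- 0L
  for (i in seq_len(trials)) {
    x <- rnorm(m); y <- rnorm(m)
    r <- cor(x, y)
    p <- 2 * pt(abs(r) * sqrt((m - 2) / (1 - r^2)), m - 2, lower.tail = FALSE)
    if (-log10(p) > 2) hits <- hits + 1L
  }
  # st = 2 corresponds to p < 0.01
  expect_gt(hits / trials, 0.005)
  expect_lt(hits / trials, 0.015)
})

test_that("stage-1 false-edge count on independent noise matches expectation", {
  n <- 10L; m <- 200L; st <- 2
  counts <- vapply(1:8, function(s) {
    set.seed(100 + s)
    data <- expression_segments(matrix(rnorm(m * n), m, n))
    e <- stage1_scan(data, st = st, max_delay = 4L)
    sum(e$src != e$dst)
  }, 0L)
  expected <- n * (n - 1) * 5 * 10^(-st)   # 4.5 per replicate
  expect_gt(mean(counts), expected / 3)
  expect_lt(mean(counts), expected * 3)
})

test_that("pruning removes the indirect chain edge and keeps direct edges", {
  set.seed(5)
  m <- 500L
  x <- rnorm(m + 2)
  z <- 0.9 * c(0, x[1:(m + 1)]) + rnorm(m + 2, sd = 0.3)
  y <- 0.9 * c(0, z[1:(m + 1)]) + rnorm(m + 2, sd = 0.3)
  data <- expression_segments(cbind(x = x[3:(m + 2)], z = z[3:(m + 2)],
                                    y = y[3:(m + 2)]))
  e1 <- stage1_scan(data, st = 2, max_delay = 4L)
  # the spurious lag-2 x -> y association is present after stage 1
  expect_true(any(e1$src == 1 & e1$dst == 3 & e1$delay == 2))
  # oracle: partial correlation of x(t-2), y(t) given z(t-1), via residuals
  s <- shift_and_concat(data, c(1L, 3L, 2L), c(2L, 0L, 1L))
  rx <- residuals(lm(s[, 1] ~ s[, 3]))
  ry <- residuals(lm(s[, 2] ~ s[, 3]))
  expect_lt(abs(cor(rx, ry)), 0.1)
  e2 <- stage2_prune(e1, data, st = 2, n0 = 2L)
  expect_false(any(e2$src == 1 & e2$dst == 3))
  expect_true(any(e2$src == 1 & e2$dst == 2 & e2$delay == 1))
  expect_true(any(e2$src == 2 & e2$dst == 3 & e2$delay == 1))
})

test_that("n0 = 0 leaves the stage-1 edge set untouched", {
  set.seed(6)
  data <- expression_segments(matrix(rnorm(100 * 4), 100, 4))
  e1 <- stage1_scan(data, st = 2)
  expect_identical(stage2_prune(e1, data, st = 2, n0 = 0L), e1)
})

test_that("a genuine delayed 2-cycle survives pruning", {
  set.seed(8)
  g <- delayed_grn(data.frame(src = c(1L, 2L), dst = c(2L, 1L),
                              delay = c(1L, 2L), effect = c(0.8, -0.8)),
                   n_observed = 2L, n_hidden = 0L)
  data <- simulate_expression(g, 400L, sigma2 = 0.2, alpha = 1)
  grn <- infer_initial_grn(data, st = 2)
  expect_true(any(grn$edges$src == 1 & grn$edges$dst == 2 & grn$edges$delay == 1))
  expect_true(any(grn$edges$src == 2 & grn$edges$dst == 1 & grn$edges$delay == 2))
})

test_that("raising the score threshold never adds edges", {
  set.seed(9)
  g <- chain6_grn()
  data <- simulate_expression(g, 150L, sigma2 = 1, alpha = 1)
  e2 <- stage1_scan(data, st = 2)
  e3 <- stage1_scan(data, st = 3)
  e4 <- stage1_scan(data, st = 4)
  expect_true(all(edge_key(e3) %in% edge_key(e2)))
  expect_true(all(edge_key(e4) %in% edge_key(e3)))
  g2 <- infer_initial_grn(data, st = 2)
  g3 <- infer_initial_grn(data, st = 3)
  expect_true(all(edge_key(g3$edges) %in% edge_key(g2$edges)))
})

test_that("the engine recovers a small observed network exactly", {
  set.seed(10)
  g <- chain6_grn()
  data <- simulate_expression(g, 200L, sigma2 = 0.1, alpha = 1)
  fit <- infer_initial_grn(data, st = 2)
  ev <- evaluate_grn(g, fit)
  expect_equal(ev$Links[["F"]], 1)
  expect_equal(ev$Delays[["F"]], 1)
  expect_equal(ev$Effects[["F"]], 1)
  expect_equal(fit$n_hidden, 0L)
  expect_true(all(fit$edges$delay >= 1L))
})

test_that("constant data yields an empty network", {
  data <- expression_segments(matrix(1, 50, 3))
  fit <- infer_initial_grn(data, st = 2)
  expect_equal(nrow(fit$edges), 0L)
})

test_that("splitting one segment only loses rows at the boundary", {
  set.seed(11)
  x <- matrix(rnorm(100 * 3), 100, 3)
  whole <- expression_segments(x)
  split2 <- expression_segments(list(x[1:60, ], x[61:100, ]))
  # at lag 0 the concatenated sample is identical, so scores match exactly
  s_w <- shift_and_concat(whole, c(1L, 2L), c(0L, 0L))
  s_s <- shift_and_concat(split2, c(1L, 2L), c(0L, 0L))
  expect_equal(s_w, s_s)
  # at lag 2 the split loses exactly 2 rows at the boundary
  s_w <- shift_and_concat(whole, c(1L, 2L), c(2L, 0L))
  s_s <- shift_and_concat(split2, c(1L, 2L), c(2L, 0L))
  expect_equal(nrow(s_w) - nrow(s_s), 2L)
  expect_true(all(apply(s_s, 1, paste, collapse = ",") %in%
                    apply(s_w, 1, paste, collapse = ",")))
})

test_that("conditioning reduces surviving edges on independent noise", {
  counts <- sapply(1:5, function(s) {
    set.seed(200 + s)
    data <- expression_segments(matrix(rnorm(150 * 8), 150, 8))
    e1 <- stage1_scan(data, st = 1.3)
    c(n0_0 = nrow(e1), n0_2 = nrow(stage2_prune(e1, data, st = 1.3, n0 = 2L)))
  })
  expect_true(all(counts["n0_2", ] <= counts["n0_0", ]))
  expect_lt(sum(counts["n0_2", ]), sum(counts["n0_0", ]))
})
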