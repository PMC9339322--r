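fake_posteriors <- function(tree, pp) {
  ntip <- length(tree$tip.label)
  lab <- ifelse(tree$edge[, 2] <= ntip, tree$tip.label[pmin(tree$edge[, 2],
                                                            ntip)],
                paste0("node", tree$edge[, 2]))
  out <- data.frame(edge = seq_along(pp), parent = tree$edge[, 1],
                    child = tree$edge[, 2], child_label = lab, pp = pp)
  attr(out, "tree") <- tree
  class(out) <- c("branch_posteriors", "data.frame")
  out
}

test_that("jump calls use a strict threshold and preorder jump indices", {
  tr <- read_newick_string("((A:1,B:1):1,C:2);")
  post <- fake_posteriors(tr, c(0.97, 0.4, 0.2, 0.1))
  calls <- call_jumps(post, 0.75)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$edge, 1L)
  expect_equal(calls$jump_index, 1L)
  expect_equal(nrow(call_jumps(post, 1)), 0L)       # boundary: nothing > 1
  at <- call_jumps(post, 0.97)
  expect_equal(nrow(at), 0L)                        # strictly greater than
  set.seed(3)
  for (rep in 1:10) {
    pp <- runif(nrow(tr$edge))
    th <- runif(1)
    expect_setequal(call_jumps(fake_posteriors(tr, pp), th)$edge,
                    which(pp > th))
  }
})

test_that("noise-free planted shifts are recovered exactly", {
  tr <- simulate_yule_tree(40, 1, seed = 5, jitter_sd = 0.2)
  x <- make_traits(tr, rep(50, 40))
  sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
    length(gcjumps:::tips_under_node(tr, tr$edge[e, 2]))
  }, integer(1))
  target <- which(sizes >= 5 & sizes <= 15)[1]
  under <- tr$tip.label[gcjumps:::tips_under_node(tr, tr$edge[target, 2])]
  x[under] <- x[under] + 7
  call <- data.frame(jump_index = 1L, edge = target, pp = 0.99)
  mag <- jump_magnitude(tr, x, call)
  expect_equal(mag$delta_gc, 7, tolerance = 1e-9)
  expect_equal(mag$direction, "up")
})

test_that("nested-jump exclusion removes contamination from inner jumps", {
  # fixed topology: outer clade (A,B,C,D), inner jump on the (A,B) cherry
  tr <- read_newick_string(
    "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,(F:1,G:1):1):1);")
  ntip <- 7L
  nodes <- list(outer = 9L, inner = 10L)  # ABCD ancestor; AB ancestor
  e_outer <- which(tr$edge[, 2] == nodes$outer)
  e_inner <- which(tr$edge[, 2] == nodes$inner)
  x <- c(A = 50, B = 50, C = 50, D = 50, E = 50, F = 50, G = 50)
  x[c("A", "B", "C", "D")] <- x[c("A", "B", "C", "D")] + 10  # outer jump
  x[c("A", "B")] <- x[c("A", "B")] - 20                      # nested jump
  calls <- data.frame(jump_index = 1:2, edge = c(e_outer, e_inner),
                      pp = c(0.99, 0.99))
  clean <- jump_magnitude(tr, x, calls[1, ], calls)
  expect_equal(clean$delta_gc, 10, tolerance = 1e-9)
  expect_equal(clean$n_affected_tips, 2L)  # A, B excluded
  # without exclusion the nested tips drag the affected median to 50
  contaminated <- jump_magnitude(tr, x, calls[1, ], calls[1, ])
  expect_equal(contaminated$delta_gc, 0)  # median(40,40,60,60) - 50
  inner <- jump_magnitude(tr, x, calls[2, ], calls)
  expect_equal(inner$delta_gc, -20, tolerance = 1e-9)
})

test_that("degenerate magnitude cases error or flag rather than guess", {
  tr <- read_newick_string("((A:1,B:1):1,C:2);")
  x <- c(A = 50, B = 50, C = 50)
  call <- data.frame(jump_index = 1L, edge = 1L, pp = 0.9)
  expect_equal(jump_magnitude(tr, x, call)$delta_gc, 0)
  expect_equal(jump_magnitude(tr, x, call)$direction, "none")
  poly <- read_newick_string("(A:1,B:1,C:1);")
  pcall <- data.frame(jump_index = 1L, edge = 1L, pp = 0.9)
  expect_error(jump_magnitude(poly, x, pcall), "not binary")
  # sister entirely excluded by a nested call -> flagged, not dropped
  cherry_calls <- data.frame(jump_index = 1:2, edge = c(2L, 3L),
                             pp = c(0.9, 0.9))
  tr2 <- read_newick_string("((A:1,B:1):1,C:2);")
  mags <- jump_magnitudes(tr2, x, cherry_calls)
  expect_equal(nrow(mags), 2L)
  expect_true(all(!mags$available))
})

test_that("direction summaries tally signs and medians exactly", {
  s <- direction_summary(c(3, -5, -2))
  expect_equal(s[c("n_down", "n_up")], list(n_down = 2L, n_up = 1L))
  expect_equal(s$median_abs_down, 3.5)
  expect_equal(s$median_abs_up, 3)
  all_up <- direction_summary(c(1, 2))
  expect_equal(all_up$n_down, 0L)
  expect_true(is.na(all_up$median_abs_down))
  set.seed(13)
  for (rep in 1:10) {
    d <- round(rnorm(20, 0, 5), 2)
    s <- direction_summary(d)
    expect_equal(s$n_down, sum(sort(d) < 0))
    expect_equal(s$n_up, sum(sort(d) > 0))
    if (s$n_down) expect_equal(s$median_abs_down, median(sort(abs(d[d < 0]))))
  }
})

test_that("depth randomisation is calibrated under its own null", {
  tr <- simulate_yule_tree(60, 1, seed = 17, jitter_sd = 0.3)
  set.seed(18)
  ps <- vapply(1:120, function(k) {
    m <- 8
    edges <- sample.int(nrow(tr$edge), m, replace = TRUE,
                        prob = tr$edge.length)
    calls <- data.frame(jump_index = seq_len(m), edge = edges, pp = 1)
    depth_randomization_test(tr, calls, n_random = 199, seed = k)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("depth bias towards one deep branch is detected", {
  # caterpillar: deep basal branch vs shallow tip branches
  tr <- ape::stree(12, "left")
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  deepest <- which.max(node_depths(tr)[tr$edge[, 1]])
  hits <- 0
  for (k in 1:10) {
    calls <- data.frame(jump_index = 1:6, edge = rep(deepest, 6), pp = 1)
    p <- depth_randomization_test(tr, calls, n_random = 499, seed = k)$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a single call on a two-branch cherry is never called non-random", {
  tr <- read_newick_string("(A:1,B:1);")
  calls <- data.frame(jump_index = 1L, edge = 1L, pp = 1)
  expect_equal(depth_randomization_test(tr, calls, seed = 1)$p_value, 1)
})
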