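test_that("minimal Newick trees parse with topology and lengths intact", {
  tr <- read_newick_string("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)
  root_children <- tr$edge[tr$edge[, 1] == length(tr$tip.label) + 1L, 2]
  expect_length(root_children, 2L)
})

test_that("malformed or length-free Newick is rejected with a located error", {
  expect_error(read_newick_string("((A:1,B:1)"), "byte")
  expect_error(read_newick_string("((A:1,B:1):1,C:2)"), "byte")
  expect_error(read_newick_string("(A,B);"), "branch length")
  expect_error(read_newick_string("((A:1,A:2):1,C:2);"), "duplicate")
})

test_that("read/write round-trip is the identity on topology, labels, lengths", {
  for (seed in 1:5) {
    tr <- simulate_yule_tree(20, 1, seed = seed, jitter_sd = 0.4)
    back <- read_newick_string(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-8))
  }
})

test_that("branch annotations are written in the documented dialect and recovered", {
  tr <- read_newick_string("(A:1,B:1);")
  txt <- write_newick(tr, branch_annotations = list("1" = c(pp = "0.97")))
  expect_match(txt, "[&pp=0.97]", fixed = TRUE)
  back <- read_newick_string(txt)
  ann <- attr(back, "branch_annotations")
  expect_length(ann, 1L)
  e <- as.integer(names(ann))
  expect_equal(back$tip.label[back$edge[e, 2]], "A")
  expect_equal(unname(ann[[1]]["pp"]), "0.97")
  expect_error(write_newick(tr, branch_annotations = list("9" = c(pp = "1"))),
               "not a branch")
})

test_that("annotation round-trip through a file preserves the tree", {
  tr <- simulate_yule_tree(12, 1, seed = 7, jitter_sd = 0.2)
  pp <- round(seq(0, 1, length.out = nrow(tr$edge)), 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path, branch_annotations = stats::setNames(
    as.list(format(pp)), seq_along(pp)))
  back <- read_newick(path)
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                   tolerance = 1e-6))
  expect_length(attr(back, "branch_annotations"), nrow(tr$edge))
})

test_that("subsampling collapses young clades to their alphabetically first tip", {
  tr <- read_newick_string("((A:0.001,B:0.002):0.5,C:0.6);")
  out <- subsample_tree(tr, 0.01)
  expect_setequal(out$tip.label, c("A", "C"))
  # pruned branch lengths run through the removed node
  expect_equal(sum(out$edge.length), 0.001 + 0.5 + 0.6)
})

test_that("subsampling is a no-op below every cherry height and idempotent", {
  tr <- simulate_yule_tree(40, 1, seed = 3, jitter_sd = 0.2)
  expect_identical(subsample_tree(tr, 1e-9)$tip.label, tr$tip.label)
  thr <- 0.3
  once <- subsample_tree(tr, thr)
  twice <- subsample_tree(once, thr)
  expect_identical(sort(once$tip.label), sort(twice$tip.label))
})

test_that("after subsampling no surviving young clade keeps more than one tip", {
  for (seed in c(2, 9)) {
    tr <- simulate_yule_tree(100, 3, seed = seed, jitter_sd = 0.5)
    thr <- 0.05
    out <- subsample_tree(tr, thr)
    h <- gcjumps:::clade_heights(out)
    ntip <- length(out$tip.label)
    violations <- 0L
    for (node in (ntip + 1L):max(out$edge)) {
      if (h[node] < thr &&
          length(gcjumps:::tips_under_node(out, node)) > 1L) {
        violations <- violations + 1L
      }
    }
    expect_equal(violations, 0L)
  }
})

test_that("node depths are additive along branches", {
  tr <- read_newick_string("((A:1,B:1):1,C:2);")
  d <- node_depths(tr)
  expect_equal(unname(d[c("A", "B", "C")]), c(2, 2, 2))
  expect_equal(unname(d["node5"]), 1)  # ancestor of the AB cherry
  star <- ape::stree(5, "star")
  star$edge.length <- rep(0.7, 5)
  expect_equal(unname(node_depths(star)[1:5]), rep(0.7, 5))
  # brute-force path sums on a random tree, and exact per-edge additivity
  tr2 <- random_test_tree(25, seed = 4)
  d2 <- node_depths(tr2)
  for (i in seq_len(25)) {
    expect_equal(unname(d2[i]), sum(tr2$edge.length[path_edges(tr2, i)]))
  }
  expect_true(all(abs(d2[tr2$edge[, 2]] - d2[tr2$edge[, 1]] -
                        tr2$edge.length) < 1e-12))
})

test_that("independent contrasts match closed forms and reject bad input", {
  tr <- read_newick_string("(A:1,B:1);")
  expect_equal(abs(unname(pic_contrasts(tr, c(A = 0, B = 2)))), 2 / sqrt(2))
  tr2 <- simulate_yule_tree(30, 1, seed = 5)
  expect_equal(max(abs(pic_contrasts(tr2, make_traits(tr2, rep(3, 30))))), 0)
  poly <- read_newick_string("(A:1,B:1,C:1);")
  expect_error(pic_contrasts(poly, c(A = 1, B = 2, C = 3)), "polytom")
  expect_error(pic_contrasts(tr, c(A = 1)), "missing trait")
})

test_that("contrast variance matches the Brownian rate on simulated data", {
  vars <- vapply(1:60, function(seed) {
    tr <- simulate_yule_tree(80, 1, seed = seed, jitter_sd = 0.3)
    sim <- simulate_levy(tr, levy_params(1, 0, 1, 50), seed = 1000 + seed)
    mean(pic_contrasts(tr, sim$traits)^2)
  }, numeric(1))
  expect_equal(mean(vars), 1, tolerance = 0.05)
})

test_that("contrasts are fat-tailed under jumps but not under Brownian motion", {
  tr <- simulate_yule_tree(250, 1, seed = 8, jitter_sd = 0.3)
  bm <- simulate_levy(tr, levy_params(1, 0, 1, 50), seed = 21)
  jumpy <- simulate_levy(tr, levy_params(1, 0.3, 30, 50), seed = 21)
  k_bm <- excess_kurtosis(pic_contrasts(tr, bm$traits))
  k_jump <- excess_kurtosis(pic_contrasts(tr, jumpy$traits))
  expect_gt(k_jump, k_bm)
  expect_gt(k_jump, 1)
})

test_that("excess kurtosis follows the moment definition", {
  expect_equal(excess_kurtosis(c(-1, 1, -1, 1)), -2)
  expect_error(excess_kurtosis(c(1, 2, 3)), "at least 4")
  expect_error(excess_kurtosis(rep(2, 10)), "zero variance")
  set.seed(42)
  expect_lt(abs(excess_kurtosis(rnorm(1e5))), 0.1)
  laplace <- rexp(1e5) * sample(c(-1, 1), 1e5, replace = TRUE)
  expect_equal(excess_kurtosis(laplace), 3, tolerance = 0.2)
})
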