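test_that("jump covariance reduces to the Brownian path matrix without jumps", {
  tr <- random_test_tree(6, seed = 1)
  V0 <- levy_covariance(tr, integer(nrow(tr$edge)), alpha = 4)
  expect_equal(V0[tr$tip.label, tr$tip.label], pathwalk_covariance(tr),
               tolerance = 1e-12)
})

test_that("a stem jump inflates a cherry's covariance block by exactly alpha", {
  tr <- read_newick_string("((A:1,B:1):1,C:2);")
  stem <- which(tr$edge[, 2] == length(tr$tip.label) + 2L)  # AB ancestor
  config <- integer(nrow(tr$edge))
  config[stem] <- 1L
  V <- levy_covariance(tr, config, alpha = 4)
  V0 <- levy_covariance(tr, integer(nrow(tr$edge)), alpha = 4)
  D <- (V - V0)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(D, rbind(c(4, 4, 0), c(4, 4, 0), c(0, 0, 0)),
               ignore_attr = TRUE)
})

test_that("jump covariance matches brute-force path summation", {
  for (seed in 1:3) {
    tr <- random_test_tree(6, seed = 30 + seed)
    set.seed(seed)
    config <- rpois(nrow(tr$edge), 0.8)
    alpha <- 2.5
    V <- levy_covariance(tr, config, alpha)
    eff <- tr$edge.length + alpha * config
    expect_equal(V[tr$tip.label, tr$tip.label],
                 pathwalk_covariance(tr, eff), tolerance = 1e-12)
  }
})

test_that("the simulator honours degenerate limits and the seed contract", {
  tr <- simulate_yule_tree(30, 1, seed = 2)
  still <- simulate_levy(tr, levy_params(1e-12, 0, 1, 47), seed = 3)
  expect_true(all(abs(still$traits - 47) < 1e-5))
  expect_true(all(still$config == 0))
  a <- simulate_levy(tr, levy_params(1, 1, 4, 50), seed = 9)
  b <- simulate_levy(tr, levy_params(1, 1, 4, 50), seed = 9)
  expect_identical(a, b)
})

test_that("simulated tip variance on a star tree matches the moment formula", {
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(1, 2000)
  v <- vapply(1:5, function(seed) {
    var(simulate_levy(star, levy_params(1, 1, 4, 0), seed = seed)$traits)
  }, numeric(1))
  # Var = sigma2_0 * t * (1 + lam * alpha) = 5
  expect_equal(mean(v), 5, tolerance = 0.05)
})

test_that("exact enumeration reduces to Brownian at lam = 0 and is monotone in n_max", {
  tr <- random_test_tree(8, seed = 5)
  set.seed(6)
  x <- make_traits(tr, rnorm(8, 50, 3))
  p0 <- levy_params(1.2, 0, 2, 50)
  expect_identical(levy_marginal_loglik_exact(tr, x, p0),
                   bm_loglik(tr, x, list(sigma2 = 1.2, x0 = 50)))
  tr3 <- read_newick_string("((A:1,B:1):1,C:2);")
  y <- c(A = 49, B = 52, C = 53)
  p <- levy_params(1, 0.5, 2, 50)
  lls <- vapply(0:12, function(nm) {
    levy_marginal_loglik_exact(tr3, y, p, n_max = nm)
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-9))
  expect_lt(lls[13] - lls[12], 1e-6)  # plateau at the truncation bound
  expect_error(levy_marginal_loglik_exact(tr, x, levy_params(1, 50, 2, 50)),
               "infeasible")
})

test_that("exact enumeration agrees with an independent brute-force sum", {
  for (seed in 1:4) {
    tr <- random_test_tree(4, seed = 40 + seed)  # 6 branches
    set.seed(seed)
    x <- make_traits(tr, rnorm(4, 50, 4))
    p <- levy_params(1, 0.5, 2, 50)
    expect_equal(levy_marginal_loglik_exact(tr, x, p, n_max = 3),
                 bruteforce_levy_loglik(tr, x, p, n_max = 3),
                 tolerance = 1e-9)
  }
})

test_that("the prior Monte-Carlo estimator covers the exact value", {
  tr <- random_test_tree(5, seed = 50)
  set.seed(51)
  x <- make_traits(tr, rnorm(5, 50, 3))
  p <- levy_params(1, 0.4, 2, 50)
  exact <- levy_marginal_loglik_exact(tr, x, p)
  hits <- 0
  for (r in 1:50) {
    est <- levy_marginal_loglik_mc(tr, x, p, n_samples = 2000, seed = r)
    if (abs(est$loglik - exact) <= 3 * est$se) hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% coverage observed at nominal ~99.7%
  p0 <- levy_params(1, 0, 2, 50)
  est0 <- levy_marginal_loglik_mc(tr, x, p0, n_samples = 200, seed = 1)
  expect_identical(est0$loglik, bm_loglik(tr, x, list(sigma2 = 1, x0 = 50)))
  expect_identical(est0$se, 0)
})

test_that("Monte-Carlo standard error shrinks like one over root n", {
  tr <- random_test_tree(5, seed = 52)
  set.seed(53)
  x <- make_traits(tr, rnorm(5, 50, 3))
  p <- levy_params(1, 0.4, 2, 50)
  se1 <- mean(vapply(1:20, function(r) {
    levy_marginal_loglik_mc(tr, x, p, n_samples = 1000, seed = r)$se
  }, numeric(1)))
  se2 <- mean(vapply(1:20, function(r) {
    levy_marginal_loglik_mc(tr, x, p, n_samples = 2000, seed = 100 + r)$se
  }, numeric(1)))
  expect_equal(se1 / se2, sqrt(2), tolerance = 0.2)
})

test_that("annealed importance sampling agrees with exact enumeration", {
  tr <- random_test_tree(4, seed = 54)
  set.seed(55)
  x <- make_traits(tr, rnorm(4, 50, 4))
  p <- levy_params(1, 0.5, 2, 50)
  exact <- levy_marginal_loglik_exact(tr, x, p)
  est <- levy_marginal_loglik_ais(tr, x, p, n_particles = 200, seed = 56)
  expect_equal(est$loglik, exact, tolerance = 3 * est$se + 0.05)
})

test_that("EM drives the jump rate to zero on jump-free data", {
  sig <- lam <- numeric(5)
  for (k in 1:5) {
    tr <- simulate_yule_tree(200, 1, seed = 59 + k, jitter_sd = 0.3)
    sim <- simulate_levy(tr, levy_params(2, 0, 1, 50), seed = 160 + k)
    fit <- suppressWarnings(fit_levy_em(tr, sim$traits, alpha = 4,
                                        seed = 170 + k, em_max_iter = 150))
    lam[k] <- fit$params$lam * sum(tr$edge.length)  # expected total jumps
    sig[k] <- fit$params$sigma2_0
  }
  # boundary estimate: at the median the fitted rate implies well under
  # 0.1 expected jumps on the whole tree
  expect_lte(median(lam), 0.1)
  expect_equal(median(sig), 2, tolerance = 0.1)
})

test_that("EM fits are reproducible from the seed", {
  tr <- simulate_yule_tree(60, 1, seed = 63, jitter_sd = 0.3)
  sim <- simulate_levy(tr, levy_params(1, 1, 4, 50), seed = 64)
  f1 <- reduced_em(tr, sim$traits, alpha = 4, seed = 65)
  f2 <- reduced_em(tr, sim$traits, alpha = 4, seed = 65)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("EM recovers generating parameters at desk scale", {
  lam <- sig <- numeric(5)
  for (k in 1:5) {
    tr <- simulate_yule_tree(150, 1, seed = 70 + k, jitter_sd = 0.3)
    sim <- simulate_levy(tr, levy_params(1, 1, 4, 50), seed = 80 + k)
    fit <- reduced_em(tr, sim$traits, alpha = 4, seed = 90 + k)
    lam[k] <- fit$params$lam
    sig[k] <- fit$params$sigma2_0
  }
  expect_gte(median(lam), 0.4)
  expect_lte(median(lam), 2)
  expect_gte(median(sig), 0.6)
  expect_lte(median(sig), 1.5)
})

test_that("alpha profiling exposes the grid and selects a sensible value", {
  tr <- simulate_yule_tree(100, 1, seed = 100, jitter_sd = 0.3)
  sim <- simulate_levy(tr, levy_params(1, 1, 4, 50), seed = 101)
  expect_equal(eval(formals(profile_alpha)$alpha_grid),
               c(0.1, 0.25, 0.5, 1, 2, 4))
  one <- suppressWarnings(
    profile_alpha(tr, sim$traits, alpha_grid = 2, seed = 102,
                  em_max_iter = 15, mcmc_steps = 50))
  expect_equal(one$params$alpha, 2)
  expect_equal(nrow(one$alpha_grid), 1L)
  pf <- suppressWarnings(
    profile_alpha(tr, sim$traits, alpha_grid = c(0.25, 1, 4), seed = 103,
                  em_max_iter = 20, mcmc_steps = 60))
  expect_equal(pf$params$alpha,
               pf$alpha_grid$alpha[which.max(pf$alpha_grid$loglik)])
})

test_that("branch posteriors are exact under a no-jump prior and on tiny trees", {
  tr3 <- read_newick_string("((A:1,B:1):1,C:2);")
  y <- c(A = 48, B = 55, C = 62)
  none <- branch_jump_posteriors(tr3, y, levy_params(1, 0, 2, 50),
                                 mcmc_steps = 500, burn_in = 50, seed = 1)
  expect_true(all(none$pp == 0))
  for (k in 1:2) {
    p <- levy_params(1, c(0.4, 0.8)[k], 2, 50)
    exact <- branch_jump_posteriors_exact(tr3, y, p)
    mc <- branch_jump_posteriors(tr3, y, p, mcmc_steps = 20000,
                                 burn_in = 1000, seed = 10 + k)
    expect_lt(max(abs(exact - mc$pp)), 0.02)
    expect_true(attr(mc, "diag_ok"))
  }
})

test_that("a planted large jump earns the top posterior on its branch", {
  hits <- 0
  for (k in 1:20) {
    tr <- simulate_yule_tree(50, 1, seed = 200 + k, jitter_sd = 0.2)
    depth <- mean(node_depths(tr)[1:50])
    mag <- 10 * sqrt(depth)
    # internal branch with a mid-sized clade under it
    sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
      length(gcjumps:::tips_under_node(tr, tr$edge[e, 2]))
    }, integer(1))
    target <- which(sizes >= 5 & sizes <= 15)[1]
    sim <- simulate_levy(tr, levy_params(1, 0, 1, 50), seed = 300 + k)
    x <- sim$traits
    under <- tr$tip.label[gcjumps:::tips_under_node(tr, tr$edge[target, 2])]
    x[under] <- x[under] + mag
    p <- levy_params(1, 0.02, mag^2, 50)  # jump sd = planted magnitude
    post <- suppressWarnings(
      branch_jump_posteriors(tr, x, p, mcmc_steps = 2000, burn_in = 200,
                             seed = 400 + k))
    if (which.max(post$pp) == target) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("posterior probabilities are roughly calibrated in the mid range", {
  p <- levy_params(1, 0.6, 3, 50)
  in_bucket <- jumped <- 0
  for (k in 1:25) {
    tr <- simulate_yule_tree(40, 1, seed = 500 + k, jitter_sd = 0.3)
    sim <- simulate_levy(tr, p, seed = 600 + k)
    post <- suppressWarnings(
      branch_jump_posteriors(tr, sim$traits, p, mcmc_steps = 2000,
                             burn_in = 200, seed = 700 + k))
    sel <- post$pp >= 0.8 & post$pp <= 0.9
    in_bucket <- in_bucket + sum(sel)
    jumped <- jumped + sum(sim$config[sel] >= 1)
  }
  expect_gte(in_bucket, 10)  # the bucket must actually be populated
  frac <- jumped / in_bucket
  expect_gte(frac, 0.7)
  expect_lte(frac, 1)
})

test_that("larger planted jumps never lower the posterior on their branch", {
  mags <- c(2, 6, 18)
  med_pp <- numeric(3)
  for (m in seq_along(mags)) {
    pps <- numeric(8)
    for (k in 1:8) {
      tr <- simulate_yule_tree(40, 1, seed = 800 + k, jitter_sd = 0.2)
      sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
        length(gcjumps:::tips_under_node(tr, tr$edge[e, 2]))
      }, integer(1))
      target <- which(sizes >= 4 & sizes <= 12)[1]
      sim <- simulate_levy(tr, levy_params(1, 0, 1, 50), seed = 900 + k)
      x <- sim$traits
      under <- tr$tip.label[gcjumps:::tips_under_node(tr, tr$edge[target, 2])]
      x[under] <- x[under] + mags[m]
      post <- suppressWarnings(
        branch_jump_posteriors(tr, x, levy_params(1, 0.05, 36, 50),
                               mcmc_steps = 1500, burn_in = 150,
                               seed = 950 + k))
      pps[k] <- post$pp[target]
    }
    med_pp[m] <- median(pps)
  }
  expect_true(all(diff(med_pp) >= 0))
})
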