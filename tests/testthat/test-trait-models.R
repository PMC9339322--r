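test_that("Brownian log-likelihood matches independent-tips closed form", {
  tr <- read_newick_string("(A:1,B:1);")
  ll <- bm_loglik(tr, c(A = 0, B = 2), list(sigma2 = 1, x0 = 1))
  expect_equal(ll, -log(2 * pi) - 1, tolerance = 1e-12)
})

test_that("Brownian log-likelihood diverges as sigma2 -> 0 at the root state", {
  tr <- simulate_yule_tree(10, 1, seed = 2)
  x <- make_traits(tr, rep(5, 10))
  lls <- vapply(c(1, 0.1, 0.01, 0.001),
                function(s) bm_loglik(tr, x, list(sigma2 = s, x0 = 5)),
                numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("pruning likelihood equals the dense matrix oracle", {
  for (seed in 1:4) {
    tr <- random_test_tree(6, seed)
    set.seed(100 + seed)
    x <- make_traits(tr, rnorm(6, 50, 4))
    C <- pathwalk_covariance(tr)
    expect_equal(bm_loglik(tr, x, list(sigma2 = 2.3, x0 = 49)),
                 dense_mvn(unname(x[tr$tip.label]), rep(49, 6), 2.3 * C),
                 tolerance = 1e-9)
  }
})

test_that("closed-form Brownian fit is the maximum-likelihood solution", {
  tr <- read_newick_string("(A:1,B:1);")
  fit <- fit_bm(tr, c(A = 0, B = 2))
  expect_equal(fit$params$x0, 1)
  expect_equal(fit$params$sigma2, 1)
  tr2 <- simulate_yule_tree(40, 1, seed = 6, jitter_sd = 0.3)
  sim <- simulate_levy(tr2, levy_params(2, 0, 1, 50), seed = 7)
  fit2 <- fit_bm(tr2, sim$traits)
  for (d in c(-0.05, 0.05)) {
    expect_gte(fit2$loglik,
               bm_loglik(tr2, sim$traits,
                         list(sigma2 = fit2$params$sigma2 * (1 + d),
                              x0 = fit2$params$x0)))
    expect_gte(fit2$loglik,
               bm_loglik(tr2, sim$traits,
                         list(sigma2 = fit2$params$sigma2,
                              x0 = fit2$params$x0 + d)))
  }
  expect_error(fit_bm(tr2, make_traits(tr2, rep(1, 40))), "zero")
})

test_that("the Brownian rate estimator is unbiased on simulated data", {
  est <- vapply(1:80, function(seed) {
    tr <- simulate_yule_tree(150, 1, seed = seed, jitter_sd = 0.3)
    sim <- simulate_levy(tr, levy_params(2, 0, 1, 50), seed = 4000 + seed)
    fit_bm(tr, sim$traits)$params$sigma2
  }, numeric(1))
  expect_equal(mean(est), 2, tolerance = 0.05)
})

test_that("OU likelihood reduces continuously to Brownian motion", {
  tr <- simulate_yule_tree(25, 1, seed = 9, jitter_sd = 0.4)
  sim <- simulate_levy(tr, levy_params(1.5, 0, 1, 40), seed = 10)
  bm <- bm_loglik(tr, sim$traits, list(sigma2 = 1.5, x0 = 40))
  ou <- ou_loglik(tr, sim$traits,
                  list(sigma2 = 1.5, alpha_ou = 1e-8, theta = 40))
  expect_equal(ou, bm, tolerance = 1e-6)
})

test_that("OU likelihood matches a dense oracle built from first principles", {
  tr <- random_test_tree(5, seed = 11)
  set.seed(12)
  x <- make_traits(tr, rnorm(5, 55, 3))
  a <- 0.8
  sig <- 2.1
  theta <- 54
  d <- node_depths(tr)[1:5]
  Ca <- pathwalk_covariance(tr)  # MRCA depths
  W <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      ta <- Ca[i, j]
      W[i, j] <- exp(-a * (d[i] + d[j] - 2 * ta)) *
        (1 - exp(-2 * a * ta)) / (2 * a)
    }
  }
  expect_equal(ou_loglik(tr, x, list(sigma2 = sig, alpha_ou = a,
                                     theta = theta)),
               dense_mvn(unname(x[tr$tip.label]), rep(theta, 5), sig * W),
               tolerance = 1e-9)
})

test_that("strong constraint on a star tree approaches the stationary variance", {
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  a <- 30
  sig <- 2
  set.seed(13)
  x <- stats::setNames(rnorm(40, 60, sqrt(sig / (2 * a))), star$tip.label)
  ll_iid <- sum(dnorm(unname(x), 60, sqrt(sig / (2 * a)), log = TRUE))
  expect_equal(ou_loglik(star, x, list(sigma2 = sig, alpha_ou = a,
                                       theta = 60)),
               ll_iid, tolerance = 1e-6)
})

test_that("OU fitting collapses to Brownian motion on Brownian data", {
  gaps <- alphas <- numeric(15)
  for (k in 1:15) {
    tr <- simulate_yule_tree(120, 1, seed = 20 + k, jitter_sd = 0.3)
    sim <- simulate_levy(tr, levy_params(1, 0, 1, 50), seed = 50 + k)
    bm <- fit_bm(tr, sim$traits)
    ou <- fit_ou(tr, sim$traits)
    expect_gte(ou$loglik, bm$loglik - 1e-8)  # BM is nested in OU
    gaps[k] <- ou$loglik - bm$loglik
    alphas[k] <- ou$params$alpha_ou
  }
  # the constraint estimate sits on the zero boundary for a large share of
  # Brownian datasets (boundary-parameter mixture), where OU equals BM
  # exactly; interior cases differ only by chi-square-scale noise
  expect_gte(sum(gaps <= 1e-4), 3)
  expect_true(all(alphas[gaps <= 1e-4] <= 1e-6))
  expect_lt(median(gaps), 2)
  expect_true(all(gaps < 5))  # interior improvements stay at chi-square scale
})

test_that("likelihood-ratio test follows the chi-square tail", {
  expect_equal(lrt(-10, -10, df = 2)$p_value, 1)
  expect_equal(lrt(-10 + 5.99 / 2, -10, df = 2)$p_value, 0.05,
               tolerance = 2e-3)
  ps <- vapply(seq(0.5, 5, by = 0.5),
               function(d) lrt(-10 + d, -10, df = 2)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(lrt(-11, -10, df = 2), "below null")
  expect_equal(lrt(-10 + 200, -10, df = 2)$p_value, 1e-16)  # documented floor
})
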