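#' Parameters of the Levy-jumps trait model
#'
#' Constructor with validation. The model is Brownian motion (rate
#' `sigma2_0`, GC%^2 per unit branch length) plus jumps arriving as a
#' Poisson process with rate `lam` per unit branch length; each jump's
#' magnitude is Normal with variance `alpha * sigma2_0`, so conditional on
#' the per-branch jump counts `n` the model is Brownian with effective
#' branch lengths `t_i + alpha * n_i`.
#'
#' @param sigma2_0 Brownian rate, > 0.
#' @param lam Jump rate per unit branch length, >= 0.
#' @param alpha Per-jump variance as a multiple of `sigma2_0`, > 0.
#' @param x0 Ancestral (root) GC%.
#' @return A list of class `"levy_params"`.
#' @export
levy_params <- function(sigma2_0, lam, alpha, x0) {
  stopifnot(sigma2_0 > 0, lam >= 0, alpha > 0)
  structure(list(sigma2_0 = sigma2_0, lam = lam, alpha = alpha, x0 = x0),
            class = "levy_params")
}

#' Tip covariance of the Levy model given a jump configuration
#'
#' Unit-rate covariance: `V(n)[j, k]` is the sum over branches on the shared
#' root-to-MRCA path of `t_i + alpha * n_i`; the full covariance is
#' `sigma2_0 * V(n)`.
#'
#' @param tree A rooted `"phylo"`.
#' @param config Integer vector of jump counts per branch (rows of
#'   `tree$edge`).
#' @param alpha Per-jump variance multiple.
#' @return Dense tip covariance matrix (unit rate).
#' @export
levy_covariance <- function(tree, config, alpha) {
  stopifnot(length(config) == nrow(tree$edge), all(config >= 0))
  t2 <- tree
  t2$edge.length <- tree$edge.length + alpha * config
  ape::vcv.phylo(t2)
}

#' Simulate trait evolution under the Levy-jumps model
#'
#' Per branch `i`, a jump count `n_i ~ Poisson(lam * t_i)` and a Gaussian
#' increment with variance `sigma2_0 * (t_i + alpha * n_i)`; tip values
#' accumulate increments root-to-tip from `x0`. Fully reproducible from
#' `seed`; the true jump configuration is returned alongside the traits.
#'
#' @param tree A rooted `"phylo"`.
#' @param params A [levy_params()] object.
#' @param seed Integer seed.
#' @param gc_bounds Optional `c(low, high)`: reflecting boundaries applied to
#'   each node value (increments folded back into the interval), emulating a
#'   constraint on attainable GC content.
#' @return List with `traits` (named numeric vector over tips), `config`
#'   (integer jump counts per edge), `jump_disp` (the jump component of
#'   each branch's increment, GC%; 0 on jump-free branches) and
#'   `node_values` (realised trait value at every node, tips first).
#' @export
simulate_levy <- function(tree, params, seed, gc_bounds = NULL) {
  stopifnot(inherits(tree, "phylo"))
  set.seed(seed)
  nedge <- nrow(tree$edge)
  t <- tree$edge.length
  n <- stats::rpois(nedge, params$lam * t)
  bm_part <- stats::rnorm(nedge, 0, sqrt(params$sigma2_0 * t))
  jump_part <- stats::rnorm(nedge, 0,
                            sqrt(params$sigma2_0 * params$alpha * n))
  incr <- bm_part + jump_part
  nnode <- max(tree$edge)
  ntip <- length(tree$tip.label)
  val <- numeric(nnode)
  val[ntip + 1L] <- params$x0
  pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nedge)) {
    e <- o[k]
    v <- val[tree$edge[e, 1]] + incr[e]
    if (!is.null(gc_bounds)) v <- reflect_into(v, gc_bounds[1], gc_bounds[2])
    val[tree$edge[e, 2]] <- v
  }
  list(traits = stats::setNames(val[seq_len(ntip)], tree$tip.label),
       config = n, jump_disp = jump_part, node_values = val)
}

# Fold a value into [lo, hi] by repeated reflection at the boundaries.
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Exact marginal log-likelihood of the Levy model by enumeration
#'
#' Sums the complete-data Gaussian likelihood over all truncated jump
#' configurations, `log sum_n [prod_i Poisson(n_i; lam t_i)] *
#' MVN(x; x0, sigma2_0 V(n))`, with log-sum-exp. Only feasible on small
#' trees; the per-branch truncation `n_max` is chosen so the retained
#' Poisson mass is at least `1 - 1e-6` per branch.
#'
#' @inheritParams simulate_levy
#' @param traits Named numeric tip GC vector.
#' @param n_max Optional common truncation for all branches (overrides the
#'   automatic per-branch choice).
#' @param max_configs Enumeration guard; exceeding it is an error directing
#'   the caller to [levy_marginal_loglik_mc()].
#' @return The (truncated) marginal log-likelihood.
#' @export
levy_marginal_loglik_exact <- function(tree, traits, params, n_max = NULL,
                                       max_configs = 1e6) {
  mu <- params$lam * tree$edge.length
  nm <- if (is.null(n_max)) {
    stats::qpois(1e-6, mu, lower.tail = FALSE)
  } else {
    rep(as.integer(n_max), length(mu))
  }
  nm[mu == 0] <- 0L
  n_conf <- prod(as.double(nm) + 1)
  if (n_conf > max_configs) {
    stop("enumeration over ", format(n_conf), " configurations infeasible; ",
         "use levy_marginal_loglik_mc()")
  }
  grid <- as.matrix(expand.grid(lapply(nm, function(k) 0:k)))
  logprior <- colSums(matrix(
    stats::dpois(t(grid), mu, log = TRUE), nrow = ncol(grid)))
  x <- traits_in_tip_order(tree, traits)
  ll <- prune_loglik_batch_cpp(tree$edge, length(tree$tip.label),
                               tree$edge.length, t(grid), params$alpha, x,
                               params$sigma2_0, params$x0)
  logsumexp(logprior + ll)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Monte-Carlo marginal log-likelihood (prior sampling)
#'
#' Draws jump configurations from the Poisson prior and averages the
#' Gaussian densities in log-sum-exp form. The standard error of the log
#' estimate comes from the delta method. Prior sampling is exact on average
#' but degrades on large trees where the posterior concentrates far from the
#' prior; see [fit_levy_em()] for the estimator used at fitting time.
#'
#' @inheritParams levy_marginal_loglik_exact
#' @param n_samples Number of prior draws (>= 100).
#' @param seed Integer seed.
#' @return List with `loglik`, `se`, `n_samples`.
#' @export
levy_marginal_loglik_mc <- function(tree, traits, params, n_samples = 1000,
                                    seed = 1) {
  stopifnot(n_samples >= 100)
  set.seed(seed)
  mu <- params$lam * tree$edge.length
  x <- traits_in_tip_order(tree, traits)
  if (all(mu == 0)) {
    ll <- bm_loglik(tree, traits,
                    list(sigma2 = params$sigma2_0, x0 = params$x0))
    return(list(loglik = ll, se = 0, n_samples = n_samples))
  }
  counts <- matrix(stats::rpois(length(mu) * n_samples, mu),
                   nrow = length(mu))
  ll <- prune_loglik_batch_cpp(tree$edge, length(tree$tip.label),
                               tree$edge.length, counts, params$alpha, x,
                               params$sigma2_0, params$x0)
  m <- max(ll)
  if (!is.finite(m)) {
    stop("all sampled densities underflow; use exact enumeration or more ",
         "samples")
  }
  w <- exp(ll - m)
  est <- m + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(n_samples))
  list(loglik = est, se = se, n_samples = n_samples)
}

#' Annealed-importance-sampling marginal log-likelihood
#'
#' Unbiased (on the likelihood scale) estimate of the Levy marginal
#' likelihood by annealed importance sampling: each particle starts at the
#' Poisson prior over jump configurations and is pulled through a ladder of
#' likelihood-tempered distributions by Metropolis sweeps. Far more stable
#' than prior sampling on trees with hundreds of branches, where the
#' posterior sits in an exponentially small corner of the prior; this is
#' the estimator [fit_levy_em()] reports when exact enumeration is
#' infeasible.
#'
#' @inheritParams levy_marginal_loglik_exact
#' @param n_particles Independent annealing runs.
#' @param n_temps Temperature rungs (geometric ladder, finer near the
#'   prior).
#' @param sweeps_per_temp Metropolis sweeps at each rung.
#' @param seed Integer seed.
#' @return List with `loglik`, `se` (delta-method standard error of the log
#'   estimate), `n_particles`.
#' @export
levy_marginal_loglik_ais <- function(tree, traits, params, n_particles = 24,
                                     n_temps = 40, sweeps_per_temp = 1,
                                     seed = 1) {
  mu <- params$lam * tree$edge.length
  if (all(mu == 0)) {
    ll <- bm_loglik(tree, traits,
                    list(sigma2 = params$sigma2_0, x0 = params$x0))
    return(list(loglik = ll, se = 0, n_particles = n_particles))
  }
  x <- traits_in_tip_order(tree, traits)
  set.seed(seed)
  lw <- levy_ais_cpp(tree$edge, length(tree$tip.label), tree$edge.length, x,
                     params$sigma2_0, params$lam, params$alpha, params$x0,
                     n_particles, n_temps, sweeps_per_temp)
  m <- max(lw)
  if (!is.finite(m)) stop("annealing weights underflow")
  w <- exp(lw - m)
  list(loglik = m + log(mean(w)),
       se = stats::sd(w) / (mean(w) * sqrt(n_particles)),
       n_particles = n_particles)
}

#' Fit the Levy-jumps model at fixed alpha by EM + MCMC
#'
#' Expectation-Maximisation over the latent per-branch jump counts. The
#' E-step samples configurations by Metropolis MCMC (single-branch +/-1
#' proposals); the M-step updates `lam` as the mean sampled jump total per
#' unit tree length and solves `(sigma2_0, x0)` from the sample-averaged
#' complete-data Gaussian log-likelihood in closed form. The relative jump
#' size `alpha` cannot be estimated this way and is profiled externally
#' ([profile_alpha()]). Convergence: relative change in `(lam, sigma2_0)`
#' below `1e-3` for 3 consecutive iterations.
#'
#' @inheritParams levy_marginal_loglik_exact
#' @param alpha Fixed per-jump variance multiple (> 0).
#' @param seed Integer seed; the fit is fully reproducible from it.
#' @param em_max_iter Maximum EM iterations.
#' @param mcmc_steps MCMC sweeps per E-step (over all branches).
#' @param n_e_samples Configurations retained per E-step.
#' @param avg_window Iterations averaged for the Monte-Carlo-EM estimate
#'   and its convergence check (the per-iteration M-step updates carry
#'   sampling noise, so convergence is judged on running means).
#' @param loglik_particles Annealing particles for the final marginal
#'   log-likelihood when exact enumeration is infeasible.
#' @return List of class `"levy_fit"`: `params` ([levy_params()]), `loglik`,
#'   `loglik_se`, `converged`, `trace` (per-iteration parameter history),
#'   `model = "Levy"`, `n_tips`, `seed`.
#' @export
fit_levy_em <- function(tree, traits, alpha, seed = 1, em_max_iter = 40,
                        mcmc_steps = 100, n_e_samples = 25, avg_window = 8,
                        loglik_particles = 24) {
  stopifnot(alpha > 0, length(tree$tip.label) >= 4)
  x <- traits_in_tip_order(tree, traits)
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  total_len <- sum(tree$edge.length)

  bm <- fit_bm(tree, traits)
  sigma2 <- bm$params$sigma2 / 2
  x0 <- bm$params$x0
  lam <- 1 / alpha  # half the observed variance assigned to jumps initially

  counts <- integer(nedge)
  trace <- matrix(NA_real_, em_max_iter, 6,
                  dimnames = list(NULL, c("iter", "lam", "sigma2_0", "x0",
                                          "rel_change", "accept")))
  converged <- FALSE
  n_iter <- 0L
  thin <- max(1L, floor(mcmc_steps / (2 * n_e_samples)))
  burn <- mcmc_steps - thin * n_e_samples
  run_mean <- function(col, it) {
    mean(trace[max(1L, it - avg_window + 1L):it, col])
  }

  for (it in seq_len(em_max_iter)) {
    set.seed(derive_seed(seed, it))
    run <- levy_mcmc_cpp(tree$edge, ntip, tree$edge.length, x, sigma2, lam,
                         alpha, x0, counts, mcmc_steps, burn, thin, TRUE)
    counts <- run$counts
    s <- run$samples  # rows: total_jumps, xhat_root, v_root, ss, sumlog
    lam_new <- max(mean(s[1, ]) / total_len, 1e-8)
    x0_new <- sum(s[2, ] / s[3, ]) / sum(1 / s[3, ])
    q <- s[4, ] + (s[2, ] - x0_new)^2 / s[3, ]
    sigma2_new <- mean(q) / ntip
    trace[it, ] <- c(it, lam_new, sigma2_new, x0_new, NA, run$accept_rate)
    n_iter <- it
    # convergence on running means: relative drift of the averaged
    # (lam, sigma2_0) between consecutive windows below 5e-3, three times
    # in a row (the averaging absorbs the E-step sampling noise)
    if (it > avg_window) {
      rel <- max(
        abs(run_mean("lam", it) - run_mean("lam", it - 1L)) /
          max(run_mean("lam", it), 1e-8),
        abs(run_mean("sigma2_0", it) - run_mean("sigma2_0", it - 1L)) /
          run_mean("sigma2_0", it))
      trace[it, "rel_change"] <- rel
      if (it >= avg_window + 3L &&
          all(trace[(it - 2L):it, "rel_change"] < 5e-3)) {
        converged <- TRUE
      }
    }
    lam <- lam_new
    sigma2 <- sigma2_new
    x0 <- x0_new
    if (converged) break
  }
  if (!converged) {
    warning("EM did not converge after ", em_max_iter,
            " iterations; returning best-so-far estimates")
  }
  # final estimate: average over the last window (Monte-Carlo EM smoothing)
  lam <- run_mean("lam", n_iter)
  sigma2 <- run_mean("sigma2_0", n_iter)
  x0 <- run_mean("x0", n_iter)
  params <- levy_params(sigma2, lam, alpha, x0)
  mlf <- levy_loglik_auto(tree, traits, params, loglik_particles,
                          derive_seed(seed, 9999))
  structure(list(model = "Levy", params = params, loglik = mlf$loglik,
                 loglik_se = mlf$se, converged = converged,
                 trace = trace[seq_len(n_iter), , drop = FALSE],
                 n_tips = ntip, seed = seed),
            class = "levy_fit")
}

# Exact enumeration when cheap, annealed importance sampling otherwise.
levy_loglik_auto <- function(tree, traits, params, n_particles, seed) {
  mu <- params$lam * tree$edge.length
  nm <- stats::qpois(1e-6, mu, lower.tail = FALSE)
  nm[mu == 0] <- 0L
  if (prod(as.double(nm) + 1) <= 2e4) {
    list(loglik = levy_marginal_loglik_exact(tree, traits, params), se = 0)
  } else {
    levy_marginal_loglik_ais(tree, traits, params, n_particles = n_particles,
                             seed = seed)
  }
}

#' Profile the relative jump size alpha over a grid
#'
#' Runs [fit_levy_em()] at each grid value and keeps the fit with the
#' largest estimated marginal log-likelihood. The default grid
#' `{0.1, 0.25, 0.5, 1, 2, 4}` lets the variance contributed per jump range
#' from 10 times less to 4 times more than the Brownian rate. A warning is
#' issued when the maximum sits on the grid boundary.
#'
#' @inheritParams fit_levy_em
#' @param alpha_grid Non-empty numeric grid of alpha values.
#' @param ... Passed to [fit_levy_em()].
#' @return A `"levy_fit"` as from [fit_levy_em()], with an extra element
#'   `alpha_grid`: a data frame of per-alpha parameter estimates and
#'   log-likelihoods.
#' @export
profile_alpha <- function(tree, traits, alpha_grid = c(0.1, 0.25, 0.5, 1, 2, 4),
                          seed = 1, ...) {
  stopifnot(length(alpha_grid) >= 1)
  alpha_grid <- sort(alpha_grid)
  fits <- lapply(seq_along(alpha_grid), function(k) {
    fit_levy_em(tree, traits, alpha = alpha_grid[k],
                seed = derive_seed(seed, k), ...)
  })
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  k <- which.max(lls)
  if (length(alpha_grid) > 2 && (k == 1L || k == length(alpha_grid))) {
    warning("profile maximum at the alpha grid boundary (alpha = ",
            alpha_grid[k], "); consider widening the grid")
  }
  best <- fits[[k]]
  best$alpha_grid <- data.frame(
    alpha = alpha_grid,
    lam = vapply(fits, function(f) f$params$lam, numeric(1)),
    sigma2_0 = vapply(fits, function(f) f$params$sigma2_0, numeric(1)),
    x0 = vapply(fits, function(f) f$params$x0, numeric(1)),
    loglik = lls,
    loglik_se = vapply(fits, `[[`, numeric(1), "loglik_se"),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  best
}

#' Empirical-Bayes posterior probability of >= 1 jump per branch
#'
#' With the model parameters fixed at their estimates, samples jump
#' configurations by MCMC and reports, per branch, the fraction of retained
#' samples with at least one jump. Two independent chains are run; their
#' maximum per-branch disagreement is the convergence diagnostic (flagged,
#' never silent, when above 0.05).
#'
#' @inheritParams fit_levy_em
#' @param params A [levy_params()] object (typically from the fit).
#' @param mcmc_steps Total sweeps per chain (must exceed `burn_in`).
#' @param burn_in Discarded leading sweeps per chain.
#' @param n_chains Independent chains (>= 2 for the diagnostic).
#' @return A data frame of class `"branch_posteriors"` with columns `edge`,
#'   `parent`, `child`, `child_label`, `pp`, carrying attributes `tree`,
#'   `diag_max_disagreement`, `diag_ok`, `params`, `seed`.
#' @export
branch_jump_posteriors <- function(tree, traits, params, mcmc_steps = 4000,
                                   burn_in = 400, seed = 1, n_chains = 2) {
  stopifnot(mcmc_steps > burn_in)
  x <- traits_in_tip_order(tree, traits)
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  pps <- matrix(NA_real_, nedge, n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, 100 + ch))
    run <- levy_mcmc_cpp(tree$edge, ntip, tree$edge.length, x,
                         params$sigma2_0, params$lam, params$alpha,
                         params$x0, integer(nedge), mcmc_steps, burn_in, 1,
                         FALSE)
    pps[, ch] <- run$pp
  }
  pp <- rowMeans(pps)
  disagreement <- if (n_chains >= 2) {
    max(apply(pps, 1, function(v) diff(range(v))))
  } else {
    NA_real_
  }
  ok <- is.na(disagreement) || disagreement <= 0.05
  if (!ok) {
    warning("chain disagreement ", signif(disagreement, 3),
            " exceeds 0.05; consider more MCMC sweeps")
  }
  ntip_lab <- function(n) ifelse(n <= ntip, tree$tip.label[pmin(n, ntip)],
                                 paste0("node", n))
  out <- data.frame(edge = seq_len(nedge), parent = tree$edge[, 1],
                    child = tree$edge[, 2],
                    child_label = ntip_lab(tree$edge[, 2]), pp = pp)
  attr(out, "tree") <- tree
  attr(out, "diag_max_disagreement") <- disagreement
  attr(out, "diag_ok") <- ok
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("branch_posteriors", "data.frame")
  out
}

#' Exact branch jump posteriors by truncated enumeration
#'
#' Oracle-grade counterpart of [branch_jump_posteriors()] for very small
#' trees: enumerates all truncated configurations and returns the exact
#' posterior probability of >= 1 jump per branch.
#'
#' @inheritParams levy_marginal_loglik_exact
#' @return Numeric vector of posterior probabilities per edge.
#' @export
branch_jump_posteriors_exact <- function(tree, traits, params, n_max = NULL,
                                         max_configs = 1e6) {
  mu <- params$lam * tree$edge.length
  nm <- if (is.null(n_max)) {
    stats::qpois(1e-9, mu, lower.tail = FALSE)
  } else {
    rep(as.integer(n_max), length(mu))
  }
  nm[mu == 0] <- 0L
  if (prod(as.double(nm) + 1) > max_configs) stop("enumeration infeasible")
  grid <- as.matrix(expand.grid(lapply(nm, function(k) 0:k)))
  logprior <- colSums(matrix(stats::dpois(t(grid), mu, log = TRUE),
                             nrow = ncol(grid)))
  x <- traits_in_tip_order(tree, traits)
  ll <- prune_loglik_batch_cpp(tree$edge, length(tree$tip.label),
                               tree$edge.length, t(grid), params$alpha, x,
                               params$sigma2_0, params$x0)
  lw <- logprior + ll
  w <- exp(lw - logsumexp(lw))
  as.numeric(crossprod(grid >= 1, w))
}
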