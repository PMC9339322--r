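#' Brownian-motion log-likelihood
#'
#' Log density of the tip GC values under single-rate Brownian motion: a
#' multivariate normal with mean `x0` at every tip and covariance
#' `sigma2 * C`, where `C[j, k]` is the root-to-MRCA shared path length of
#' tips j and k. Evaluated in O(N) by Felsenstein's pruning algorithm.
#'
#' @param tree A rooted `"phylo"` with branch lengths.
#' @param traits Named numeric vector of tip GC percentages.
#' @param params List with `sigma2 > 0` (Brownian rate, GC%^2 per unit branch
#'   length) and `x0` (root GC%), as returned by [fit_bm()].
#' @return The log-likelihood (a scalar).
#' @export
bm_loglik <- function(tree, traits, params) {
  stopifnot(params$sigma2 > 0)
  st <- prune_stats(tree, traits)
  loglik_from_stats(st, length(tree$tip.label), params$sigma2, params$x0)
}

loglik_from_stats <- function(st, ntip, sigma2, x0) {
  q <- st$ss + (st$xhat_root - x0)^2 / st$v_root
  -0.5 * (ntip * log(2 * pi * sigma2) + st$sumlog + log(st$v_root) +
            q / sigma2)
}

#' Maximum-likelihood Brownian fit
#'
#' Closed-form ML estimates: `x0` is the GLS mean
#' `(1' C^-1 x) / (1' C^-1 1)` and `sigma2` the ML (not REML) rate
#' `(x - x0)' C^-1 (x - x0) / N`, both read off a single pruning pass.
#'
#' @inheritParams bm_loglik
#' @return List with `params` (list `sigma2`, `x0`), `loglik`, `n_tips`,
#'   `model = "BM"`.
#' @export
fit_bm <- function(tree, traits) {
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("need at least 2 tips")
  st <- prune_stats(tree, traits)
  if (st$ss <= 0) stop("zero phylogenetic variance: all contrasts are zero")
  x0 <- st$xhat_root
  sigma2 <- st$ss / ntip
  list(model = "BM",
       params = list(sigma2 = sigma2, x0 = x0),
       loglik = loglik_from_stats(st, ntip, sigma2, x0),
       n_tips = ntip, converged = TRUE)
}

#' Ornstein-Uhlenbeck log-likelihood (fixed root at the optimum)
#'
#' Single-optimum OU on a possibly non-ultrametric tree, with the root state
#' fixed at the optimum `theta` (so the tip mean is `theta` everywhere). Tip
#' covariance uses the fixed-root (non-stationary) form
#' `Cov(i, j) = sigma2/(2 a) * exp(-a (d_i + d_j - 2 t_a)) * (1 - exp(-2 a t_a))`
#' with `d` the tip depths and `t_a` the MRCA depth; as `a -> 0` this
#' converges continuously to the Brownian covariance.
#'
#' @inheritParams bm_loglik
#' @param params List with `sigma2 > 0`, `alpha_ou >= 0` (constraint
#'   strength per unit branch length), `theta` (optimum, GC%).
#' @return The log-likelihood.
#' @export
ou_loglik <- function(tree, traits, params) {
  stopifnot(params$sigma2 > 0, params$alpha_ou >= 0)
  if (params$alpha_ou == 0) {
    return(bm_loglik(tree, traits,
                     list(sigma2 = params$sigma2, x0 = params$theta)))
  }
  x <- traits_in_tip_order(tree, traits)
  W <- ou_unit_covariance(tree, params$alpha_ou)
  dense_mvn_loglik(x, rep(params$theta, length(x)), params$sigma2 * W)
}

# Unit-rate fixed-root OU covariance (dense).
ou_unit_covariance <- function(tree, a) {
  Ca <- ape::vcv.phylo(tree)          # shared path lengths = MRCA depths
  d <- diag(Ca)
  exp(-a * (outer(d, d, "+") - 2 * Ca)) * (1 - exp(-2 * a * Ca)) / (2 * a)
}

dense_mvn_loglik <- function(x, mu, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("covariance matrix not positive definite")
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit
#'
#' Profiles the constraint strength `alpha_ou` on a log grid over
#' `[1e-8, 10 / tree height]` (plus the exact Brownian boundary
#' `alpha_ou = 0`), with `theta` and `sigma2` solved by GLS in closed form at
#' each `alpha_ou`. The root state is constrained to the optimum, the common
#' single-optimum default for non-ultrametric trees.
#'
#' @inheritParams bm_loglik
#' @param n_starts Number of local refinements of the profile grid.
#' @return List with `params` (`sigma2`, `alpha_ou`, `theta`), `loglik`,
#'   `n_tips`, `model = "OU"`, `converged`.
#' @export
fit_ou <- function(tree, traits, n_starts = 5) {
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("need at least 2 tips")
  x <- traits_in_tip_order(tree, traits)
  height <- max(node_depths(tree))
  if (height <= 0) stop("tree has zero height")

  profile <- function(a) {
    W <- ou_unit_covariance(tree, a)
    R <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(R)) return(list(loglik = -Inf))
    ones <- backsolve(R, rep(1, ntip), transpose = TRUE)
    xs <- backsolve(R, x, transpose = TRUE)
    theta <- sum(ones * xs) / sum(ones^2)
    q <- sum((xs - theta * ones)^2)
    if (q <= 0) return(list(loglik = -Inf))
    sigma2 <- q / ntip
    ll <- -0.5 * (ntip * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) +
                    ntip)
    list(loglik = ll, sigma2 = sigma2, theta = theta)
  }

  # Brownian boundary candidate (alpha_ou = 0) evaluated exactly.
  bm <- fit_bm(tree, traits)
  best <- list(loglik = bm$loglik, sigma2 = bm$params$sigma2,
               theta = bm$params$x0, alpha = 0)

  lo <- log(1e-8)
  hi <- log(10 / height)
  grid <- exp(seq(lo, hi, length.out = 24))
  for (refine in seq_len(n_starts)) {
    fits <- lapply(grid, profile)
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    k <- which.max(lls)
    # an interior optimum must beat the Brownian boundary by more than
    # numerical noise, otherwise the fit collapses to alpha_ou = 0
    if (lls[k] > best$loglik + 1e-7) {
      best <- c(fits[[k]], list(alpha = grid[k]))
    }
    # zoom around the current best grid point
    lg <- log(grid)
    span <- if (length(grid) > 1) diff(range(lg)) / (length(grid) - 1) else 1
    centre <- log(max(grid[k], 1e-8))
    grid <- exp(seq(max(lo, centre - span), min(hi, centre + span),
                    length.out = 9))
  }
  list(model = "OU",
       params = list(sigma2 = best$sigma2, alpha_ou = best$alpha,
                     theta = best$theta),
       loglik = best$loglik, n_tips = ntip, converged = TRUE)
}

#' Likelihood-ratio test for nested trait models
#'
#' Upper chi-square tail probability of `2 * (loglik_alt - loglik_null)` with
#' `df` degrees of freedom. Reported p-values are clamped below at
#' `p_floor = 1e-16`. For the Levy-jumps vs Brownian comparison `df = 2`
#' (jump rate and relative jump size added).
#'
#' @param loglik_alt,loglik_null Log-likelihoods of the nested pair; the
#'   alternative may not fall below the null by more than `tol` (that would
#'   signal broken optimisation).
#' @param df Positive integer degrees of freedom.
#' @param tol Tolerance for `loglik_alt < loglik_null`; raise it when the
#'   log-likelihoods are Monte-Carlo estimates.
#' @param p_floor Smallest reportable p-value.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(loglik_alt, loglik_null, df, tol = 1e-9, p_floor = 1e-16) {
  stopifnot(df >= 1)
  if (loglik_alt < loglik_null - tol) {
    stop("alternative log-likelihood below null (", loglik_alt, " < ",
         loglik_null, "): broken optimisation?")
  }
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = max(p, p_floor))
}

#' Compare BM, OU and Levy-jump fits on one dataset
#'
#' Convenience wrapper producing the model-comparison table used throughout
#' the analysis: BM and OU maximum likelihoods, the Levy fit's estimated
#' marginal log-likelihood, and the Levy-vs-BM likelihood-ratio test.
#'
#' @inheritParams bm_loglik
#' @param levy_fit A fit from [profile_alpha()] (or [fit_levy_em()]).
#' @param df Degrees of freedom for the Levy-vs-BM test (default 2).
#' @return List with the three fits and the `lrt` result.
#' @export
compare_models <- function(tree, traits, levy_fit, df = 2) {
  bm <- fit_bm(tree, traits)
  ou <- fit_ou(tree, traits)
  # Monte-Carlo loglik estimates can dip below the BM value by noise when
  # there are no jumps; use the estimator's standard error as tolerance.
  tol <- max(1e-9, 3 * (levy_fit$loglik_se %||% 0))
  test <- lrt(max(levy_fit$loglik, bm$loglik), bm$loglik, df = df, tol = tol)
  list(bm = bm, ou = ou, levy = levy_fit, lrt = test)
}

#' Serialise a model fit to the package's JSON report format
#'
#' @param fit A fit object from [fit_bm()], [fit_ou()], [fit_levy_em()] or
#'   [profile_alpha()].
#' @param path Output path; `NULL` returns the JSON string.
#' @param seed Seed to record, if any.
#' @return The JSON string, invisibly when written.
#' @export
write_fit_report <- function(fit, path = NULL, seed = NULL) {
  rep <- list(model = fit$model, params = unclass(fit$params), loglik = fit$loglik,
              n_tips = fit$n_tips, converged = isTRUE(fit$converged),
              seed = seed)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
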