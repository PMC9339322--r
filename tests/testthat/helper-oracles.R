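# Independent oracles used across the suite. These deliberately avoid the
# package's pruning machinery (and ape::vcv) so that agreement is a real
# cross-check: covariances come from explicit root-to-tip path enumeration,
# densities from dense Cholesky algebra.

# Edges on the root-to-node path, walking parent pointers.
path_edges <- function(tree, node) {
  out <- integer(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (!length(e)) break
    out <- c(out, e)
    node <- tree$edge[e, 1]
  }
  out
}

# Brute-force BM covariance: C[i, j] = total length of shared path edges.
pathwalk_covariance <- function(tree, elen = tree$edge.length) {
  ntip <- length(tree$tip.label)
  paths <- lapply(seq_len(ntip), function(i) path_edges(tree, i))
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}

dense_mvn <- function(x, mu, V) {
  R <- chol(V)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# Independent Levy marginal likelihood: recursive enumeration of counts with
# dense Gaussian densities over path-walk covariances.
bruteforce_levy_loglik <- function(tree, traits, params, n_max) {
  x <- unname(traits[tree$tip.label])
  nedge <- nrow(tree$edge)
  mu <- params$lam * tree$edge.length
  terms <- c()
  counts <- integer(nedge)
  recurse <- function(e) {
    if (e > nedge) {
      eff <- tree$edge.length + params$alpha * counts
      V <- params$sigma2_0 * pathwalk_covariance(tree, eff)
      lp <- sum(dpois(counts, mu, log = TRUE))
      terms <<- c(terms, lp + dense_mvn(x, rep(params$x0, length(x)), V))
      return(invisible())
    }
    for (k in 0:n_max) {
      counts[e] <<- k
      recurse(e + 1)
    }
    counts[e] <<- 0L
  }
  recurse(1L)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# Independent two-sided Fisher p: sum dhyper mass of tables no more probable
# than observed.
bruteforce_fisher_p <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small random non-ultrametric binary tree (independent of the package's
# Yule generator).
random_test_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- tr$edge.length + 0.05  # keep away from zero
  tr
}

make_traits <- function(tree, values) {
  stats::setNames(values, tree$tip.label)
}

reduced_em <- function(tree, traits, alpha, seed, em_max_iter = 30) {
  suppressWarnings(fit_levy_em(tree, traits, alpha = alpha, seed = seed,
                               em_max_iter = em_max_iter, mcmc_steps = 70,
                               n_e_samples = 20, loglik_particles = 16))
}
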