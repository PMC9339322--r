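#' Pooled precision and recall of inferred jump branches
#'
#' An inferred branch is a "true jump estimate" when the truth places at
#' least one simulated jump on it, otherwise a "false jump estimate".
#' Precision is `100 * TP / (TP + FP)`; recall is `100 * TP / (number of
#' simulated jumps)`. Numerators and denominators are summed across
#' simulations before dividing (pooling). When nothing is inferred anywhere,
#' precision is undefined and reported as `NA`, never 0 or 100.
#'
#' @param inferred List (one element per simulation) of integer vectors of
#'   inferred branch (edge) indices.
#' @param truth List (same length) of integer jump-count vectors per edge.
#' @param recall_denominator `"branches"` (default): branches carrying >= 1
#'   simulated jump, treating multiple jumps on a branch as one detectable
#'   event; `"events"`: raw jump counts.
#' @return List with `precision`, `recall` (percent), `n_true_est`,
#'   `n_false_est`, `n_sim_jumps`.
#' @export
precision_recall <- function(inferred, truth,
                             recall_denominator = c("branches", "events")) {
  recall_denominator <- match.arg(recall_denominator)
  stopifnot(length(inferred) == length(truth))
  tp <- fp <- denom <- 0L
  for (s in seq_along(truth)) {
    jumpy <- which(truth[[s]] >= 1L)
    inf <- unique(inferred[[s]])
    tp <- tp + sum(inf %in% jumpy)
    fp <- fp + sum(!(inf %in% jumpy))
    denom <- denom + if (recall_denominator == "branches") {
      length(jumpy)
    } else {
      sum(truth[[s]])
    }
  }
  list(precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
       recall = if (denom > 0) 100 * tp / denom else NA_real_,
       n_true_est = tp, n_false_est = fp, n_sim_jumps = denom)
}

#' Simulation-based calibration of the posterior-probability threshold
#'
#' Simulates datasets under the fitted Levy parameters on the given tree,
#' re-infers branch posteriors with the truth hidden (parameters fixed at
#' the values used to simulate, matching how the thresholds were calibrated
#' against real-data fits), classifies branches at each candidate threshold,
#' and pools precision/recall across simulations.
#'
#' @param tree A rooted `"phylo"`.
#' @param fitted A [levy_params()] object (the data fit).
#' @param n_simulations Number of independent simulated datasets (default 5).
#' @param thresholds Candidate pp thresholds in (0, 1); the default is a
#'   0.05-step grid plus 0.75, 0.9, 0.95.
#' @param seed Integer seed.
#' @param refit When `TRUE`, parameters are re-estimated on each simulated
#'   dataset (via [fit_levy_em()] at the fitted alpha) before computing
#'   posteriors.
#' @param mcmc_steps,burn_in Passed to [branch_jump_posteriors()].
#' @return A data frame of class `"calibration_curve"`: columns `threshold`,
#'   `precision_pct`, `recall_pct`, `n_true_est`, `n_false_est`,
#'   `n_sim_jumps`; attributes `per_simulation` (list of per-simulation
#'   curves), `truth` (list of true configurations), `posteriors` (list of
#'   pp vectors), `magnitudes` (list of per-branch true cumulative jump
#'   displacement proxies), `n_simulations`, `seed`.
#' @export
run_calibration <- function(tree, fitted, n_simulations = 5,
                            thresholds = default_thresholds(), seed = 1,
                            refit = FALSE, mcmc_steps = 4000, burn_in = 400) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  thresholds <- sort(unique(thresholds))
  truth <- list()
  pps <- list()
  mags <- list()
  for (s in seq_len(n_simulations)) {
    sim <- simulate_levy(tree, fitted, seed = derive_seed(seed, s))
    truth[[s]] <- sim$config
    mags[[s]] <- abs(sim$jump_disp)
    if (sum(sim$config) == 0) {
      message("calibration simulation ", s, " contains zero jumps ",
              "(contributes to precision only)")
    }
    params_s <- fitted
    if (refit) {
      fit_s <- fit_levy_em(tree, sim$traits, alpha = fitted$alpha,
                           seed = derive_seed(seed, 500 + s))
      params_s <- fit_s$params
    }
    post <- branch_jump_posteriors(tree, sim$traits, params_s,
                                   mcmc_steps = mcmc_steps,
                                   burn_in = burn_in,
                                   seed = derive_seed(seed, 1000 + s))
    pps[[s]] <- post$pp
  }
  curve <- do.call(rbind, lapply(thresholds, function(th) {
    inferred <- lapply(pps, function(pp) which(pp > th))
    pr <- precision_recall(inferred, truth)
    data.frame(threshold = th, precision_pct = pr$precision,
               recall_pct = pr$recall, n_true_est = pr$n_true_est,
               n_false_est = pr$n_false_est, n_sim_jumps = pr$n_sim_jumps)
  }))
  per_sim <- lapply(seq_len(n_simulations), function(s) {
    do.call(rbind, lapply(thresholds, function(th) {
      pr <- precision_recall(list(which(pps[[s]] > th)), truth[s])
      data.frame(threshold = th, precision_pct = pr$precision,
                 recall_pct = pr$recall)
    }))
  })
  attr(curve, "per_simulation") <- per_sim
  attr(curve, "truth") <- truth
  attr(curve, "posteriors") <- pps
  attr(curve, "magnitudes") <- mags
  attr(curve, "n_simulations") <- n_simulations
  attr(curve, "seed") <- seed
  class(curve) <- c("calibration_curve", "data.frame")
  curve
}

#' @rdname run_calibration
#' @export
default_thresholds <- function() {
  sort(unique(c(seq(0.05, 0.95, by = 0.05), 0.75, 0.9, 0.95)))
}

#' Choose the detection threshold from a calibration curve
#'
#' Among thresholds whose pooled precision reaches `min_precision`, returns
#' the one with maximum recall (ties broken toward the lower threshold).
#' When no threshold qualifies, the highest-precision threshold is returned
#' flagged `attainable = FALSE`. Thresholds where precision is undefined
#' (nothing inferred) are excluded from the rule.
#'
#' @param curve A `"calibration_curve"` from [run_calibration()].
#' @param min_precision Required pooled precision, percent (default 90).
#' @return List of class `"chosen_threshold"`: `threshold`,
#'   `precision_pct`, `recall_pct`, `attainable`, `n_simulations`.
#' @export
choose_threshold <- function(curve, min_precision = 90) {
  stopifnot(nrow(curve) >= 1)
  defined <- !is.na(curve$precision_pct)
  ok <- defined & curve$precision_pct >= min_precision
  if (any(ok)) {
    cand <- curve[ok, ]
    best <- cand[order(-cand$recall_pct, cand$threshold), ][1, ]
    attainable <- TRUE
  } else if (any(defined)) {
    cand <- curve[defined, ]
    best <- cand[order(-cand$precision_pct, cand$threshold), ][1, ]
    attainable <- FALSE
  } else {
    stop("precision undefined at every threshold (nothing was inferred)")
  }
  structure(list(threshold = best$threshold,
                 precision_pct = best$precision_pct,
                 recall_pct = best$recall_pct,
                 attainable = attainable,
                 n_simulations = attr(curve, "n_simulations") %||% NA_integer_),
            class = "chosen_threshold")
}

#' Recall stratified by true jump magnitude
#'
#' Pools calibration simulations and bins branches carrying simulated jumps
#' by the absolute cumulative trait displacement attributable to jumps on
#' them, then reports recall per bin at a given threshold. Mirrors the
#' observation that bigger jumps are recalled more often.
#'
#' @param curve A `"calibration_curve"` from [run_calibration()] (carries
#'   the truth, posteriors and true jump displacements as attributes).
#' @param threshold Detection threshold.
#' @param breaks Bin edges for |jump displacement| in GC%.
#' @return Data frame: `bin`, `n_jump_branches`, `n_recalled`, `recall_pct`.
#' @export
recall_by_magnitude <- function(curve, threshold,
                                breaks = c(0, 5, 10, 15, 20, Inf)) {
  truth <- attr(curve, "truth")
  pps <- attr(curve, "posteriors")
  mag <- attr(curve, "magnitudes")
  size <- unlist(lapply(seq_along(truth), function(s) {
    mag[[s]][truth[[s]] >= 1]
  }))
  hit <- unlist(lapply(seq_along(truth), function(s) {
    (pps[[s]] > threshold)[truth[[s]] >= 1]
  }))
  bin <- cut(size, breaks, right = FALSE)
  do.call(rbind, lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    data.frame(bin = b, n_jump_branches = length(idx),
               n_recalled = sum(hit[idx]),
               recall_pct = if (length(idx)) 100 * mean(hit[idx]) else NA_real_)
  }))
}
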