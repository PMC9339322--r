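#' Run the full GC-jump detection pipeline on one clade
#'
#' Executes the stages in analysis order: optional de-replication
#' subsampling; BM, OU and alpha-profiled Levy fits with the Levy-vs-BM
#' likelihood-ratio test; empirical-Bayes branch posteriors at the fitted
#' parameters; simulation-based threshold calibration (simulate with known
#' jumps, sweep thresholds, pick the smallest-loss threshold meeting the
#' precision rule); jump calls, sister-clade magnitudes and the direction
#' summary; the depth-randomisation placement test; and, when annotations
#' are supplied, ecological tallies with Fisher's exact test on direction
#' by host-switch direction. Intermediates are written to `out_dir` under
#' stable filenames when given.
#'
#' @param tree A rooted `"phylo"`, or a Newick path.
#' @param traits Named numeric GC vector, or a trait-TSV path.
#' @param annotations Optional annotations data frame (as from
#'   [read_ecology_annotations()]) or TSV path; rows are matched to calls by
#'   `jump_index`.
#' @param config List of stage settings; unset entries take the defaults of
#'   `pipeline_config()`.
#' @param out_dir Optional output directory.
#' @return List with every stage's result: `tree`, `models`
#'   (BM/OU/Levy/LRT), `posteriors`, `calibration`, `chosen_threshold`,
#'   `calls`, `magnitudes`, `directions`, `depth_test`, `ecology` (or
#'   `NULL`), `config`, `log`.
#' @export
run_gc_jump_pipeline <- function(tree, traits, annotations = NULL,
                                 config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(pipeline_config(), config)
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (is.character(annotations)) {
    annotations <- read_ecology_annotations(annotations)
  }
  log <- list()
  tick <- function(stage, ...) {
    log[[stage]] <<- c(list(stage = stage, time = Sys.time()), list(...))
  }

  if (!is.null(cfg$subsample_threshold)) {
    tree <- subsample_tree(tree, cfg$subsample_threshold)
    traits <- traits[tree$tip.label]
    tick("subsample", n_tips = length(tree$tip.label))
  }
  validate_traits(traits, tree)

  levy <- profile_alpha(tree, traits, alpha_grid = cfg$alpha_grid,
                        seed = cfg$seed, em_max_iter = cfg$em_max_iter,
                        mcmc_steps = cfg$em_mcmc_steps)
  models <- compare_models(tree, traits, levy, df = cfg$lrt_df)
  tick("fit", alpha = levy$params$alpha, lam = levy$params$lam,
       p_levy_vs_bm = models$lrt$p_value)

  posteriors <- branch_jump_posteriors(
    tree, traits, levy$params, mcmc_steps = cfg$pp_mcmc_steps,
    burn_in = cfg$pp_burn_in, seed = derive_seed(cfg$seed, 11))
  tick("posteriors", max_pp = max(posteriors$pp))

  calib <- run_calibration(tree, levy$params,
                           n_simulations = cfg$n_simulations,
                           thresholds = cfg$thresholds,
                           seed = derive_seed(cfg$seed, 12),
                           mcmc_steps = cfg$pp_mcmc_steps,
                           burn_in = cfg$pp_burn_in)
  chosen <- choose_threshold(calib, min_precision = cfg$min_precision)
  tick("calibration", threshold = chosen$threshold,
       precision = chosen$precision_pct, recall = chosen$recall_pct,
       attainable = chosen$attainable)

  calls <- call_jumps(posteriors, chosen)
  mags <- if (nrow(calls)) jump_magnitudes(tree, traits, calls) else NULL
  dirs <- if (!is.null(mags) && any(mags$available)) {
    direction_summary(mags)
  } else {
    NULL
  }
  depth <- if (nrow(calls)) {
    depth_randomization_test(tree, calls, n_random = cfg$n_random_depth,
                             seed = derive_seed(cfg$seed, 13))
  } else {
    NULL
  }
  tick("jumps", n_calls = nrow(calls))

  eco <- NULL
  if (!is.null(annotations) && !is.null(mags) && any(mags$available)) {
    eco <- ecology_analysis(mags, annotations)
    tick("ecology", fisher_p = eco$fisher$p_two_sided %||% NA_real_)
  }

  result <- list(tree = tree, models = models, posteriors = posteriors,
                 calibration = calib, chosen_threshold = chosen,
                 calls = calls, magnitudes = mags, directions = dirs,
                 depth_test = depth, ecology = eco, config = cfg, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @rdname run_gc_jump_pipeline
#' @export
pipeline_config <- function() {
  list(seed = 1,
       subsample_threshold = NULL,    # e.g. 0.01 substitutions/site
       alpha_grid = c(0.1, 0.25, 0.5, 1, 2, 4),
       em_max_iter = 40,
       em_mcmc_steps = 120,
       lrt_df = 2,
       pp_mcmc_steps = 4000,
       pp_burn_in = 400,
       n_simulations = 5,
       thresholds = default_thresholds(),
       min_precision = 90,
       n_random_depth = 1000)
}

# Direction-by-switch tallies and Fisher's exact test for a set of called
# jumps with annotations.
ecology_analysis <- function(magnitudes, annotations) {
  ok <- magnitudes$available & magnitudes$direction %in% c("up", "down")
  mg <- magnitudes[ok, ]
  idx <- match(mg$jump_index, annotations$jump_index)
  records <- data.frame(jump_index = mg$jump_index, direction = mg$direction)
  records$categories <- lapply(seq_len(nrow(mg)), function(i) {
    if (is.na(idx[i])) return("unknown")
    classify_switch(annotations[idx[i], ])
  })
  tallies <- tally_directions(records)
  fisher <- NULL
  gain <- tallies[tallies$category == "host_gain", ]
  loss <- tallies[tallies$category == "host_loss", ]
  if (nrow(gain) == 1 && nrow(loss) == 1 && gain$n + loss$n > 0) {
    tab <- rbind(c(gain$n_down, gain$n_up), c(loss$n_down, loss$n_up))
    fisher <- fisher_exact_2x2(tab)
  }
  list(records = records, tallies = tallies, fisher = fisher)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_newick(result$tree, p("tree_pp.nwk"),
               branch_annotations = stats::setNames(
                 as.list(sprintf("%.4f", result$posteriors$pp)),
                 seq_len(nrow(result$posteriors))))
  write_fit_report(result$models$bm, p("fit_bm.json"))
  write_fit_report(result$models$ou, p("fit_ou.json"))
  write_fit_report(result$models$levy, p("fit_levy.json"),
                   seed = result$config$seed)
  utils::write.table(as.data.frame(result$calibration), p("calibration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(result$chosen_threshold), p("threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$magnitudes)) {
    write_jump_table(result$magnitudes, p("jumps.tsv"))
  }
  if (!is.null(result$ecology)) {
    utils::write.table(result$ecology$tallies, p("ecology_tallies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$ecology$fisher)) {
      jsonlite::write_json(
        list(p_two_sided = result$ecology$fisher$p_two_sided,
             odds_ratio = result$ecology$fisher$odds_ratio),
        p("fisher.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out_dir)
}
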