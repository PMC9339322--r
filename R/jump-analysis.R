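#' Call jumps at a posterior-probability threshold
#'
#' Branches with pp strictly greater than the threshold are deemed to have
#' experienced a jump, and each receives a serial "jump index" assigned in
#' deterministic preorder traversal order of the tree.
#'
#' @param posteriors A `"branch_posteriors"` data frame from
#'   [branch_jump_posteriors()].
#' @param threshold A number in `[0, 1]` or a `"chosen_threshold"` from
#'   [choose_threshold()].
#' @return Data frame with columns `jump_index`, `edge`, `pp`,
#'   `child_label`; zero rows when nothing exceeds the threshold.
#' @export
call_jumps <- function(posteriors, threshold) {
  th <- if (inherits(threshold, "chosen_threshold")) threshold$threshold
        else threshold
  stopifnot(is.numeric(th), th >= 0, th <= 1)
  tree <- attr(posteriors, "tree")
  pre <- preorder_edge_ranks(tree)
  hit <- which(posteriors$pp > th)
  hit <- hit[order(pre[hit])]
  data.frame(jump_index = seq_along(hit), edge = hit,
             pp = posteriors$pp[hit],
             child_label = posteriors$child_label[hit])
}

preorder_edge_ranks <- function(tree) {
  pre <- ape::reorder.phylo(tree, "cladewise")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  match(key, paste(pre$edge[, 1], pre$edge[, 2]))
}

#' Jump direction and magnitude from sister-clade medians
#'
#' The magnitude of the jump on a called branch is the median GC content of
#' the tips descending from it minus the median GC of the tips descending
#' from its sister branch. Tips lying under any *other* called branch nested
#' inside either side are excluded first, so nested jumps do not contaminate
#' the estimate (applied on both the affected and the sister side).
#'
#' @param tree A rooted `"phylo"`; the called branch's parent must be
#'   binary so the sister is uniquely defined.
#' @param traits Named numeric tip GC vector.
#' @param call A single row of the [call_jumps()] table (or a list with
#'   `edge`; `pp`/`jump_index` carried through if present).
#' @param all_calls The full [call_jumps()] table (used for nested-jump
#'   exclusion; may be the same single row).
#' @return List with `edge`, `delta_gc`, `direction` (`"up"`, `"down"` or
#'   `"none"` at exactly zero), `n_affected_tips`, `n_sister_tips`.
#' @export
jump_magnitude <- function(tree, traits, call, all_calls = call) {
  edge <- call$edge
  stopifnot(length(edge) == 1)
  validate_traits(traits, tree)
  parent <- tree$edge[edge, 1]
  siblings <- which(tree$edge[, 1] == parent)
  if (length(siblings) != 2L) {
    stop("parent of called branch ", edge, " is not binary; ",
         "sister clade undefined")
  }
  sister_edge <- setdiff(siblings, edge)
  other <- setdiff(all_calls$edge, edge)
  affected <- excluded_tip_set(tree, edge, other)
  sister <- excluded_tip_set(tree, sister_edge, other)
  if (!length(affected)) {
    stop("jump call on edge ", edge,
         ": no affected tips remain after nested-jump exclusion")
  }
  if (!length(sister)) {
    stop("jump call on edge ", edge,
         ": no sister tips remain after nested-jump exclusion")
  }
  delta <- stats::median(traits[tree$tip.label[affected]]) -
    stats::median(traits[tree$tip.label[sister]])
  list(edge = edge, delta_gc = delta,
       direction = if (delta > 0) "up" else if (delta < 0) "down" else "none",
       n_affected_tips = length(affected), n_sister_tips = length(sister))
}

# Tips under `edge`, minus tips under any of `excl_edges` that are nested
# strictly inside it.
excluded_tip_set <- function(tree, edge, excl_edges) {
  tips <- tips_under_node(tree, tree$edge[edge, 2])
  for (e in excl_edges) {
    sub <- tips_under_node(tree, tree$edge[e, 2])
    if (all(sub %in% tips)) tips <- setdiff(tips, sub)
  }
  tips
}

#' Magnitudes for a whole table of jump calls
#'
#' Applies [jump_magnitude()] to every call; calls whose magnitude is
#' undefined (sister side fully excluded, or a polytomous parent) are
#' retained with `NA` and flagged `available = FALSE` rather than dropped.
#'
#' @inheritParams jump_magnitude
#' @param calls The [call_jumps()] table.
#' @return Data frame: `jump_index`, `edge`, `pp`, `delta_gc`, `direction`,
#'   `n_affected_tips`, `n_sister_tips`, `available`.
#' @export
jump_magnitudes <- function(tree, traits, calls) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    res <- tryCatch(jump_magnitude(tree, traits, calls[i, ], calls),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(jump_index = calls$jump_index[i], edge = calls$edge[i],
                 pp = calls$pp[i], delta_gc = NA_real_,
                 direction = NA_character_, n_affected_tips = NA_integer_,
                 n_sister_tips = NA_integer_, available = FALSE)
    } else {
      data.frame(jump_index = calls$jump_index[i], edge = calls$edge[i],
                 pp = calls$pp[i], delta_gc = res$delta_gc,
                 direction = res$direction,
                 n_affected_tips = res$n_affected_tips,
                 n_sister_tips = res$n_sister_tips, available = TRUE)
    }
  })
  do.call(rbind, rows)
}

#' Tally jump directions and median magnitudes
#'
#' @param magnitudes A data frame with columns `delta_gc` (and optionally
#'   `available`), e.g. from [jump_magnitudes()]; or a bare numeric vector
#'   of delta values.
#' @return List: `n_down`, `n_up`, `n_zero` (exact ties, counted
#'   separately), `median_abs_down`, `median_abs_up`.
#' @export
direction_summary <- function(magnitudes) {
  delta <- if (is.numeric(magnitudes)) {
    magnitudes
  } else {
    d <- magnitudes$delta_gc
    if (!is.null(magnitudes$available)) d <- d[magnitudes$available]
    d
  }
  delta <- delta[!is.na(delta)]
  if (!length(delta)) stop("no available magnitudes to summarise")
  down <- delta[delta < 0]
  up <- delta[delta > 0]
  list(n_down = length(down), n_up = length(up),
       n_zero = sum(delta == 0),
       median_abs_down = if (length(down)) stats::median(abs(down)) else NA_real_,
       median_abs_up = if (length(up)) stats::median(abs(up)) else NA_real_)
}

#' Are called jumps placed differently from branch-length-proportional
#' random jumps?
#'
#' Observed statistic: the branch-midpoint depths of the called branches.
#' Null: the same number of branches drawn with probability proportional to
#' branch length (with replacement), `n_random` times; draws are pooled into
#' a reference depth distribution. The Monte-Carlo p-value compares the
#' Kolmogorov-Smirnov distance of the observed depths from the pooled null
#' against the distances of the individual null draws (two-sided by
#' construction of the KS distance).
#'
#' @param tree A rooted `"phylo"`.
#' @param calls A [call_jumps()] table (>= 1 row).
#' @param n_random Number of null draws.
#' @param seed Integer seed.
#' @return List: `p_value`, `observed_depths`, `ks_distance`.
#' @export
depth_randomization_test <- function(tree, calls, n_random = 1000, seed = 1) {
  stopifnot(nrow(calls) >= 1)
  set.seed(seed)
  depths <- node_depths(tree)
  mid <- depths[tree$edge[, 1]] + tree$edge.length / 2
  obs <- mid[calls$edge]
  m <- length(obs)
  draws <- matrix(
    sample.int(nrow(tree$edge), m * n_random, replace = TRUE,
               prob = tree$edge.length),
    nrow = m)
  pooled <- mid[as.vector(draws)]
  ks_dist <- function(x, ref) {
    suppressWarnings(stats::ks.test(x, ref)$statistic)
  }
  if (length(unique(pooled)) == 1L && length(unique(obs)) == 1L &&
      obs[1] == pooled[1]) {
    return(list(p_value = 1, observed_depths = obs, ks_distance = 0))
  }
  d_obs <- ks_dist(obs, pooled)
  d_null <- vapply(seq_len(n_random), function(j) {
    ks_dist(mid[draws[, j]], pooled)
  }, numeric(1))
  p <- (1 + sum(d_null >= d_obs)) / (n_random + 1)
  list(p_value = p, observed_depths = unname(obs),
       ks_distance = unname(d_obs))
}

#' Export a jump table to TSV
#'
#' @param magnitudes A [jump_magnitudes()] data frame.
#' @param path Output file.
#' @param clade_id Identifier written into the first column.
#' @return The path, invisibly.
#' @export
write_jump_table <- function(magnitudes, path, clade_id = "clade") {
  out <- cbind(clade_id = clade_id, magnitudes)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
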