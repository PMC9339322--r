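#' Reported per-clade summary statistics for ten bacterial orders
#'
#' Summary values from a published genome-database-scale survey of GC
#' content evolution across ten order-level clades of Bacteroidetes and
#' Proteobacteria (GTDB release 80 phylogenies): maximum log-likelihoods of
#' the Brownian, single-optimum OU and Levy-jumps models, the Levy-vs-BM
#' likelihood-ratio p-value (floored at 1e-16), clade size, estimated
#' ancestral GC%, and the number of detected jumps with its down/up split.
#' Shipped as the worked-example input for the ecological analysis; the
#' clade phylogenies themselves are not included.
#'
#' @return Data frame with columns `clade`, `phylum`, `ml_bm`, `ml_ou`,
#'   `ml_levy`, `p_levy_vs_bm`, `n_taxa`, `ancestral_gc`, `n_jumps`,
#'   `n_down`, `n_up`.
#' @export
clade_summary <- function() {
  path <- system.file("extdata", "clade_summary.tsv", package = "gcjumps",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Reported direction-by-lifestyle jump counts
#'
#' Down/up jump tallies from the same survey for the jumps with usable
#' habitat information: all analysable jumps, the host-gain subset (affected
#' clade host-associated, sister free-living) and the host-loss subset (the
#' reverse switch). The marine subset (45 jumps) is not included because its
#' direction split was not reported.
#'
#' @return Data frame with columns `category`, `n_down`, `n_up`.
#' @export
host_switch_counts <- function() {
  path <- system.file("extdata", "host_switch_counts.tsv",
                      package = "gcjumps", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
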