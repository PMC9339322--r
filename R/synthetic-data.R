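#' Simulate a Yule (pure-birth) tree
#'
#' Lineages split at rate `birth_rate` each, starting from a root with two
#' lineages, until `n_tips` are alive; time then advances by one final
#' exponential holding time before the tree is cut, so the expected tip
#' depth at unit rate is `sum_{k=2}^{n} 1/k`. All tips are contemporaneous
#' (ultrametric) unless `jitter_sd > 0`, in which case each branch length is
#' multiplied by a mean-one lognormal factor to emulate the non-ultrametric
#' substitutions-per-site trees of real phylogenomic data.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param seed Integer seed; identical seeds give identical Newick output.
#' @param jitter_sd Lognormal sdlog of the multiplicative branch-length
#'   jitter (0 = none).
#' @return A rooted binary `"phylo"` with tip labels `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1,
                               jitter_sd = 0) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  set.seed(seed)
  # grow: active lineages carry (parent node id, birth time)
  ntip <- n_tips
  nnode <- 2L * ntip - 1L
  root <- ntip + 1L
  parent <- integer(nnode)
  birth <- numeric(nnode)
  next_internal <- root
  active <- c(root, root)       # parent node of each active lineage
  active_start <- c(0, 0)
  tnow <- 0
  while (length(active) < ntip) {
    k <- length(active)
    tnow <- tnow + stats::rexp(1, birth_rate * k)
    i <- sample.int(k, 1)
    next_internal <- next_internal + 1L
    parent[next_internal] <- active[i]
    birth[next_internal] <- tnow
    # lineage i ends at the new internal node; two new lineages start there
    active <- c(active[-i], next_internal, next_internal)
    active_start <- c(active_start[-i], tnow, tnow)
  }
  tnow <- tnow + stats::rexp(1, birth_rate * ntip)
  # remaining active lineages become tips (in a scrambled but seeded order)
  ord <- sample.int(ntip)
  edge <- matrix(0L, nnode - 1L, 2)
  elen <- numeric(nnode - 1L)
  e <- 0L
  for (i in seq_len(ntip)) {
    e <- e + 1L
    edge[e, ] <- c(active[i], ord[i])
    elen[e] <- tnow - active_start[i]
  }
  if (next_internal > root) {
    for (nd in (root + 1L):next_internal) {
      e <- e + 1L
      edge[e, ] <- c(parent[nd], nd)
      elen[e] <- birth[nd] - birth[parent[nd]]
    }
  }
  if (jitter_sd > 0) {
    elen <- elen * stats::rlnorm(length(elen), -jitter_sd^2 / 2, jitter_sd)
  }
  tree <- list(edge = edge, edge.length = elen,
               tip.label = paste0("t", seq_len(ntip)),
               Nnode = ntip - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "order") <- "cladewise"
  tree
}

#' Generate a complete synthetic GC-jump dataset
#'
#' One seeded call produces everything a pipeline run needs: a Yule tree
#' standing in for an order-level bacterial clade, tip GC values evolved
#' under the Levy-jumps model (optionally with reflecting boundaries on the
#' attainable GC range), the hidden truth (jump configuration and the
#' generating parameters), and per-jump ecological annotations whose
#' association between jump direction and host-switch direction is
#' controlled by `ecology_effect`.
#'
#' @param n_tips Tips in the clade (real order-level clades span roughly
#'   200-800).
#' @param params A [levy_params()] object.
#' @param gc_bounds Optional `c(low, high)` reflecting boundaries in GC%
#'   (the observed bacterial range is roughly 25-75).
#' @param ecology_effect Number in `[-1, 1]`: 0 makes host-switch direction
#'   independent of jump direction; positive values tilt down-jumps toward
#'   host gain (`P(host_gain | down) = 0.5 + effect/2`).
#' @param seed Integer seed.
#' @param birth_rate,jitter_sd Passed to [simulate_yule_tree()].
#' @return List of class `"gc_jump_dataset"`: `tree`, `traits`, `truth`
#'   (list `config`, `jump_disp`, `params`), `annotations` (one row per
#'   jump branch), `seed`.
#' @export
generate_dataset <- function(n_tips, params, gc_bounds = NULL,
                             ecology_effect = 0, seed = 1, birth_rate = 1,
                             jitter_sd = 0.3) {
  stopifnot(abs(ecology_effect) <= 1)
  tree <- simulate_yule_tree(n_tips, birth_rate, seed = derive_seed(seed, 1),
                             jitter_sd = jitter_sd)
  sim <- simulate_levy(tree, params, seed = derive_seed(seed, 2),
                       gc_bounds = gc_bounds)
  set.seed(derive_seed(seed, 3))
  jump_edges <- which(sim$config >= 1L)
  ann <- NULL
  if (length(jump_edges)) {
    # realised branch change (after any boundary reflection): near a GC
    # ceiling an upward jump folds back down, which is what tilts jump
    # direction against the ancestral state
    realised <- sim$node_values[tree$edge[jump_edges, 2]] -
      sim$node_values[tree$edge[jump_edges, 1]]
    dirn <- ifelse(realised >= 0, "up", "down")
    p_gain <- ifelse(dirn == "down", 0.5 + ecology_effect / 2,
                     0.5 - ecology_effect / 2)
    gain <- stats::runif(length(jump_edges)) < p_gain
    ann <- data.frame(
      edge = jump_edges,
      direction = dirn,
      affected_host = ifelse(gain, "host_associated", "not_host_dependent"),
      sister_host = ifelse(gain, "not_host_dependent", "host_associated"),
      marine = stats::runif(length(jump_edges)) < 0.3,
      affected_oxygen = sample(OXYGEN_LEVELS[1:4], length(jump_edges),
                               replace = TRUE),
      sister_oxygen = sample(OXYGEN_LEVELS[1:4], length(jump_edges),
                             replace = TRUE))
  }
  structure(list(tree = tree, traits = sim$traits,
                 truth = list(config = sim$config,
                              jump_disp = sim$jump_disp, params = params),
                 annotations = ann, seed = seed),
            class = "gc_jump_dataset")
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' Emits `tree.nwk`, `gc.tsv` and `annotations.tsv` (the formats the
#' inference side reads) plus `truth.json`, a sidecar holding the hidden
#' jump configuration and generating parameters that inference code never
#' reads.
#'
#' @param dataset A `"gc_jump_dataset"` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write_trait_table(dataset$traits, file.path(dir, "gc.tsv"))
  if (!is.null(dataset$annotations)) {
    ann <- dataset$annotations
    long <- rbind(
      data.frame(clade_id = "synthetic", jump_index = seq_len(nrow(ann)),
                 side = "affected", host_status = ann$affected_host,
                 marine = ann$marine, oxygen_class = ann$affected_oxygen,
                 source_note = "synthetic"),
      data.frame(clade_id = "synthetic", jump_index = seq_len(nrow(ann)),
                 side = "sister", host_status = ann$sister_host,
                 marine = ann$marine, oxygen_class = ann$sister_oxygen,
                 source_note = "synthetic"))
    utils::write.table(long, file.path(dir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- list(config = dataset$truth$config,
                jump_disp = dataset$truth$jump_disp,
                params = unclass(dataset$truth$params),
                seed = dataset$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
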