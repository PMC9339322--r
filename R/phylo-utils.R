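#' Root-to-node path lengths
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric vector over all nodes (tips `1..N` then internals),
#'   `depth(root) = 0`, `depth(child) = depth(parent) + branch length`.
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  d <- ape::node.depth.edgelength(tree)
  names(d) <- node_names(tree)
  d
}

node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  c(tree$tip.label, paste0("node", (ntip + 1L):nnode))
}

# Clade height of every node: maximum path length from the node down to any
# descendant tip (0 at tips).
clade_heights <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  h <- numeric(nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]
    c <- po$edge[i, 2]
    h[p] <- max(h[p], h[c] + po$edge.length[i])
  }
  h
}

# Tip indices descending from each node (phangorn; includes the node itself
# for tips).
tips_under_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  phangorn::Descendants(tree, node, type = "tips")[[1]]
}

#' De-replicate a phylogeny by collapsing young clades
#'
#' Every maximal clade whose height (largest node-to-descendant-tip path
#' length) is below `age_threshold` is collapsed to a single representative
#' tip: the lexicographically smallest tip label, so the result is
#' reproducible without random state. Branch lengths through removed unary
#' nodes are summed. This removes redundant near-identical strains before
#' model fitting, mirroring de-replication of densely sequenced species at
#' 0.01 substitutions per site.
#'
#' @param tree A `"phylo"` object.
#' @param age_threshold Clade-height threshold, substitutions per site;
#'   must be positive.
#' @return The pruned `"phylo"`; unchanged if no clade is younger than the
#'   threshold.
#' @export
subsample_tree <- function(tree, age_threshold) {
  stopifnot(inherits(tree, "phylo"), age_threshold > 0)
  ntip <- length(tree$tip.label)
  h <- clade_heights(tree)
  drop <- character(0)
  # preorder walk; stop descending at the first (maximal) young clade
  children <- split(tree$edge[, 2], tree$edge[, 1])
  visit <- function(node) {
    if (node <= ntip) return(invisible())
    if (h[node] < age_threshold) {
      tips <- tree$tip.label[tips_under_node(tree, node)]
      keep <- sort(tips)[1]
      drop <<- c(drop, setdiff(tips, keep))
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) visit(ch)
  }
  visit(ntip + 1L)
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

#' Phylogenetically independent contrasts
#'
#' Standard variance-scaled contrasts (Felsenstein's algorithm with
#' branch-length inflation propagated rootward), computed via [ape::pic()].
#' Requires a fully bifurcating tree; polytomies are rejected explicitly
#' because silent resolution would change the contrasts.
#'
#' @param tree A binary rooted `"phylo"`.
#' @param traits Named numeric vector of tip GC percentages.
#' @return Numeric vector of `N - 1` scaled contrasts, named by the internal
#'   node they were computed at.
#' @export
pic_contrasts <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (tree$Nnode != ntip - 1L) {
    stop("tree has polytomies; resolve them (e.g. with zero-length ",
         "branches via ape::multi2di) before computing contrasts")
  }
  x <- traits_in_tip_order(tree, traits)
  if (any_zero_contrast_denominator(tree)) {
    stop("zero contrast denominator: both branches at a contrast node have ",
         "zero length")
  }
  ape::pic(stats::setNames(x, tree$tip.label), tree)
}

# A contrast node with both (inflated) child branch variances zero makes the
# scaled contrast undefined. Detect by running the inflation recursion on
# branch lengths alone.
any_zero_contrast_denominator <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  flag <- FALSE
  rec <- function(node) {
    if (node <= ntip) return(0)
    e <- kids[[as.character(node)]]
    V <- tree$edge.length[e] + vapply(tree$edge[e, 2], rec, numeric(1))
    if (sum(V) <= 0) flag <<- TRUE
    if (flag) return(0)
    prod(V) / sum(V)
  }
  rec(ntip + 1L)
  flag
}

#' Sample excess kurtosis
#'
#' Central-moment estimator `m4 / m2^2 - 3` with no small-sample correction;
#' positive values diagnose fat-tailed contrast distributions, the signature
#' of jump-contaminated (non-Brownian) trait evolution.
#'
#' @param values Numeric vector, at least 4 values with nonzero variance.
#' @return The excess kurtosis (0 for a normal distribution).
#' @export
excess_kurtosis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("zero variance")
  mean((values - m)^4) / m2^2 - 3
}

# --- internal plumbing shared by the model code ------------------------------

# Pruning summaries (root estimate, its variance, quadratic form, log
# determinant contribution) for BM with the given effective branch lengths.
prune_stats <- function(tree, traits, eff = tree$edge.length) {
  x <- traits_in_tip_order(tree, traits)
  st <- prune_stats_cpp(tree$edge, length(tree$tip.label), eff, x)
  if (!isTRUE(st$ok)) {
    bad <- st$bad_node
    tips <- tree$tip.label[tips_under_node(tree, bad)]
    stop("singular phylogenetic covariance: zero-distance tips under node ",
         bad, " (", paste(utils::head(tips, 2), collapse = ", "), ")")
  }
  st
}

# Deterministic seed derivation for sub-streams; stays inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647) + 1L
}
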