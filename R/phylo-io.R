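#' Read a rooted phylogeny from a Newick file
#'
#' Parses a Newick tree with mandatory branch lengths. Branch comments in the
#' dialect `[&key=value,...]` (placed after a tip/node label and before the
#' colon) are extracted and attached to the edge above the commented node; a
#' plain tree without comments parses unchanged. Topology parsing is
#' delegated to [ape::read.tree()] after a syntax pre-scan that reports the
#' byte offset of the first structural error.
#'
#' @param path Path to a Newick file (single tree).
#' @return An object of class `"phylo"` (see \pkg{ape}), with an additional
#'   attribute `branch_annotations`: a named list per annotated edge index
#'   (row of `tree$edge`), each a named character vector of key/value pairs.
#'   `NULL`-length attribute when the file carries no comments.
#' @details All per-branch vectors in this package (jump counts, posterior
#'   probabilities) align with rows of `tree$edge`; an edge is identified by
#'   its row index, and named by the label of its child node.
#' @seealso [write_newick()]
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  read_newick_string(txt)
}

#' @rdname read_newick
#' @param text A Newick string (alternative entry point used by tests).
#' @export
read_newick_string <- function(text) {
  check_newick_syntax(text)
  ann <- extract_annotations(text)
  tree <- tryCatch(
    ape::read.tree(text = ann$text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse failure: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("Newick parse failure: ape could not read the tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("missing branch length(s): every branch must carry a length")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  annotations <- restore_annotations(tree, ann$map)
  tree <- annotations$tree
  if (length(annotations$by_edge)) {
    attr(tree, "branch_annotations") <- annotations$by_edge
  }
  tree
}

# Structural pre-scan: balanced parentheses and a terminating semicolon,
# reporting 1-based byte offsets.
check_newick_syntax <- function(text) {
  bytes <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(bytes)) {
    ch <- bytes[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick format error at byte %d: unmatched ')'", i))
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf(
      "Newick format error at byte %d: %d unclosed '('", nchar(text), depth))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf(
      "Newick format error at byte %d: missing terminating ';'", nchar(text)))
  }
  invisible(TRUE)
}

# Replace [&...] comments with label-suffix tokens ape can carry through.
extract_annotations <- function(text) {
  map <- list()
  i <- 0L
  repeat {
    m <- regexpr("\\[&[^]]*\\]", text)
    if (m == -1L) break
    i <- i + 1L
    tok <- sprintf("xGCJANNx%d", i)
    comment <- substr(text, m + 2L, m + attr(m, "match.length") - 2L)
    map[[tok]] <- parse_annotation(comment)
    text <- paste0(substr(text, 1L, m - 1L), tok,
                   substr(text, m + attr(m, "match.length"), nchar(text)))
  }
  list(text = text, map = map)
}

parse_annotation <- function(comment) {
  parts <- strsplit(comment, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else NA_character_,
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  vals
}

restore_annotations <- function(tree, map) {
  by_edge <- list()
  strip <- function(labels, node_ids) {
    for (k in seq_along(labels)) {
      lab <- labels[k]
      m <- regexpr("xGCJANNx[0-9]+$", lab)
      if (m != -1L) {
        tok <- substr(lab, m, nchar(lab))
        labels[k] <- substr(lab, 1L, m - 1L)
        e <- which(tree$edge[, 2] == node_ids[k])
        if (length(e) != 1L) {
          stop("annotation attached to a node with no parent branch")
        }
        by_edge[[as.character(e)]] <<- map[[tok]]
      }
    }
    labels
  }
  ntip <- length(tree$tip.label)
  tree$tip.label <- strip(tree$tip.label, seq_len(ntip))
  if (!is.null(tree$node.label)) {
    tree$node.label <- strip(tree$node.label, ntip + seq_along(tree$node.label))
    if (all(tree$node.label == "")) tree$node.label <- NULL
  }
  list(tree = tree, by_edge = by_edge)
}

#' Write a phylogeny to Newick, optionally with per-branch annotations
#'
#' Plain trees are serialised with [ape::write.tree()]. When
#' `branch_annotations` is given, each annotated branch's child element gains
#' a comment `[&key=value]` after its label (before the colon), the dialect
#' [read_newick()] understands; posterior-probability-annotated trees use the
#' key `pp`.
#'
#' @param tree A `"phylo"` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @param branch_annotations Optional named list or vector: names are edge
#'   indices (rows of `tree$edge`), values either a single value or a named
#'   vector of key/value pairs. A bare numeric vector is written under the
#'   key `pp`.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, branch_annotations = NULL,
                         digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(branch_annotations)) {
    out <- ape::write.tree(tree, digits = digits)
  } else {
    nedge <- nrow(tree$edge)
    ann <- normalise_annotations(branch_annotations, nedge)
    out <- write_newick_annotated(tree, ann, digits)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

normalise_annotations <- function(x, nedge) {
  if (is.numeric(x) && !is.list(x)) {
    x <- lapply(x, function(v) c(pp = format(v, digits = 6)))
    names(x) <- names(x) %||% stop("annotation vector must be named by edge")
  }
  idx <- suppressWarnings(as.integer(names(x)))
  if (anyNA(idx) || any(idx < 1L) || any(idx > nedge)) {
    stop("annotation key is not a branch: edge indices must be in 1..", nedge)
  }
  stats::setNames(x, idx)
}

write_newick_annotated <- function(tree, ann, digits) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) format(x, digits = digits, scientific = FALSE,
                                trim = TRUE)
  fmt_ann <- function(e) {
    a <- ann[[as.character(e)]]
    if (is.null(a)) return("")
    kv <- if (is.null(names(a))) {
      paste0("pp=", a)
    } else {
      paste0(names(a), "=", unname(a), collapse = ",")
    }
    paste0("[&", kv, "]")
  }
  rec <- function(node, edge_above) {
    body <- if (node <= ntip) {
      tree$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      inner <- vapply(kids, function(e) rec(tree$edge[e, 2], e), character(1))
      lab <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
      paste0("(", paste(inner, collapse = ","), ")", lab)
    }
    if (is.na(edge_above)) return(paste0(body, ";"))
    paste0(body, fmt_ann(edge_above), ":", fmt_len(tree$edge.length[edge_above]))
  }
  rec(ntip + 1L, NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write tip-trait tables
#'
#' A trait table maps tip labels to genomic GC percentages. On disk it is a
#' TSV with header `tip_label<TAB>gc_percent`.
#'
#' @param path Path to the TSV file.
#' @param tree Optional `"phylo"`; when given, labels are checked against its
#'   tips.
#' @return A named numeric vector (names are tip labels, values GC%).
#' @export
read_trait_table <- function(path, tree = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("tip_label", "gc_percent") %in% names(df))) {
    stop("trait TSV must have header 'tip_label<TAB>gc_percent'")
  }
  traits <- stats::setNames(as.numeric(df$gc_percent), df$tip_label)
  validate_traits(traits, tree, range = c(0, 100))
  traits
}

#' @rdname read_trait_table
#' @param traits Named numeric vector of GC percentages.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(
    data.frame(tip_label = names(traits), gc_percent = unname(traits)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_traits <- function(traits, tree = NULL, range = NULL) {
  if (is.null(names(traits)) || anyDuplicated(names(traits))) {
    stop("trait table must be uniquely named by tip label")
  }
  if (!is.null(range) && any(traits < range[1] | traits > range[2])) {
    stop("GC percentages must lie in [", range[1], ", ", range[2], "]")
  }
  if (!is.null(tree)) {
    missing <- setdiff(tree$tip.label, names(traits))
    if (length(missing)) {
      stop("missing trait for tip(s): ", paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(traits), tree$tip.label)
    if (length(extra)) {
      stop("trait table has labels not in the tree: ",
           paste(extra, collapse = ", "))
    }
  }
  invisible(traits)
}

# Traits in the tree's tip order, after validation.
traits_in_tip_order <- function(tree, traits) {
  validate_traits(traits, tree)
  unname(traits[tree$tip.label])
}
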