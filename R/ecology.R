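HOST_LEVELS <- c("host_dependent", "host_associated", "not_host_dependent",
                 "unknown")
OXYGEN_LEVELS <- c("anaerobic", "facultative", "aerobic", "obligately_aerobic",
                   "unknown")
# ordered oxygen scale: anaerobic < facultative < aerobic <= obligately_aerobic
OXYGEN_RANK <- c(anaerobic = 1, facultative = 2, aerobic = 3,
                 obligately_aerobic = 3, unknown = NA)

#' Classify the ecological switch implied by a jump's annotation
#'
#' Deterministic rules over the closed vocabularies. `host_gain`: affected
#' clade host-associated or host-dependent while the sister is not host
#' dependent (a putative switch from free-living to host association);
#' `host_loss`: the reverse; `obligate_host`: the affected clade is strictly
#' host dependent; `oxygen_up` / `oxygen_down`: movement along the ordered
#' oxygen-dependence scale; `marine`: affected clade isolated from a marine
#' habitat. Any `unknown` on a side propagates to the label `unknown` for
#' that comparison; it is never guessed.
#'
#' @param annotation List or one-row data frame with fields
#'   `affected_host`, `sister_host` (values `host_dependent`,
#'   `host_associated`, `not_host_dependent`, `unknown`), `marine`
#'   (logical), `affected_oxygen`, `sister_oxygen` (values `anaerobic`,
#'   `facultative`, `aerobic`, `obligately_aerobic`, `unknown`).
#' @return Character vector of zero or more category labels (multi-label).
#' @export
classify_switch <- function(annotation) {
  a <- annotation
  chk <- function(x, levels, what) {
    if (!x %in% levels) {
      stop("invalid ", what, " value '", x, "'; must be one of: ",
           paste(levels, collapse = ", "))
    }
    x
  }
  ah <- chk(a$affected_host, HOST_LEVELS, "host status")
  sh <- chk(a$sister_host, HOST_LEVELS, "host status")
  ao <- chk(a$affected_oxygen %||% "unknown", OXYGEN_LEVELS, "oxygen class")
  so <- chk(a$sister_oxygen %||% "unknown", OXYGEN_LEVELS, "oxygen class")
  out <- character(0)
  hosty <- c("host_dependent", "host_associated")
  if (ah == "unknown" || sh == "unknown") {
    out <- c(out, "unknown")
  } else {
    if (ah == "host_dependent") out <- c(out, "obligate_host")
    if (ah %in% hosty && sh == "not_host_dependent") out <- c(out, "host_gain")
    if (ah == "not_host_dependent" && sh %in% hosty) out <- c(out, "host_loss")
    if (!any(c("host_gain", "host_loss") %in% out)) out <- c(out, "no_switch")
  }
  if (isTRUE(a$marine)) out <- c(out, "marine")
  ra <- OXYGEN_RANK[[ao]]
  rs <- OXYGEN_RANK[[so]]
  if (!is.na(ra) && !is.na(rs)) {
    if (ra > rs) out <- c(out, "oxygen_up")
    if (ra < rs) out <- c(out, "oxygen_down")
  }
  unique(out)
}

#' Tally jump directions within ecological categories
#'
#' @param records Data frame with one row per jump: a `direction` column
#'   (`"up"`/`"down"`) and a `categories` list-column (each element a
#'   character vector from [classify_switch()]); rows labelled `unknown`
#'   contribute only to the `unknown` category.
#' @return Data frame per category: `category`, `n_down`, `n_up`, `n`,
#'   `pct_down`, `pct_up` (unrounded), `pct_down_display`,
#'   `pct_up_display` (rounded half-up to integers, the convention used for
#'   display).
#' @export
tally_directions <- function(records) {
  stopifnot(nrow(records) >= 1)
  cats <- sort(unique(unlist(records$categories)))
  rows <- lapply(cats, function(cat) {
    in_cat <- vapply(records$categories, function(cs) cat %in% cs, logical(1))
    nd <- sum(records$direction[in_cat] == "down")
    nu <- sum(records$direction[in_cat] == "up")
    n <- nd + nu
    data.frame(category = cat, n_down = nd, n_up = nu, n = n,
               pct_down = if (n) 100 * nd / n else NA_real_,
               pct_up = if (n) 100 * nu / n else NA_real_,
               pct_down_display = if (n) round_half_up(100 * nd / n) else NA,
               pct_up_display = if (n) round_half_up(100 * nu / n) else NA)
  })
  do.call(rbind, rows)
}

round_half_up <- function(x) floor(x + 0.5)

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood method: with margins
#' fixed, sum the hypergeometric probabilities of every table at most as
#' probable as the observed one (a relative tolerance of 1e-7 guards
#' floating-point ties, as is conventional). Implemented directly from
#' log-factorials. The odds ratio is the sample odds ratio `ad/bc`, with a
#' Haldane-Anscombe 0.5 correction applied to all cells when any cell is
#' zero.
#'
#' @param table A 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`
#'   (rows: lifestyle-switch direction; columns: jump direction), or the four
#'   counts `a, b, c, d` given separately.
#' @param b,c_,d Optional scalar counts when `table` is given as `a`.
#' @return List of class `"fisher_result"`: `p_two_sided`, `odds_ratio`,
#'   `table`.
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c_ = NULL, d = NULL) {
  m <- if (is.matrix(table)) table else rbind(c(table, b), c(c_, d))
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), all(m == round(m)))
  if (sum(m) == 0) stop("all-zero table")
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  log_hyper <- function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  }
  lp <- vapply(lo:hi, log_hyper, numeric(1))
  lp_obs <- log_hyper(a)
  keep <- lp <= lp_obs + 1e-7
  p <- exp(logsumexp(lp[keep]))
  mm <- if (any(m == 0)) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  structure(list(p_two_sided = min(p, 1), odds_ratio = or, table = m),
            class = "fisher_result")
}

#' Read per-jump ecological annotations from TSV
#'
#' Long format, two rows per jump: columns `clade_id`, `jump_index`, `side`
#' (`affected` or `sister`), `host_status`, `marine`, `oxygen_class`,
#' `source_note`. Returned wide, one row per jump, ready for
#' [classify_switch()].
#'
#' @param path TSV path.
#' @return Data frame with columns `clade_id`, `jump_index`,
#'   `affected_host`, `sister_host`, `marine`, `affected_oxygen`,
#'   `sister_oxygen`.
#' @export
read_ecology_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("clade_id", "jump_index", "side", "host_status", "marine",
            "oxygen_class")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  wide <- lapply(split(df, list(df$clade_id, df$jump_index), drop = TRUE),
                 function(g) {
    aff <- g[g$side == "affected", ]
    sis <- g[g$side == "sister", ]
    if (nrow(aff) != 1 || nrow(sis) != 1) {
      stop("each (clade, jump) needs exactly one 'affected' and one ",
           "'sister' row")
    }
    data.frame(clade_id = aff$clade_id, jump_index = aff$jump_index,
               affected_host = aff$host_status, sister_host = sis$host_status,
               marine = as.logical(aff$marine),
               affected_oxygen = aff$oxygen_class,
               sister_oxygen = sis$oxygen_class)
  })
  out <- do.call(rbind, wide)
  rownames(out) <- NULL
  out[order(out$clade_id, out$jump_index), ]
}
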