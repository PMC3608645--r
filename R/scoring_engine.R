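#' Reliability score for expression status
#'
#' Vote-counting consensus across datasets: each dataset asserting that a
#' gene is expressed in the given condition contributes two points to the
#' expressed score, and likewise for not-detected. Opposing calls are never
#' netted against each other — both scores are kept, and a `consistent`
#' flag records whether exactly one side has support. A dataset counts at
#' most once per status (duplicates are collapsed at ingestion).
#'
#' @param symbol Gene symbol (canonicalized against the corpus alias map).
#' @param condition Canonical condition label.
#' @param corpus A [corpus()].
#' @return An object of class `status_score`: list with `symbol`,
#'   `condition`, `expressed_score`, `not_detected_score`, `n_expressed`,
#'   `n_not_detected`, `consistent`.
#' @export
#' @examples
#' # a gene reported expressed by 6 of 6 datasets scores 12
score_status <- function(symbol, condition, corpus) {
  stopifnot(inherits(corpus, "rag_corpus"))
  symbol <- normalize_symbol(symbol)
  if (length(symbol) != 1) stop("score_status takes one symbol")
  if (!is_known_condition(condition))
    stop("unknown condition '", condition, "'")
  symbol <- unname(c(corpus$alias_map, stats::setNames(symbol, symbol))[symbol])
  calls <- corpus_calls(corpus)
  sel <- calls[calls$symbol == symbol & !is.na(calls$condition) &
                 calls$condition == condition, , drop = FALSE]
  n_exp <- length(unique(sel$dataset_id[sel$call == "expressed"]))
  n_nd <- length(unique(sel$dataset_id[sel$call == "not_detected"]))
  new_status_score(symbol, condition, n_exp, n_nd)
}

new_status_score <- function(symbol, condition, n_expressed, n_not_detected) {
  structure(
    list(symbol = symbol, condition = condition,
         expressed_score = 2L * n_expressed,
         not_detected_score = 2L * n_not_detected,
         n_expressed = as.integer(n_expressed),
         n_not_detected = as.integer(n_not_detected),
         consistent = xor(n_expressed > 0, n_not_detected > 0)),
    class = "status_score"
  )
}

#' Reliability score for expression pattern
#'
#' Counts datasets reporting a gene up- or down-regulated on an ordered
#' condition comparison. `up` means higher in the first-named condition of
#' the pair; a dataset curated against the reversed pair has its calls
#' direction-flipped before counting, so the score is invariant to how the
#' source study oriented its contrast.
#'
#' @param symbol Gene symbol.
#' @param comparison Ordered condition pair (length-2 vector or
#'   `"<a>_vs_<b>"` string), see [parse_comparison()].
#' @param corpus A [corpus()].
#' @return An object of class `pattern_score`: list with `symbol`,
#'   `comparison`, `up_score`, `down_score`, `n_up`, `n_down`, `consistent`.
#' @export
score_pattern <- function(symbol, comparison, corpus) {
  stopifnot(inherits(corpus, "rag_corpus"))
  symbol <- normalize_symbol(symbol)
  if (length(symbol) != 1) stop("score_pattern takes one symbol")
  cmp <- parse_comparison(comparison)
  symbol <- unname(c(corpus$alias_map, stats::setNames(symbol, symbol))[symbol])
  fwd <- comparison_id(cmp)
  rev_ <- comparison_id(rev(cmp))
  calls <- corpus_calls(corpus)
  sel <- calls[calls$symbol == symbol & !is.na(calls$comparison) &
                 calls$comparison %in% c(fwd, rev_), , drop = FALSE]
  # flip reversed-orientation calls into the requested direction
  eff <- ifelse(sel$comparison == fwd, sel$call,
                ifelse(sel$call == "up", "down", "up"))
  n_up <- length(unique(sel$dataset_id[eff == "up"]))
  n_down <- length(unique(sel$dataset_id[eff == "down"]))
  new_pattern_score(symbol, fwd, n_up, n_down)
}

new_pattern_score <- function(symbol, comparison_id, n_up, n_down) {
  structure(
    list(symbol = symbol, comparison = comparison_id,
         up_score = 2L * n_up, down_score = 2L * n_down,
         n_up = as.integer(n_up), n_down = as.integer(n_down),
         consistent = xor(n_up > 0, n_down > 0)),
    class = "pattern_score"
  )
}

#' Combine status and pattern scores into cumulative scores
#'
#' The cumulative Up-Ex score is the sum of the expressed score and the
#' upregulation score; the cumulative Down-Nd score sums the not-detected
#' and downregulation scores. Both are always computed — classification into
#' RAG sets is a separate step ([derive_rags()]).
#'
#' @param status A `status_score` for the gene, in the first condition of
#'   the pattern's comparison.
#' @param pattern A `pattern_score` for the same gene.
#' @return An object of class `gene_score_card`.
#' @export
#' @examples
#' # expressed in 6 datasets (12) + up in 9 (18) -> cumulative Up-Ex 30
cumulative_scores <- function(status, pattern) {
  stopifnot(inherits(status, "status_score"), inherits(pattern, "pattern_score"))
  if (status$symbol != pattern$symbol)
    stop("status and pattern scores refer to different symbols: ",
         status$symbol, " vs ", pattern$symbol)
  first_cond <- strsplit(pattern$comparison, "_vs_", fixed = TRUE)[[1]][1]
  if (status$condition != first_cond)
    stop("status condition '", status$condition,
         "' is not the first member of the comparison '", pattern$comparison, "'")
  structure(
    list(symbol = status$symbol, status = status, pattern = pattern,
         cumulative_upex = pattern$up_score + status$expressed_score,
         cumulative_downnd = pattern$down_score + status$not_detected_score),
    class = "gene_score_card"
  )
}

#' @export
print.gene_score_card <- function(x, ...) {
  cat(sprintf(
    "%s: expressed %d / not-detected %d | up %d / down %d | Up-Ex %d, Down-Nd %d\n",
    x$symbol, x$status$expressed_score, x$status$not_detected_score,
    x$pattern$up_score, x$pattern$down_score,
    x$cumulative_upex, x$cumulative_downnd))
  invisible(x)
}

#' Score every gene in a corpus
#'
#' Produces one score card per symbol occurring anywhere in the corpus,
#' scored for the first condition of `comparison` (status) and for the
#' comparison itself (pattern). Output order is deterministic: cumulative
#' Up-Ex score descending, then up score descending, then symbol
#' lexicographic (the C locale), mirroring the score-sorted presentation of
#' published consensus tables.
#'
#' @param corpus A non-empty [corpus()].
#' @param comparison Ordered condition pair; status scores use its first
#'   member as the condition.
#' @return Data frame (class `gene_score_table`) with one row per symbol
#'   and columns `symbol`, `n_expressed`, `n_not_detected`, `n_up`,
#'   `n_down`, `expressed_score`, `not_detected_score`, `up_score`,
#'   `down_score`, `consistent_status`, `consistent_pattern`,
#'   `cumulative_upex`, `cumulative_downnd`.
#' @export
score_all <- function(corpus, comparison = c("receptive", "pre_receptive")) {
  stopifnot(inherits(corpus, "rag_corpus"))
  if (length(corpus$datasets) == 0) stop("empty corpus")
  cmp <- parse_comparison(comparison)
  fwd <- comparison_id(cmp)
  rev_ <- comparison_id(rev(cmp))
  condition <- cmp[1]
  calls <- corpus_calls(corpus)
  symbols <- sort(unique(calls$symbol), method = "radix")

  count_votes <- function(sel, want) {
    if (nrow(sel) == 0)
      return(stats::setNames(integer(length(symbols)), symbols))
    sel <- sel[sel$eff == want, c("dataset_id", "symbol")]
    sel <- unique(sel)
    tab <- table(factor(sel$symbol, levels = symbols))
    stats::setNames(as.integer(tab), symbols)
  }

  st <- calls[!is.na(calls$condition) & calls$condition == condition, , drop = FALSE]
  st$eff <- st$call
  pt <- calls[!is.na(calls$comparison) & calls$comparison %in% c(fwd, rev_), , drop = FALSE]
  pt$eff <- ifelse(pt$comparison == fwd, pt$call,
                   ifelse(pt$call == "up", "down", "up"))

  n_exp <- count_votes(st, "expressed")
  n_nd <- count_votes(st, "not_detected")
  n_up <- count_votes(pt, "up")
  n_down <- count_votes(pt, "down")

  out <- data.frame(
    symbol = symbols,
    n_expressed = n_exp, n_not_detected = n_nd, n_up = n_up, n_down = n_down,
    expressed_score = 2L * n_exp, not_detected_score = 2L * n_nd,
    up_score = 2L * n_up, down_score = 2L * n_down,
    consistent_status = xor(n_exp > 0, n_nd > 0),
    consistent_pattern = xor(n_up > 0, n_down > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$cumulative_upex <- out$up_score + out$expressed_score
  out$cumulative_downnd <- out$down_score + out$not_detected_score
  ord <- order(-out$cumulative_upex, -out$up_score,
               out$symbol, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "comparison") <- fwd
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Write a score table to TSV
#'
#' @param scores A `gene_score_table` from [score_all()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "gene_score_table"))
  cols <- c("symbol", "expressed_score", "not_detected_score", "up_score",
            "down_score", "cumulative_upex", "cumulative_downnd",
            "consistent_status", "consistent_pattern")
  write.table(as.data.frame(scores)[cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
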