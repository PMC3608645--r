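#' Build a minimal corpus realizing prescribed vote counts
#'
#' Deterministic constructor for worked examples and tests: creates exactly
#' enough single-purpose datasets that each gene in `votes` receives the
#' requested number of expressed / not-detected status calls (in the first
#' condition of `comparison`) and up / down pattern calls. Dataset `i`
#' carries the i-th vote of every gene, so the corpus has
#' `max(total votes per gene)` datasets.
#'
#' @param votes Data frame with column `symbol` and any of the integer
#'   columns `n_expressed`, `n_not_detected`, `n_up`, `n_down` (missing
#'   columns default to 0).
#' @param comparison Ordered condition pair for the pattern calls.
#' @param cohort Cohort recorded on every simulated dataset.
#' @return A [corpus()].
#' @export
#' @examples
#' cv <- corpus_from_votes(data.frame(symbol = "SPP1",
#'                                    n_expressed = 6, n_up = 9))
#' score_all(cv)[, c("symbol", "cumulative_upex")]
corpus_from_votes <- function(votes,
                              comparison = c("receptive", "pre_receptive"),
                              cohort = "healthy") {
  stopifnot(is.data.frame(votes), "symbol" %in% names(votes))
  cmp <- parse_comparison(comparison)
  cmp_id <- comparison_id(cmp)
  condition <- cmp[1]
  for (col in c("n_expressed", "n_not_detected", "n_up", "n_down"))
    if (!col %in% names(votes)) votes[[col]] <- 0L
  counts <- vapply(c("n_expressed", "n_not_detected", "n_up", "n_down"),
                   function(col) as.integer(votes[[col]]),
                   integer(nrow(votes)))
  counts <- matrix(counts, nrow = nrow(votes))
  if (any(counts < 0)) stop("vote counts must be non-negative")
  n_datasets <- max(1L, counts[, 1] + counts[, 2], counts[, 3] + counts[, 4])
  sym <- normalize_symbol(votes$symbol)

  datasets <- lapply(seq_len(n_datasets), function(i) {
    rows <- lapply(seq_len(nrow(votes)), function(g) {
      # dataset i holds the i-th status vote and the i-th pattern vote of
      # gene g; expressed votes fill before not-detected, up before down,
      # which is valid because a gene never gets opposing votes from the
      # same dataset this way unless the caller asked for contradictions
      status <- if (i <= counts[g, 1]) "expressed"
        else if (i <= counts[g, 1] + counts[g, 2]) "not_detected" else NA
      pattern <- if (i <= counts[g, 3]) "up"
        else if (i <= counts[g, 3] + counts[g, 4]) "down" else NA
      out <- NULL
      if (!is.na(status))
        out <- rbind(out, data.frame(symbol = sym[g], call = status,
                                     condition = condition,
                                     comparison = NA_character_,
                                     stringsAsFactors = FALSE))
      if (!is.na(pattern))
        out <- rbind(out, data.frame(symbol = sym[g], call = pattern,
                                     condition = NA_character_,
                                     comparison = cmp_id,
                                     stringsAsFactors = FALSE))
      out
    })
    calls <- do.call(rbind, rows)
    if (is.null(calls)) calls <- empty_calls()
    dataset_record(
      dataset_id = sprintf("VOTE%03d", i),
      metadata = study_metadata(sprintf("VOTESTUDY%03d", i), cohort = cohort),
      condition = condition, calls = calls)
  })
  corpus(datasets, provenance = "vote-count constructed corpus")
}
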