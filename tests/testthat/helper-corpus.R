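# Shared fixtures and the independent brute-force scoring oracle.

meta <- function(id = "S1", cohort = "healthy", ...) {
  study_metadata(id, cohort = cohort, ...)
}

calls_df <- function(...) {
  # rows as c(symbol, call, condition_or_NA, comparison_or_NA)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(symbol = r[[1]], call = r[[2]],
               condition = if (is.na(r[[3]])) NA_character_ else r[[3]],
               comparison = if (is.na(r[[4]])) NA_character_ else r[[4]],
               stringsAsFactors = FALSE)
  }))
}

CMP <- "receptive_vs_pre_receptive"

status_row <- function(sym, call, condition = "receptive")
  list(sym, call, condition, NA)
pattern_row <- function(sym, call, comparison = CMP)
  list(sym, call, NA, comparison)

small_dataset <- function(id, ..., cohort = "healthy", condition = "receptive") {
  dataset_record(id, meta(paste0("STUDY_", id), cohort = cohort),
                 condition, calls_df(...))
}

# Independent oracle: per-symbol, per-dataset double loop, counting each
# dataset at most once per call kind; deliberately naive and separate from
# the vectorized path in score_all().
oracle_scores <- function(corp, comparison = c("receptive", "pre_receptive")) {
  cmp <- parse_comparison(comparison)
  fwd <- comparison_id(cmp)
  bwd <- comparison_id(rev(cmp))
  calls <- corpus_calls(corp)
  syms <- sort(unique(calls$symbol), method = "radix")
  out <- data.frame(symbol = syms, n_expressed = 0L, n_not_detected = 0L,
                    n_up = 0L, n_down = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(syms)) {
    s <- syms[i]
    for (d in unique(calls$dataset_id)) {
      dc <- calls[calls$dataset_id == d & calls$symbol == s, , drop = FALSE]
      if (nrow(dc) == 0) next
      st <- dc[!is.na(dc$condition) & dc$condition == cmp[1], , drop = FALSE]
      if (any(st$call == "expressed")) out$n_expressed[i] <- out$n_expressed[i] + 1L
      if (any(st$call == "not_detected")) out$n_not_detected[i] <- out$n_not_detected[i] + 1L
      pc <- dc[!is.na(dc$comparison), , drop = FALSE]
      up <- any((pc$call == "up" & pc$comparison == fwd) |
                  (pc$call == "down" & pc$comparison == bwd))
      dn <- any((pc$call == "down" & pc$comparison == fwd) |
                  (pc$call == "up" & pc$comparison == bwd))
      if (up) out$n_up[i] <- out$n_up[i] + 1L
      if (dn) out$n_down[i] <- out$n_down[i] + 1L
    }
  }
  out
}

# Random corpus with no intra-dataset contradictions (at most one status and
# one pattern call per gene per dataset), exercising both comparison
# orientations and an off-target condition.
random_corpus <- function(n_genes = sample(2:20, 1),
                          n_datasets = sample(1:10, 1)) {
  pool <- sprintf("G%02d", seq_len(n_genes))
  dsets <- lapply(seq_len(n_datasets), function(i) {
    rows <- list()
    orient <- if (stats::runif(1) < 0.3) "pre_receptive_vs_receptive" else CMP
    for (s in pool) {
      if (stats::runif(1) < 0.6) {
        cond <- if (stats::runif(1) < 0.15) "proliferative" else "receptive"
        rows <- c(rows, list(status_row(
          s, sample(c("expressed", "not_detected"), 1), cond)))
      }
      if (stats::runif(1) < 0.4) {
        rows <- c(rows, list(pattern_row(
          s, sample(c("up", "down"), 1), orient)))
      }
    }
    if (length(rows) == 0)
      rows <- list(status_row(pool[1], "expressed"))
    do.call(small_dataset, c(list(sprintf("RD%03d", i)), rows))
  })
  corpus(dsets)
}
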