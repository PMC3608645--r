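#' Parameters controlling RAG classification
#'
#' The defaults reproduce the published minimum cumulative score of 4: one
#' supporting dataset on each dimension (2 + 2) is enough, provided no
#' dataset contradicts — "consistently" is read as zero contradicting
#' datasets, not as a majority vote.
#'
#' @param min_status_datasets Minimum datasets supporting the status call
#'   (expressed for Up-Ex, not-detected for Down-Nd). Default 1.
#' @param min_pattern_datasets Minimum datasets supporting the pattern call.
#'   Default 1.
#' @param require_zero_contradiction If `TRUE` (default) a single opposing
#'   dataset disqualifies a gene from the class. If `FALSE`, a gene
#'   qualifying for both classes is assigned to the one with the larger
#'   cumulative score; ties are excluded from both.
#' @param cohorts_included Cohorts whose datasets enter scoring. Default
#'   `"healthy"`: consensus is derived from natural-cycle healthy
#'   participants only, excluding gynaecological disorders, stimulated
#'   cycles and IVF-failure cohorts.
#' @return An object of class `rag_params`.
#' @export
rag_params <- function(min_status_datasets = 1L,
                       min_pattern_datasets = 1L,
                       require_zero_contradiction = TRUE,
                       cohorts_included = "healthy") {
  min_status_datasets <- as.integer(min_status_datasets)
  min_pattern_datasets <- as.integer(min_pattern_datasets)
  if (is.na(min_status_datasets) || min_status_datasets < 1 ||
      is.na(min_pattern_datasets) || min_pattern_datasets < 1)
    stop("minimum dataset counts must be positive integers")
  cohorts_included <- match.arg(cohorts_included, .cohorts, several.ok = TRUE)
  stopifnot(is.logical(require_zero_contradiction),
            length(require_zero_contradiction) == 1)
  structure(
    list(min_status_datasets = min_status_datasets,
         min_pattern_datasets = min_pattern_datasets,
         require_zero_contradiction = require_zero_contradiction,
         cohorts_included = cohorts_included),
    class = "rag_params"
  )
}

#' Restrict a corpus to the cohorts under study
#'
#' @param corpus A [corpus()].
#' @param params A [rag_params()]; only `cohorts_included` is used.
#' @return The filtered `rag_corpus`. Errors if nothing survives the filter.
#' @export
filter_datasets <- function(corpus, params = rag_params()) {
  stopifnot(inherits(corpus, "rag_corpus"), inherits(params, "rag_params"))
  keep <- vapply(corpus$datasets,
                 function(d) d$metadata$cohort %in% params$cohorts_included,
                 TRUE)
  message("filter_datasets: retaining ", sum(keep), " of ", length(keep),
          " dataset(s) (cohorts: ",
          paste(params$cohorts_included, collapse = ", "), ")")
  if (!any(keep))
    stop("no datasets left after cohort filtering (wanted: ",
         paste(params$cohorts_included, collapse = ", "), ")")
  out <- corpus
  out$datasets <- corpus$datasets[keep]
  out
}

new_rag_result <- function(up_ex, down_nd, params, corpus_digest,
                           comparison, source = "derived") {
  structure(
    list(up_ex = up_ex, down_nd = down_nd, params = params,
         corpus_digest = corpus_digest,
         comparison = comparison, source = source),
    class = "rag_result"
  )
}

#' @export
print.rag_result <- function(x, ...) {
  cat("rag_result (", x$source, "): ", nrow(x$up_ex), " Up-Ex, ",
      nrow(x$down_nd), " Down-Nd gene(s)\n", sep = "")
  invisible(x)
}

# provenance hash of the corpus contents (not of in-memory representation)
corpus_digest <- function(corpus) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_corpus(corpus, tmp)
  unname(tools::md5sum(tmp))
}

#' Derive receptivity-associated genes from a corpus
#'
#' Applies the cohort filter, scores every gene ([score_all()]) and
#' classifies. Up-Ex membership requires at least `min_status_datasets`
#' datasets reporting the gene expressed in the first comparison condition
#' AND at least `min_pattern_datasets` reporting it upregulated, with (by
#' default) zero datasets reporting not-detected or downregulated. Down-Nd
#' is the mirror image. Entries are ranked by cumulative score descending,
#' then pattern score descending, then symbol.
#'
#' @param corpus A [corpus()] (unfiltered is fine; the cohort filter is
#'   applied here and is idempotent).
#' @param comparison Ordered condition pair, `up` = higher in the first.
#' @param params A [rag_params()].
#' @param gene_names Optional named character vector mapping symbol to
#'   descriptive gene name for export.
#' @return A `rag_result`: `up_ex` and `down_nd` data frames with columns
#'   `symbol`, `gene_name`, `pattern_score`, `status_score`, `cumulative`,
#'   plus the `params` used and a `corpus_digest` provenance hash.
#' @export
derive_rags <- function(corpus, comparison = c("receptive", "pre_receptive"),
                        params = rag_params(), gene_names = NULL) {
  stopifnot(inherits(corpus, "rag_corpus"), inherits(params, "rag_params"))
  cmp <- parse_comparison(comparison)
  filtered <- filter_datasets(corpus, params)
  scores <- score_all(filtered, cmp)

  up_ok <- scores$n_expressed >= params$min_status_datasets &
    scores$n_up >= params$min_pattern_datasets
  dn_ok <- scores$n_not_detected >= params$min_status_datasets &
    scores$n_down >= params$min_pattern_datasets
  if (params$require_zero_contradiction) {
    up_ok <- up_ok & scores$n_not_detected == 0 & scores$n_down == 0
    dn_ok <- dn_ok & scores$n_expressed == 0 & scores$n_up == 0
  } else {
    both <- up_ok & dn_ok
    dominant_up <- scores$cumulative_upex > scores$cumulative_downnd
    dominant_dn <- scores$cumulative_downnd > scores$cumulative_upex
    up_ok[both] <- dominant_up[both]
    dn_ok[both] <- dominant_dn[both]  # ties excluded from both classes
  }

  shape <- function(sel, pattern_col, status_col, cum_col) {
    df <- scores[sel, , drop = FALSE]
    out <- data.frame(
      symbol = df$symbol,
      gene_name = if (is.null(gene_names)) character(nrow(df)) else
        ifelse(is.na(gene_names[df$symbol]), "", gene_names[df$symbol]),
      pattern_score = df[[pattern_col]],
      status_score = df[[status_col]],
      cumulative = df[[cum_col]],
      stringsAsFactors = FALSE
    )
    ord <- order(-out$cumulative, -out$pattern_score, out$symbol,
                 method = "radix")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  new_rag_result(
    up_ex = shape(up_ok, "up_score", "expressed_score", "cumulative_upex"),
    down_nd = shape(dn_ok, "down_score", "not_detected_score", "cumulative_downnd"),
    params = params, corpus_digest = corpus_digest(filtered),
    comparison = cmp
  )
}

#' Up-Ex reference genes behaving suboptimally in a case cohort
#'
#' Given a reference Up-Ex gene set (e.g. derived from healthy natural-cycle
#' datasets) and a corpus from a cohort of interest (e.g. women with
#' repeated IVF failure), returns the reference Up-Ex genes whose behaviour
#' in the case corpus contradicts their reference class: reported
#' downregulated or not-detected in at least one case dataset and
#' upregulated in none. Output is alphabetical, deterministic.
#'
#' @param reference A `rag_result` whose `up_ex` slot defines the reference
#'   gene set.
#' @param case_corpus A [corpus()] from the case cohort.
#' @param comparison Ordered condition pair, as for the reference.
#' @return Character vector of gene symbols, sorted.
#' @export
derive_suboptimal <- function(reference, case_corpus,
                              comparison = c("receptive", "pre_receptive")) {
  stopifnot(inherits(reference, "rag_result"),
            inherits(case_corpus, "rag_corpus"))
  cmp <- parse_comparison(comparison)
  fwd <- comparison_id(cmp)
  calls <- corpus_calls(case_corpus)
  has_cmp <- !is.na(calls$comparison) &
    calls$comparison %in% c(fwd, reverse_comparison_id(fwd))
  if (!any(has_cmp))
    stop("comparison '", fwd, "' absent from case corpus")
  scores <- score_all(case_corpus, cmp)
  ref_syms <- reference$up_ex$symbol
  sc <- scores[match(ref_syms, scores$symbol), , drop = FALSE]
  contradicted <- !is.na(sc$symbol) &
    (sc$n_down + sc$n_not_detected) >= 1 & sc$n_up == 0
  sort(ref_syms[contradicted], method = "radix")
}

#' Export a RAG result as ranked TSV tables
#'
#' Writes `up_ex.tsv` and `down_nd.tsv` under `dir`, shaped like the
#' published tables: serial number, gene symbol, gene name (empty when
#' unknown), pattern score, status score, cumulative score. Output is
#' byte-stable across runs on the same result.
#'
#' @param result A `rag_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
export_rag_tables <- function(result, dir) {
  stopifnot(inherits(result, "rag_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  write_one <- function(df, file) {
    path <- file.path(dir, file)
    out <- data.frame(s_no = seq_len(nrow(df)), symbol = df$symbol,
                      name = df$gene_name,
                      pattern_score = df$pattern_score,
                      status_score = df$status_score,
                      cumulative_score = df$cumulative,
                      stringsAsFactors = FALSE)
    con <- file(path, open = "wb")  # fixed eol for byte stability
    on.exit(close(con))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", fileEncoding = "UTF-8")
    path
  }
  paths <- c(write_one(result$up_ex, "up_ex.tsv"),
             write_one(result$down_nd, "down_nd.tsv"))
  invisible(paths)
}
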