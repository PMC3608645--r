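# Cohort filtering, RAG classification, suboptimal subset, exports.

toy_corpus <- function() {
  # A: expressed+up in 3/3; B: up in 2, down in 1; C: not_detected+down in 2
  mk <- function(id, rows) do.call(small_dataset, c(list(id), rows))
  corpus(list(
    mk("T1", list(status_row("A", "expressed"), pattern_row("A", "up"),
                  pattern_row("B", "up"),
                  status_row("C", "not_detected"), pattern_row("C", "down"))),
    mk("T2", list(status_row("A", "expressed"), pattern_row("A", "up"),
                  pattern_row("B", "up"),
                  status_row("C", "not_detected"), pattern_row("C", "down"))),
    mk("T3", list(status_row("A", "expressed"), pattern_row("A", "up"),
                  pattern_row("B", "down")))
  ))
}

test_that("filter_datasets retains requested cohorts and errors on empty result", {
  corp <- corpus(list(
    small_dataset("H1", status_row("A", "expressed")),
    small_dataset("H2", status_row("A", "expressed")),
    small_dataset("H3", status_row("A", "expressed")),
    small_dataset("P1", status_row("A", "expressed"), cohort = "disorder"),
    small_dataset("P2", status_row("A", "expressed"), cohort = "stimulated")))
  expect_message(kept <- filter_datasets(corp, rag_params()),
                 "retaining 3 of 5")
  expect_length(kept$datasets, 3)

  all_in <- rag_params(cohorts_included = c("healthy", "disorder",
                                            "stimulated", "ivf_failure"))
  expect_length(suppressMessages(filter_datasets(corp, all_in))$datasets, 5)

  only_ivf <- rag_params(cohorts_included = "ivf_failure")
  expect_error(suppressMessages(filter_datasets(corp, only_ivf)),
               "no datasets left")
})

test_that("derive_rags classifies the toy corpus by the consistency rule", {
  res <- suppressMessages(derive_rags(toy_corpus()))
  expect_equal(res$up_ex$symbol, "A")
  expect_equal(res$up_ex$cumulative, 12L)  # 3 datasets x (2+2)
  expect_equal(res$down_nd$symbol, "C")
  expect_equal(res$down_nd$cumulative, 8L)
  # B is inconsistent (2 up, 1 down): excluded from both classes
  expect_false("B" %in% c(res$up_ex$symbol, res$down_nd$symbol))
  expect_s3_class(res, "rag_result")
  expect_match(res$corpus_digest, "^[0-9a-f]{32}$")
})

test_that("a 6-expressed/9-up gene derives with cumulative 30", {
  corp <- corpus_from_votes(data.frame(symbol = "SPP1", n_expressed = 6, n_up = 9))
  res <- suppressMessages(derive_rags(corp))
  expect_equal(res$up_ex$symbol, "SPP1")
  expect_equal(res$up_ex$pattern_score, 18L)
  expect_equal(res$up_ex$status_score, 12L)
  expect_equal(res$up_ex$cumulative, 30L)
})

test_that("support thresholds and the contradiction toggle behave as documented", {
  votes <- data.frame(symbol = c("STRONG", "WEAK", "SPLIT"),
                      n_expressed = c(4, 1, 4), n_up = c(3, 1, 4),
                      n_down = c(0, 0, 1))
  corp <- corpus_from_votes(votes)
  strict <- suppressMessages(derive_rags(corp, params = rag_params(
    min_status_datasets = 2, min_pattern_datasets = 2)))
  expect_equal(strict$up_ex$symbol, "STRONG")  # WEAK under-supported, SPLIT contradicted

  lax <- suppressMessages(derive_rags(corp, params = rag_params(
    require_zero_contradiction = FALSE)))
  expect_setequal(lax$up_ex$symbol, c("STRONG", "WEAK", "SPLIT"))
})

test_that("without zero-contradiction the dominant class wins and ties drop", {
  # DOM: upex cumulative 8 vs downnd 4 -> upex; TIE: 4 vs 4 -> excluded
  corp <- corpus_from_votes(data.frame(
    symbol = c("DOM", "TIE"),
    n_expressed = c(2, 1), n_not_detected = c(1, 1),
    n_up = c(2, 1), n_down = c(1, 1)))
  res <- suppressMessages(derive_rags(corp, params = rag_params(
    require_zero_contradiction = FALSE)))
  expect_equal(res$up_ex$symbol, "DOM")
  expect_equal(nrow(res$down_nd), 0)
  expect_length(intersect(res$up_ex$symbol, res$down_nd$symbol), 0)
})

test_that("up_ex and down_nd stay disjoint on random corpora under both modes", {
  set.seed(31415)
  for (rep in 1:25) {
    corp <- random_corpus(n_genes = 10, n_datasets = 6)
    for (rzc in c(TRUE, FALSE)) {
      res <- suppressMessages(derive_rags(corp, params = rag_params(
        require_zero_contradiction = rzc)))
      expect_length(intersect(res$up_ex$symbol, res$down_nd$symbol), 0)
    }
  }
})

test_that("classification is stable under dataset relabeling and sub-corpus pruning", {
  set.seed(2718)
  corp <- random_corpus(n_genes = 12, n_datasets = 8)
  res <- suppressMessages(derive_rags(corp))
  relab <- unname(corp$datasets)
  for (i in seq_along(relab)) relab[[i]]$dataset_id <- sprintf("Z%02d", i)
  res2 <- suppressMessages(derive_rags(corpus(rev(relab))))
  expect_equal(res2$up_ex, res$up_ex)
  expect_equal(res2$down_nd, res$down_nd)

  # dropping a dataset never introduces a contradiction: any Up-Ex gene
  # still meeting the support minima stays Up-Ex in the sub-corpus
  if (length(corp$datasets) > 1 && nrow(res$up_ex) > 0) {
    sub <- corpus(unname(corp$datasets)[-1])
    sub_scores <- score_all(sub)
    res_sub <- suppressMessages(derive_rags(sub))
    still_supported <- res$up_ex$symbol[
      res$up_ex$symbol %in% sub_scores$symbol[
        sub_scores$n_expressed >= 1 & sub_scores$n_up >= 1]]
    expect_true(all(still_supported %in% res_sub$up_ex$symbol))
  }
})

test_that("fixture ranking agrees with the module tie-break where scores strictly decrease", {
  fx <- load_fixture_tables()
  for (df in list(fx$up_ex, fx$down_nd)) {
    ord <- order(-df$cumulative, -df$pattern_score, df$symbol, method = "radix")
    redone <- df[ord, ]
    expect_equal(redone$cumulative, df$cumulative)  # already score-sorted
    # rows whose cumulative score is unique are pinned by the tie-break
    tab <- table(df$cumulative)
    singleton <- which(df$cumulative %in% as.integer(names(tab)[tab == 1]))
    expect_equal(redone$symbol[singleton], df$symbol[singleton])
  }
})

test_that("derive_suboptimal flags reference genes contradicted by the case cohort", {
  reference <- suppressMessages(derive_rags(corpus_from_votes(
    data.frame(symbol = c("A", "B"), n_expressed = c(2, 2), n_up = c(2, 2)))))
  case_corp <- corpus(list(
    small_dataset("IVF1", pattern_row("A", "down"), pattern_row("B", "up"),
                  cohort = "ivf_failure")))
  expect_equal(derive_suboptimal(reference, case_corp), "A")

  # agreement everywhere -> empty; absence of the genes -> empty
  agree <- corpus(list(small_dataset("IVF2", pattern_row("A", "up"),
                                     pattern_row("B", "up"),
                                     cohort = "ivf_failure")))
  expect_length(derive_suboptimal(reference, agree), 0)
  other <- corpus(list(small_dataset("IVF3", pattern_row("ZZZ", "down"),
                                     cohort = "ivf_failure")))
  expect_length(derive_suboptimal(reference, other), 0)

  # not-detected status contradicts an Up-Ex reference too
  nd <- corpus(list(small_dataset("IVF4", status_row("B", "not_detected"),
                                  pattern_row("ZZZ", "down"),
                                  cohort = "ivf_failure")))
  expect_equal(derive_suboptimal(reference, nd), "B")

  # comparison absent from the case corpus is an error
  no_cmp <- corpus(list(small_dataset("IVF5", status_row("A", "expressed"),
                                      cohort = "ivf_failure")))
  expect_error(derive_suboptimal(reference, no_cmp), "absent from case corpus")
})

test_that("export_rag_tables writes published-shaped, byte-stable TSVs", {
  fx <- load_fixture_tables()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- export_rag_tables(fx, dir1)
  expect_equal(nrow(read.delim(file.path(dir1, "up_ex.tsv"))), 151)
  expect_equal(nrow(read.delim(file.path(dir1, "down_nd.tsv"))), 28)
  export_rag_tables(fx, dir2)
  for (f in c("up_ex.tsv", "down_nd.tsv"))
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))

  empty <- suppressMessages(derive_rags(corpus(list(
    small_dataset("E1", status_row("ONLY", "expressed"))))))
  pe <- export_rag_tables(empty, withr::local_tempdir())
  expect_equal(nrow(read.delim(pe[1])), 0)
  expect_equal(readLines(pe[1], n = 1),
               "s_no\tsymbol\tname\tpattern_score\tstatus_score\tcumulative_score")
})
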