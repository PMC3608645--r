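#' Parameters for the synthetic corpus generator
#'
#' The generator emulates the statistical shape of a curated cross-study
#' corpus at the call level: a panel of genes with fixed ground-truth
#' classes, and a set of datasets that each report a random subset of the
#' panel, with each reported call flipped to its contradiction with a small
#' probability. The defaults are scaled-down but structurally faithful: a
#' dozen datasets (real corpora run to dozens of gene lists per contrast), a
#' 500-gene panel, true-RAG fractions matching the published prevalence
#' (151/19285 Up-Ex, 28/19285 Down-Nd, i.e. about 0.8% and 0.15%), 63% of
#' background genes expressed (12099/19285), half-coverage per dataset, and
#' a 5% curation/platform noise rate.
#'
#' @param n_genes Number of genes in the panel.
#' @param n_datasets Number of simulated datasets.
#' @param frac_true_upex,frac_true_downnd Fractions of the panel whose
#'   ground truth is Up-Ex / Down-Nd; must sum to at most 1.
#' @param frac_background_expressed Fraction of the remaining background
#'   genes that are truly expressed (the rest are truly absent).
#' @param p_report Probability that a given dataset reports a given gene.
#' @param p_flip Probability that each reported call contradicts the ground
#'   truth, independently per call.
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the parameter set.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 500L, n_datasets = 12L,
                              frac_true_upex = 0.008,
                              frac_true_downnd = 0.0015,
                              frac_background_expressed = 0.63,
                              p_report = 0.5, p_flip = 0.05,
                              seed = 1L) {
  n_genes <- as.integer(n_genes); n_datasets <- as.integer(n_datasets)
  if (is.na(n_genes) || n_genes < 1) stop("n_genes must be a positive integer")
  if (is.na(n_datasets) || n_datasets < 1) stop("n_datasets must be a positive integer")
  probs <- c(frac_true_upex = frac_true_upex,
             frac_true_downnd = frac_true_downnd,
             frac_background_expressed = frac_background_expressed,
             p_report = p_report, p_flip = p_flip)
  bad <- !is.finite(probs) | probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities out of [0,1]: ", paste(names(probs)[bad], collapse = ", "))
  if (frac_true_upex + frac_true_downnd > 1)
    stop("frac_true_upex + frac_true_downnd must not exceed 1")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(
    list(n_genes = n_genes, n_datasets = n_datasets,
         frac_true_upex = frac_true_upex, frac_true_downnd = frac_true_downnd,
         frac_background_expressed = frac_background_expressed,
         p_report = p_report, p_flip = p_flip, seed = seed),
    class = "simulation_params"
  )
}

.truth_classes <- c("true_upex", "true_downnd",
                    "background_expressed", "background_absent")

#' Simulate a corpus of study gene lists with known ground truth
#'
#' Gene classes are assigned by rounding the requested fractions
#' (`round(frac * n_genes)` true Up-Ex and Down-Nd genes; the background is
#' split by `frac_background_expressed`) and shuffled over the panel. For
#' each dataset and each gene, with probability `p_report` the dataset
#' reports the gene: a true Up-Ex gene emits an `expressed` status call and
#' an `up` pattern call, a true Down-Nd gene emits `not_detected` and
#' `down`, and background genes emit only the status call matching their
#' class. Every emitted call is independently flipped to its contradiction
#' with probability `p_flip`. All randomness flows from `seed`; per-dataset
#' substreams are drawn up front so generation is reproducible and
#' insensitive to evaluation order.
#'
#' @param params A [simulation_params()].
#' @return List with components `corpus` (a [corpus()], cohort `healthy`,
#'   condition `receptive`, comparison receptive-vs-pre-receptive) and
#'   `truth` (a `synthetic_truth`: data frame `genes` with columns `symbol`,
#'   `class`, plus the parameter echo).
#' @export
#' @examples
#' sim <- simulate_corpus(simulation_params(n_genes = 50, n_datasets = 4,
#'                                          seed = 7))
#' table(sim$truth$genes$class)
simulate_corpus <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_genes
  symbols <- sprintf("SG%05d", seq_len(n))

  n_up <- round(params$frac_true_upex * n)
  n_dn <- round(params$frac_true_downnd * n)
  if (n_up + n_dn > n) stop("class fractions round to more genes than the panel holds")
  n_bg <- n - n_up - n_dn
  n_bg_expr <- round(params$frac_background_expressed * n_bg)
  classes <- rep(.truth_classes, c(n_up, n_dn, n_bg_expr, n_bg - n_bg_expr))

  set.seed(params$seed)
  classes <- sample(classes)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, params$n_datasets)

  status_true <- ifelse(classes %in% c("true_upex", "background_expressed"),
                        "expressed", "not_detected")
  pattern_true <- ifelse(classes == "true_upex", "up",
                         ifelse(classes == "true_downnd", "down", NA_character_))
  cmp_id <- "receptive_vs_pre_receptive"

  datasets <- lapply(seq_len(params$n_datasets), function(i) {
    set.seed(dataset_seeds[i])
    reported <- stats::runif(n) < params$p_report
    idx <- which(reported)
    flip_status <- stats::runif(length(idx)) < params$p_flip
    status_call <- ifelse(
      xor(status_true[idx] == "expressed", flip_status),
      "expressed", "not_detected")
    has_pattern <- !is.na(pattern_true[idx])
    flip_pattern <- stats::runif(sum(has_pattern)) < params$p_flip
    pattern_call <- ifelse(
      xor(pattern_true[idx][has_pattern] == "up", flip_pattern),
      "up", "down")
    calls <- rbind(
      data.frame(symbol = symbols[idx], call = as.character(status_call),
                 condition = rep("receptive", length(idx)),
                 comparison = rep(NA_character_, length(idx)),
                 stringsAsFactors = FALSE),
      data.frame(symbol = symbols[idx][has_pattern],
                 call = as.character(pattern_call),
                 condition = rep(NA_character_, sum(has_pattern)),
                 comparison = rep(cmp_id, sum(has_pattern)),
                 stringsAsFactors = FALSE)
    )
    dataset_record(
      dataset_id = sprintf("SIMD%03d", i),
      metadata = study_metadata(sprintf("SIMSTUDY%03d", i), cohort = "healthy",
                                sample_size = 10L, strategy = "microarray",
                                platform = "simulated",
                                n_hybridizations = 10L),
      condition = "receptive", calls = calls)
  })
  truth <- structure(
    list(genes = data.frame(symbol = symbols, class = classes,
                            stringsAsFactors = FALSE),
         params = params),
    class = "synthetic_truth")
  list(corpus = corpus(datasets,
                       provenance = sprintf("simulated corpus (seed %d)", params$seed)),
       truth = truth)
}

#' Parameter recovery of a RAG derivation against simulation ground truth
#'
#' Compares the classified Up-Ex and Down-Nd gene sets with the simulated
#' truth classes and reports counts and rates per class. Precision is `NA`
#' when a class has no predictions; recall is `NA` when the truth holds no
#' genes of that class.
#'
#' @param result A `rag_result` derived from the truth's corpus.
#' @param truth The `synthetic_truth` returned by [simulate_corpus()].
#' @return Data frame with rows `upex` and `downnd` and columns `class`,
#'   `n_true`, `n_pred`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(result, "rag_result"), inherits(truth, "synthetic_truth"))
  universe <- truth$genes$symbol
  pred_syms <- c(result$up_ex$symbol, result$down_nd$symbol)
  alien <- setdiff(pred_syms, universe)
  if (length(alien) > 0)
    stop("symbol universe mismatch: result contains gene(s) absent from the ",
         "simulation truth: ", paste(utils::head(alien, 5), collapse = ", "))
  one <- function(label, predicted, truth_class) {
    truth_set <- truth$genes$symbol[truth$genes$class == truth_class]
    tp <- length(intersect(predicted, truth_set))
    fp <- length(setdiff(predicted, truth_set))
    fn <- length(setdiff(truth_set, predicted))
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(class = label, n_true = length(truth_set),
               n_pred = length(predicted), tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  }
  rbind(one("upex", result$up_ex$symbol, "true_upex"),
        one("downnd", result$down_nd$symbol, "true_downnd"))
}
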