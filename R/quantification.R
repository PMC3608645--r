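#' qPCR delta-Ct: target normalized to the housekeeping gene
#'
#' Replicate Ct values (e.g. triplicate wells) are averaged arithmetically
#' before subtraction.
#'
#' @param ct_target Numeric vector of Ct values (cycles) for the gene of
#'   interest; replicates are averaged.
#' @param ct_reference Numeric vector of Ct values for the housekeeping
#'   gene (e.g. 18S rRNA); replicates are averaged.
#' @return delta-Ct in cycles: `mean(ct_target) - mean(ct_reference)`.
#' @export
#' @examples
#' delta_ct(c(24.9, 25.0, 25.1), 10)  # 15
delta_ct <- function(ct_target, ct_reference) {
  if (!is.numeric(ct_target) || !is.numeric(ct_reference) ||
      length(ct_target) == 0 || length(ct_reference) == 0 ||
      any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite numbers")
  if (any(ct_target < 0) || any(ct_reference < 0))
    stop("Ct values must be non-negative")
  mean(ct_target) - mean(ct_reference)
}

#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification: the delta-delta-Ct is the experimental
#' sample's delta-Ct minus the calibrator's, and the fold change is
#' `2^-ddCt`. One cycle later than the calibrator halves the estimate; two
#' cycles earlier quadruples it. No amplification-efficiency correction is
#' applied.
#'
#' @param delta_ct_experimental delta-Ct of the experimental sample.
#' @param delta_ct_control delta-Ct of the calibrator/control sample.
#' @return Fold change (dimensionless, strictly positive). Vectorized.
#' @export
#' @examples
#' relative_expression(15, 15)  # 1
#' relative_expression(16, 15)  # 0.5
#' relative_expression(13, 15)  # 4
relative_expression <- function(delta_ct_experimental, delta_ct_control) {
  if (any(!is.finite(delta_ct_experimental)) || any(!is.finite(delta_ct_control)))
    stop("delta-Ct values must be finite")
  2^(-(delta_ct_experimental - delta_ct_control))
}

#' Percentage of spheroids attached
#'
#' @param attached Non-negative integer count of attached spheroids.
#' @param total Positive integer count of spheroids added.
#' @return `100 * attached / total`, in `[0, 100]`. Vectorized.
#' @export
#' @examples
#' percent_attached(13, 60)
percent_attached <- function(attached, total) {
  attached <- as.numeric(attached); total <- as.numeric(total)
  if (any(!is.finite(attached)) || any(!is.finite(total)))
    stop("counts must be finite")
  if (any(total < 1)) stop("total must be a positive count")
  if (any(attached < 0) || any(attached > total))
    stop("attached must lie in [0, total]")
  100 * attached / total
}

#' Reduction in attachment percentage after treatment
#'
#' By default the reduction is reported in percentage points
#' (`control - treated`), the reading consistent with reported antibody-
#' blocking effects; set `relative = TRUE` for the relative reduction
#' `100 * (control - treated) / control`.
#'
#' @param treated Attachment percentage after treatment, in `[0, 100]`.
#' @param control Attachment percentage in the control, in `[0, 100]`.
#' @param relative Report relative (%) rather than absolute (points)
#'   reduction. Default `FALSE`.
#' @return Reduction in percentage points (or percent if `relative`).
#' @export
#' @examples
#' percent_reduction(treated = 50.5, control = 70)  # 19.5 points
percent_reduction <- function(treated, control, relative = FALSE) {
  if (any(!is.finite(treated)) || any(!is.finite(control)))
    stop("percentages must be finite")
  if (any(treated < 0 | treated > 100) || any(control < 0 | control > 100))
    stop("percentages must lie in [0, 100]")
  if (relative) {
    if (any(control == 0)) stop("relative reduction undefined for control = 0")
    100 * (control - treated) / control
  } else {
    control - treated
  }
}

#' Relative-expression table for a set of samples
#'
#' Convenience wrapper over [delta_ct()] and [relative_expression()] for a
#' per-sample Ct table, normalizing every sample to one calibrator sample.
#'
#' @param ct_table Data frame with columns `sample_id`, `ct_target`,
#'   `ct_reference`; repeated `sample_id` rows are treated as replicates
#'   and averaged.
#' @param calibrator `sample_id` of the calibrator/control sample.
#' @return Data frame with one row per sample: `sample_id`, `delta_ct`,
#'   `ddct`, `relative_expression`.
#' @export
relative_expression_table <- function(ct_table, calibrator) {
  stopifnot(is.data.frame(ct_table),
            all(c("sample_id", "ct_target", "ct_reference") %in% names(ct_table)))
  ids <- unique(as.character(ct_table$sample_id))
  if (!calibrator %in% ids)
    stop("calibrator sample '", calibrator, "' not present in the Ct table")
  dct <- vapply(ids, function(id) {
    rows <- ct_table[ct_table$sample_id == id, , drop = FALSE]
    delta_ct(rows$ct_target, rows$ct_reference)
  }, 0)
  ddct <- dct - dct[[calibrator]]
  data.frame(sample_id = ids, delta_ct = unname(dct), ddct = unname(ddct),
             relative_expression = unname(relative_expression(dct, dct[[calibrator]])),
             stringsAsFactors = FALSE)
}
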