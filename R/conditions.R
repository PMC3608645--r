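#' Default condition canonicalization table
#'
#' Source studies label endometrial sampling windows inconsistently
#' ("mid-secretory", "LH+7", "day 21", ...). Scoring requires a canonical
#' vocabulary, so raw labels are mapped to one of `pre_receptive`,
#' `receptive`, `proliferative`, `secretory`; anything unmapped is tagged
#' `other:<raw>` and kept, never dropped. The defaults encode the usual
#' clinical correspondence: the receptive window opens around LH+7 / cycle
#' day 21 (mid-secretory), the pre-receptive biopsy is taken around LH+2
#' (early secretory).
#'
#' @return Named character vector mapping lower-cased raw labels to
#'   canonical condition names.
#' @export
#' @examples
#' default_condition_map()[c("lh+7", "early secretory")]
default_condition_map <- function() {
  c(
    "receptive"          = "receptive",
    "mid-secretory"      = "receptive",
    "mid secretory"      = "receptive",
    "midsecretory"       = "receptive",
    "lh+7"               = "receptive",
    "lh+8"               = "receptive",
    "window of implantation" = "receptive",
    "pre-receptive"      = "pre_receptive",
    "pre receptive"      = "pre_receptive",
    "prereceptive"       = "pre_receptive",
    "early secretory"    = "pre_receptive",
    "early-secretory"    = "pre_receptive",
    "lh+2"               = "pre_receptive",
    "lh+3"               = "pre_receptive",
    "proliferative"      = "proliferative",
    "late proliferative" = "proliferative",
    "secretory"          = "secretory",
    "late secretory"     = "secretory"
  )
}

#' Canonical condition vocabulary (excluding `other:` tags)
#' @keywords internal
.canonical_conditions <- c("pre_receptive", "receptive", "proliferative", "secretory")

#' Canonicalize condition labels
#'
#' Deterministic lookup of curated free-text labels against a condition map.
#' Matching is case-insensitive after whitespace trimming. Labels already in
#' canonical form pass through; unmapped labels become `other:<raw>` so that
#' no curated call is silently discarded.
#'
#' @param raw_label Character vector of curated condition labels.
#' @param condition_map Named character vector (see
#'   [default_condition_map()]); names are matched case-insensitively.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' canonical_condition(c("LH+7", "Early Secretory", "menstrual"))
canonical_condition <- function(raw_label, condition_map = default_condition_map()) {
  stopifnot(is.character(raw_label))
  if (length(condition_map) > 0 && is.null(names(condition_map)))
    stop("condition_map must be a named character vector")
  key <- tolower(trimws(raw_label))
  names(condition_map) <- tolower(trimws(names(condition_map)))
  out <- unname(condition_map[key])
  already <- is.na(out) & key %in% c(.canonical_conditions, tolower(.canonical_conditions))
  out[already] <- key[already]
  unmapped <- is.na(out)
  out[unmapped] <- paste0("other:", trimws(raw_label[unmapped]))
  out
}

is_known_condition <- function(x) {
  x %in% .canonical_conditions | startsWith(x, "other:")
}

#' Parse and format condition comparisons
#'
#' A comparison is an ordered pair of canonical conditions; the direction
#' convention throughout the package is that an `up` call means higher
#' expression in the *first* condition of the pair. The string form joins the
#' two sides with `"_vs_"`, e.g. `"receptive_vs_pre_receptive"`.
#'
#' @param x Either a length-2 character vector of condition labels or a
#'   single `"<a>_vs_<b>"` string.
#' @param condition_map Passed to [canonical_condition()].
#' @return `parse_comparison()`: length-2 character vector of canonical
#'   conditions; `comparison_id()`: the `"<a>_vs_<b>"` string.
#' @export
#' @examples
#' parse_comparison("receptive_vs_pre_receptive")
#' comparison_id(c("receptive", "pre_receptive"))
parse_comparison <- function(x, condition_map = default_condition_map()) {
  if (length(x) == 1 && grepl("_vs_", x, fixed = TRUE)) {
    x <- strsplit(x, "_vs_", fixed = TRUE)[[1]]
  }
  if (length(x) != 2)
    stop("a comparison must name exactly two conditions, got: ",
         paste(x, collapse = ", "))
  out <- canonical_condition(x, condition_map)
  if (out[1] == out[2])
    stop("a comparison must contrast two distinct conditions, got '",
         out[1], "' twice")
  out
}

#' @rdname parse_comparison
#' @export
comparison_id <- function(x) {
  paste(x, collapse = "_vs_")
}

reverse_comparison_id <- function(id) {
  comparison_id(rev(strsplit(id, "_vs_", fixed = TRUE)[[1]]))
}
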