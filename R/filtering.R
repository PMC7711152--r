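# OTU-table filtering: singleton removal, dataset-wide relative-abundance
# thresholding, and negative-control contaminant removal. Filters change OTU
# membership only; surviving counts are never altered. Each filter records the
# OTUs it removed in the table's filter log.

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples equals exactly 1 (the
#' dataset-wide reading of "singleton"). Sample membership and surviving
#' counts are unchanged.
#'
#' @param tbl wide OTU tibble (`sample_id` + count columns).
#' @return the filtered tibble. The ids removed by this step are available via
#'   [removed_otus()], and the cumulative ledger via [filter_log()].
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = c("a", "b"), x = c(1L, 0L), y = c(3L, 4L))
#' removed_otus(remove_singletons(tbl))
remove_singletons <- function(tbl) {
  m <- otu_matrix(tbl)
  check_that(is_whole(m), "Singleton removal requires integer counts.")
  removed <- colnames(m)[colSums(m) == 1]
  annotate_filter(drop_otus(tbl, removed), "remove_singletons", removed)
}

#' Dataset-wide relative-abundance threshold filter
#'
#' An OTU is retained iff its total count divided by the grand total count is
#' `>= threshold` (boundary equality retains). The default 1e-4 corresponds to
#' the 0.01% threshold conventional in amplicon pipelines. A per-sample mode
#' retains an OTU iff its relative abundance reaches the threshold in at least
#' one sample.
#'
#' @param tbl wide OTU tibble.
#' @param threshold fraction in \[0, 1).
#' @param mode `"total"` (default, dataset-wide fraction) or `"per_sample_max"`.
#' @return the filtered tibble (see [removed_otus()], [filter_log()]).
#' @export
filter_rare_otus <- function(tbl, threshold = 1e-4,
                             mode = c("total", "per_sample_max")) {
  mode <- match.arg(mode)
  check_that(
    is.numeric(threshold) && length(threshold) == 1 &&
      threshold >= 0 && threshold < 1,
    "`threshold` must lie in [0, 1)."
  )
  m <- otu_matrix(tbl)
  keep <- if (mode == "total") {
    colSums(m) / sum(m) >= threshold
  } else {
    rel <- m / pmax(rowSums(m), 1)
    apply(rel, 2, max) >= threshold
  }
  removed <- colnames(m)[!keep]
  annotate_filter(drop_otus(tbl, removed), "filter_rare_otus", removed)
}

#' Negative-control contaminant filter
#'
#' Removes from `tbl` every OTU whose relative abundance within any single
#' control sample is `>= cutoff` (default 0.05%), the strict reading of a
#' "present in the controls" rule; `rule = "mean"` instead compares the mean
#' relative abundance across controls.
#'
#' @param tbl wide OTU tibble to filter.
#' @param controls wide OTU tibble of negative-control samples sharing `tbl`'s
#'   OTU universe (column order may differ).
#' @param cutoff fraction in \[0, 1).
#' @param rule `"max"` (default) or `"mean"` over control samples.
#' @return the filtered tibble (see [removed_otus()], [filter_log()]).
#' @export
filter_contaminants <- function(tbl, controls, cutoff = 5e-4,
                                rule = c("max", "mean")) {
  rule <- match.arg(rule)
  check_that(
    is.numeric(cutoff) && length(cutoff) == 1 && cutoff >= 0 && cutoff < 1,
    "`cutoff` must lie in [0, 1)."
  )
  m <- otu_matrix(tbl)
  mc <- otu_matrix(controls)
  check_that(
    setequal(colnames(m), colnames(mc)),
    "`controls` must share the OTU universe of `tbl`."
  )
  mc <- mc[, colnames(m), drop = FALSE]
  rel <- mc / pmax(rowSums(mc), 1)
  stat <- if (rule == "max") apply(rel, 2, max) else colMeans(rel)
  removed <- colnames(m)[stat >= cutoff & cutoff > 0]
  if (cutoff == 0) removed <- colnames(m) # degenerate: everything is >= 0
  annotate_filter(drop_otus(tbl, removed), "filter_contaminants", removed)
}

#' OTUs removed by the most recent filter step
#'
#' @param tbl a tibble returned by one of the filter functions.
#' @return character vector of OTU ids (possibly empty).
#' @export
removed_otus <- function(tbl) {
  attr(tbl, "removed_otus") %||% character()
}

#' Cumulative removal ledger
#'
#' @param tbl a tibble that has passed through one or more filter steps.
#' @return tibble with columns `step` and `otu_id`, in application order.
#' @export
filter_log <- function(tbl) {
  attr(tbl, "filter_log") %||% tibble(step = character(), otu_id = character())
}

drop_otus <- function(tbl, removed) {
  if (!length(removed)) return(tbl)
  tbl[setdiff(names(tbl), removed)]
}

annotate_filter <- function(out, step, removed) {
  log <- dplyr::bind_rows(
    filter_log(out),
    tibble(step = step, otu_id = as.character(removed))
  )
  attr(out, "removed_otus") <- as.character(removed)
  attr(out, "filter_log") <- log
  out
}
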