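# Relative-abundance and fourth-root transforms. The fourth root compresses
# the influence of dominant taxa so that rank-based ordination and
# dissimilarity statistics are not driven solely by the most abundant OTUs.

#' Convert counts to relative abundance
#'
#' Divides each count by its sample total. Samples whose total count is zero
#' become all-zero rows and trigger a warning (they cannot be normalized).
#'
#' @param tbl wide OTU tibble (`sample_id` + count columns).
#' @return a wide tibble of fractions with attribute `fourth_root = FALSE`;
#'   every non-degenerate row sums to 1 within 1e-9.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = "a", x = 2L, y = 2L, z = 6L)
#' relative_abundance(tbl)
relative_abundance <- function(tbl) {
  m <- otu_matrix(tbl)
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warn(paste0(
      "Zero-total sample(s) left as all-zero rows: ",
      paste(rownames(m)[zero], collapse = ", ")
    ))
  }
  rel <- m / ifelse(tot == 0, 1, tot)
  out <- matrix_to_otu_tbl(rel)
  attr(out, "fourth_root") <- FALSE
  out
}

#' Fourth-root transform of relative abundances
#'
#' Applies `x^(1/4)` elementwise. Values stay in \[0, 1\] and the transform is
#' strictly monotone, so rank-based statistics see the same ordering while
#' dominant OTUs are down-weighted. Applying the transform twice is refused.
#'
#' @param rel a relative-abundance tibble from [relative_abundance()] (values
#'   in \[0, 1\]).
#' @return the transformed tibble with attribute `fourth_root = TRUE`.
#' @export
fourth_root <- function(rel) {
  check_that(
    !isTRUE(attr(rel, "fourth_root")),
    "`rel` has already been fourth-root transformed."
  )
  m <- otu_matrix(rel, check = FALSE)
  check_that(
    all(m >= 0 & m <= 1),
    "`rel` must contain relative abundances in [0, 1]."
  )
  out <- matrix_to_otu_tbl(m^0.25)
  attr(out, "fourth_root") <- TRUE
  out
}

#' Has a table been fourth-root transformed?
#'
#' @param rel a tibble produced by [relative_abundance()] or [fourth_root()].
#' @return logical.
#' @export
is_fourth_root <- function(rel) isTRUE(attr(rel, "fourth_root"))
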