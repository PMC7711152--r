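# SIMPER: additive decomposition of the average between-group Bray-Curtis
# dissimilarity into per-OTU contributions. For each between-group sample pair
# (j, k) OTU i contributes |x_ij - x_ik| / sum_m(x_mj + x_mk); contributions
# are averaged over all between-group pairs, so they sum exactly to the mean
# between-group Bray-Curtis dissimilarity.

#' Similarity percentage (SIMPER) decomposition
#'
#' Identifies the OTUs contributing most to the average Bray-Curtis
#' dissimilarity between groups. With more than two groups, every group pair
#' is decomposed.
#'
#' @param tbl wide abundance tibble (`sample_id` + numeric columns); typically
#'   relative abundances (possibly fourth-root transformed).
#' @param groups group labels, one per sample; every group must be non-empty.
#' @return object of class `amendr_simper`: `contributions` is a tibble with
#'   `comparison`, `otu_id`, `average` (mean per-pair contribution),
#'   `contribution_pct` and `cumulative_pct` (ranked by decreasing
#'   contribution); `overall` is a tibble of the mean between-group
#'   dissimilarity per comparison. [tidy()] returns the contributions,
#'   [glance()] the overall summaries.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = c("a1", "a2", "b1", "b2"),
#'   x = c(10, 12, 1, 0), y = c(1, 2, 9, 11)
#' )
#' tidy(simper(relative_abundance(tbl), c("A", "A", "B", "B")))
simper <- function(tbl, groups) {
  m <- otu_matrix(tbl, check = FALSE)
  check_that(all(m >= 0), "Abundances must be non-negative.")
  g <- as.factor(groups)
  check_that(length(g) == nrow(m), "`groups` must have one label per sample.")
  check_that(nlevels(g) >= 2, "SIMPER needs at least 2 groups.")
  check_that(
    all(table(g) >= 1),
    "Every group must have at least one sample."
  )

  pairs <- combn(levels(g), 2, simplify = FALSE)
  pieces <- lapply(pairs, function(pr) {
    simper_pair(m, which(g == pr[1]), which(g == pr[2]),
      comparison = paste(pr[1], pr[2], sep = " vs ")
    )
  })
  structure(
    list(
      contributions = dplyr::bind_rows(lapply(pieces, `[[`, "contributions")),
      overall = dplyr::bind_rows(lapply(pieces, `[[`, "overall"))
    ),
    class = "amendr_simper"
  )
}

simper_pair <- function(m, idx_a, idx_b, comparison) {
  ia <- rep(idx_a, each = length(idx_b))
  ib <- rep(idx_b, times = length(idx_a))
  numer <- abs(m[ia, , drop = FALSE] - m[ib, , drop = FALSE])
  denom <- rowSums(m[ia, , drop = FALSE] + m[ib, , drop = FALSE])
  check_that(
    all(denom > 0),
    "A between-group sample pair has zero total abundance."
  )
  avg <- colMeans(numer / denom)
  overall <- sum(avg)
  pct <- if (overall > 0) 100 * avg / overall else rep(0, length(avg))
  ord <- order(avg, decreasing = TRUE)
  contributions <- tibble(
    comparison = comparison,
    otu_id = colnames(m)[ord],
    average = unname(avg[ord]),
    contribution_pct = unname(pct[ord]),
    cumulative_pct = cumsum(unname(pct[ord]))
  )
  list(
    contributions = contributions,
    overall = tibble(
      comparison = comparison,
      overall_dissimilarity = overall,
      n_pairs = length(ia)
    )
  )
}

#' @export
print.amendr_simper <- function(x, n = 5, ...) {
  cat("<amendr_simper>\n")
  for (cmp in x$overall$comparison) {
    ov <- x$overall[x$overall$comparison == cmp, ]
    cat(
      "  ", cmp, ": mean between-group dissimilarity ",
      signif(ov$overall_dissimilarity, 4), "\n",
      sep = ""
    )
    top <- head(x$contributions[x$contributions$comparison == cmp, ], n)
    for (i in seq_len(nrow(top))) {
      cat(
        "    ", top$otu_id[i], "  ", signif(top$average[i], 3),
        " (", round(top$contribution_pct[i], 1), "%)\n",
        sep = ""
      )
    }
  }
  invisible(x)
}
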