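# Bray-Curtis dissimilarity, implemented directly (it is the metric under all
# ordination and variance statistics here).

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|u - v|) / sum(u + v)`: 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param u,v non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return scalar in \[0, 1\].
#' @export
#' @examples
#' bray_curtis(c(1, 0, 3), c(0, 2, 1)) # 5/7
bray_curtis <- function(u, v) {
  check_that(
    is.numeric(u) && is.numeric(v) && length(u) == length(v),
    "`u` and `v` must be numeric vectors of equal length."
  )
  check_that(all(u >= 0) && all(v >= 0), "Abundances must be non-negative.")
  denom <- sum(u + v)
  check_that(denom > 0, "Bray-Curtis is undefined for two all-zero vectors.")
  sum(abs(u - v)) / denom
}

#' Bray-Curtis dissimilarity matrix for an abundance table
#'
#' @param tbl wide abundance tibble (`sample_id` + numeric columns); counts,
#'   relative abundances, or transformed relative abundances.
#' @return a [stats::dist] object with sample ids as labels.
#' @export
bray_curtis_dist <- function(tbl) {
  m <- otu_matrix(tbl, check = FALSE)
  check_that(all(m >= 0), "Abundances must be non-negative.")
  check_that(all(rowSums(m) > 0), "Every sample must have positive total abundance.")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  stats::as.dist(d)
}

# Validate/coerce a dist or symmetric matrix into a labelled square matrix.
as_dissimilarity_matrix <- function(d) {
  if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else if (is.matrix(d)) {
    m <- d
  } else {
    abort("`d` must be a 'dist' object or a symmetric matrix.")
  }
  check_that(nrow(m) == ncol(m), "Dissimilarity matrix must be square.")
  check_that(
    isTRUE(all.equal(m, t(m), tolerance = 1e-10, check.attributes = FALSE)),
    "Dissimilarity matrix must be symmetric."
  )
  check_that(all(abs(diag(m)) < 1e-12), "Dissimilarity matrix must have a zero diagonal.")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("sample_", seq_len(nrow(m)))
  }
  m
}
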