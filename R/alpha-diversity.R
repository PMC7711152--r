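# Alpha-diversity estimators computed per sample from raw counts.

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over OTUs with `p_i > 0`, in natural-log units.
#'
#' @param counts one sample's count (or abundance) vector; at least one entry
#'   must be positive.
#' @return non-negative scalar; `H <= log(observed richness)` with equality iff
#'   the positive counts are uniform.
#' @export
#' @examples
#' shannon_index(c(1, 1, 1, 1)) # log(4)
shannon_index <- function(counts) {
  check_that(
    is.numeric(counts) && all(counts >= 0) && any(counts > 0),
    "`counts` must be non-negative with at least one positive entry."
  )
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Chao1 richness estimator
#'
#' Nonparametric richness based on singleton (`F1`) and doubleton (`F2`)
#' counts: `S_obs + F1^2 / (2 F2)` when `F2 > 0`, otherwise the bias-corrected
#' form `S_obs + F1 (F1 - 1) / 2`.
#'
#' @param counts one sample's integer count vector; at least one entry must be
#'   positive.
#' @return estimate `>=` observed richness.
#' @export
chao1 <- function(counts) {
  check_that(
    is.numeric(counts) && all(counts >= 0) && any(counts > 0) &&
      is_whole(counts),
    "`counts` must be non-negative integers with at least one positive entry."
  )
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Per-sample alpha diversity table
#'
#' @param tbl wide OTU tibble of counts.
#' @return tibble with `sample_id`, `richness` (observed OTUs), `shannon`
#'   (natural log) and `chao1`.
#' @export
alpha_diversity <- function(tbl) {
  m <- otu_matrix(tbl)
  tibble(
    sample_id = rownames(m),
    richness = as.integer(unname(rowSums(m > 0))),
    shannon = unname(apply(m, 1, shannon_index)),
    chao1 = unname(apply(m, 1, chao1))
  )
}
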