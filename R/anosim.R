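# Analysis of similarity (ANOSIM): rank-based permutation test of whether
# between-group dissimilarities exceed within-group dissimilarities.
#
#   R = (mean rank between - mean rank within) / (M / 2),  M = n(n-1)/2
#
# with mid-ranks for tied dissimilarities. R is near 0 when grouping is
# unrelated to the dissimilarities and reaches 1 when all between-group
# dissimilarities exceed all within-group ones.

#' Analysis of similarity (ANOSIM)
#'
#' Tests group structure in a dissimilarity matrix by comparing mean
#' between-group and within-group dissimilarity ranks, with significance from
#' label permutations. When the number of distinct relabelings is at most
#' `exhaustive_limit` (and `exhaustive = "auto"`), all relabelings are
#' enumerated and the p-value is the exact tail proportion (the observed
#' labeling counted); otherwise `n_permutations` random permutations are drawn
#' and `p = (b + 1) / (n_permutations + 1)` where `b` counts permuted `R >=`
#' observed `R`.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups group labels, one per sample; at least 2 groups, each with at
#'   least 2 members.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param exhaustive `"auto"` (default), `"never"`, or `"always"`.
#' @param exhaustive_limit enumeration threshold on distinct relabelings
#'   (default 10000).
#' @return object of class `amendr_anosim` with fields `statistic` (R),
#'   `p_value`, `n_permutations` (permutations actually evaluated),
#'   `exhaustive`, `seed`, and `permuted` (the permuted R distribution).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(12), 6), matrix(rnorm(12, 3), 6))
#' fit <- anosim_test(dist(x), rep(c("a", "b"), each = 6), seed = 1)
#' tidy(fit)
anosim_test <- function(d, groups, n_permutations = 999, seed = 1L,
                        exhaustive = c("auto", "never", "always"),
                        exhaustive_limit = 10000) {
  exhaustive <- match.arg(exhaustive)
  m <- as_dissimilarity_matrix(d)
  n <- nrow(m)
  g <- as.factor(groups)
  check_that(length(g) == n, "`groups` must have one label per sample.")
  check_that(nlevels(droplevels(g)) >= 2, "ANOSIM needs at least 2 groups.")
  g <- droplevels(g)
  check_that(
    all(table(g) >= 2),
    "Every group must have at least 2 members."
  )

  pair <- which(lower.tri(m), arr.ind = TRUE)
  r <- rank(m[pair], ties.method = "average") # mid-ranks
  big_m <- length(r)
  gi <- as.integer(g)

  r_of <- function(lbl_mat) {
    # lbl_mat: n x B matrix of integer labels; returns R for each column
    same <- lbl_mat[pair[, 1], , drop = FALSE] ==
      lbl_mat[pair[, 2], , drop = FALSE]
    n_within <- colSums(same)
    sum_within <- colSums(r * same)
    mean_within <- sum_within / n_within
    mean_between <- (sum(r) - sum_within) / (big_m - n_within)
    (mean_between - mean_within) / (big_m / 2)
  }

  r_obs <- r_of(matrix(gi, ncol = 1))

  n_distinct <- distinct_relabelings(table(g))
  use_exhaustive <- switch(exhaustive,
    auto = n_distinct <= exhaustive_limit,
    always = TRUE,
    never = FALSE
  )

  if (use_exhaustive) {
    labels <- multiset_permutations(gi)
    r_perm <- r_of(labels)
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- ncol(labels)
  } else {
    perms <- with_local_seed(seed, {
      vapply(seq_len(n_permutations), function(b) gi[sample.int(n)],
        integer(n)
      )
    })
    r_perm <- r_of(perms)
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }

  structure(
    list(
      statistic = unname(r_obs),
      p_value = p,
      n_permutations = as.integer(n_used),
      exhaustive = use_exhaustive,
      seed = as.integer(seed),
      groups = g,
      permuted = as.numeric(r_perm)
    ),
    class = "amendr_anosim"
  )
}

# Number of distinct assignments of a label multiset to positions.
distinct_relabelings <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# All distinct arrangements of the label multiset `gi`, as an n x m integer
# matrix (includes the identity arrangement). Recursive placement of each
# label level into the remaining positions.
multiset_permutations <- function(gi) {
  n <- length(gi)
  sizes <- table(gi)
  levels_int <- as.integer(names(sizes))
  rec <- function(positions, lv) {
    if (lv == length(levels_int)) {
      col <- rep(NA_integer_, n)
      col[positions] <- levels_int[lv]
      return(matrix(col, ncol = 1))
    }
    k <- sizes[[lv]]
    chosen <- combn(positions, k, simplify = FALSE)
    do.call(cbind, lapply(chosen, function(ch) {
      rest <- rec(setdiff(positions, ch), lv + 1)
      rest[ch, ] <- levels_int[lv]
      rest
    }))
  }
  rec(seq_len(n), 1L)
}

#' @export
print.amendr_anosim <- function(x, ...) {
  cat(
    "<amendr_anosim> R = ", signif(x$statistic, 5),
    ", p = ", signif(x$p_value, 4),
    " (", if (x$exhaustive) "exhaustive, " else "",
    x$n_permutations, " permutations)\n",
    sep = ""
  )
  invisible(x)
}
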