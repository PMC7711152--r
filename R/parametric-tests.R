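# Classical parametric tests used alongside the rank-based statistics: one-way
# ANOVA for differential abundance of individual OTUs across substrate bins,
# and the two-sample variance-ratio F-test for OTUs whose colonization is
# sporadic (rarely present, but abundant when present). Both delegate to the
# standard base-R fits.

#' One-way ANOVA
#'
#' Classical between/within mean-square ratio with an F-distribution p-value,
#' via [stats::aov()].
#'
#' @param values numeric response (e.g. one OTU's relative abundance).
#' @param groups group labels; at least 2 groups, total n greater than the
#'   number of groups.
#' @return tibble with `statistic` (F), `p_value`, `df_between`, `df_within`.
#' @export
#' @examples
#' anova_oneway(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3)) # F = 54
anova_oneway <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  check_that(
    is.numeric(values) && length(values) == length(g),
    "`values` and `groups` must have equal length."
  )
  check_that(nlevels(g) >= 2, "ANOVA needs at least 2 groups.")
  check_that(
    length(values) > nlevels(g),
    "Total sample size must exceed the number of groups."
  )
  means <- tapply(values, g, mean)
  ssb <- sum(tapply(values, g, length) * (means - mean(values))^2)
  ssw <- sum((values - means[g])^2)
  check_that(
    ssb > 0 || ssw > 0,
    "F is undefined: zero between-group and zero within-group variance."
  )
  fit <- anova(aov(values ~ g))
  tibble(
    statistic = fit[["F value"]][1],
    p_value = fit[["Pr(>F)"]][1],
    df_between = fit[["Df"]][1],
    df_within = fit[["Df"]][2]
  )
}

#' Two-sample variance-ratio F-test (two-sided)
#'
#' `F = var(x) / var(y)` with a two-sided p-value from the F distribution, via
#' [stats::var.test()]. Used to test whether abundance variance on solid
#' substrates exceeds that in water samples.
#'
#' @param x,y numeric samples, each of size >= 2; `var(y)` must be positive.
#' @return tibble with `statistic` (F), `p_value`, `df1`, `df2`.
#' @export
variance_ratio_test <- function(x, y) {
  check_that(
    is.numeric(x) && is.numeric(y) && length(x) >= 2 && length(y) >= 2,
    "`x` and `y` must each contain at least 2 values."
  )
  check_that(stats::var(y) > 0, "F is undefined: `y` has zero variance.")
  fit <- var.test(x, y, alternative = "two.sided")
  tibble(
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    df1 = unname(fit$parameter[1]),
    df2 = unname(fit$parameter[2])
  )
}
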