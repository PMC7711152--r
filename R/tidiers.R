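# broom-style tidy()/glance() methods for the fitted result objects.

#' @exportS3Method generics::tidy
tidy.amendr_nmds <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.amendr_nmds <- function(x, ...) {
  tibble(
    stress = x$stress,
    converged = x$converged,
    n_restarts = x$n_restarts,
    k = ncol(x$points) - 1L,
    n = nrow(x$points),
    seed = x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.amendr_anosim <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive,
    seed = x$seed
  )
}

#' @exportS3Method generics::glance
glance.amendr_anosim <- tidy.amendr_anosim

#' @exportS3Method generics::tidy
tidy.amendr_simper <- function(x, ...) x$contributions

#' @exportS3Method generics::glance
glance.amendr_simper <- function(x, ...) x$overall
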