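# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except the packaged succession tables where regeneration
# itself is under test.

# Tiny hand-checkable OTU table: 3 samples x 4 OTUs.
tiny_otu <- function() {
  tibble::tibble(
    sample_id = c("a", "b", "c"),
    otu_w = c(2L, 0L, 5L),
    otu_x = c(2L, 1L, 0L),
    otu_y = c(6L, 3L, 0L),
    otu_z = c(0L, 0L, 1L)
  )
}

# Wide tibble from a matrix with dimnames.
otu_tbl_from_matrix <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# Random count table for property-style loops.
random_otu_tbl <- function(n_samples, n_otus, lambda = 20) {
  m <- matrix(
    stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus,
    dimnames = list(
      sprintf("s%02d", seq_len(n_samples)),
      sprintf("o%02d", seq_len(n_otus))
    )
  )
  otu_tbl_from_matrix(m)
}

# Independent stress-1 evaluation used by the brute-force NMDS oracle: same
# definition (isotonic regression on the dissimilarity rank order) but
# computed outside the package's optimization path.
oracle_stress <- function(par, delta, n, k) {
  x <- matrix(par, n, k)
  dv <- as.numeric(stats::dist(x))
  ord <- order(delta, dv)
  dhat <- numeric(length(dv))
  dhat[ord] <- stats::isoreg(dv[ord])$yf
  sqrt(sum((dhat - dv)^2) / sum(dv^2))
}

# Dense random-restart direct minimization of oracle_stress.
oracle_min_stress <- function(dmat, k, n_starts = 60, seed = 5) {
  delta <- dmat[lower.tri(dmat)]
  n <- nrow(dmat)
  best <- Inf
  withr::with_seed(seed, {
    for (i in seq_len(n_starts)) {
      o <- stats::optim(stats::rnorm(n * k), oracle_stress,
        delta = delta, n = n, k = k,
        method = "Nelder-Mead", control = list(maxit = 8000, reltol = 1e-13)
      )
      o <- stats::optim(o$par, oracle_stress,
        delta = delta, n = n, k = k,
        method = "Nelder-Mead", control = list(maxit = 8000, reltol = 1e-14)
      )
      best <- min(best, o$value)
    }
  })
  best
}
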