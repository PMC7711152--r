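# Non-metric multidimensional scaling by majorization (SMACOF-style Guttman
# updates) alternated with monotone (isotonic) regression of configuration
# distances on the rank order of the input dissimilarities. The criterion is
# Kruskal stress-1:
#
#   stress = sqrt( sum((dhat_ij - d_ij)^2) / sum(d_ij^2) )
#
# where d are configuration distances and dhat the monotone disparities. Ties
# in the input dissimilarities are handled by Kruskal's primary approach
# (tied dissimilarities impose no order among themselves): pairs are ordered
# by dissimilarity with configuration distance as tie-break before the pooled
# adjacent violators fit.

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Best-of-restarts NMDS: restart 1 starts from the classical metric
#' eigendecomposition ([stats::cmdscale()]), the remaining restarts from
#' seeded random Gaussian configurations. Within a restart, stress is
#' non-increasing across iterations (an iteration that would increase stress
#' is rejected and the restart stops). Deterministic for a fixed seed.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix with zero
#'   diagonal.
#' @param k embedding dimension (default 2); requires `n >= k + 1` samples.
#' @param n_restarts number of starts (default 20: 1 metric + 19 random).
#' @param max_iter maximum majorization iterations per restart (default 300).
#' @param tol relative stress-improvement convergence tolerance (default 1e-6).
#' @param seed integer seed for the random starts.
#' @return object of class `amendr_nmds`: `points` (tibble `sample_id`,
#'   `NMDS1..NMDSk`), `stress`, `converged`, `n_restarts`, `seed`,
#'   `stress_trace` (per-iteration stress of the best restart). Use [tidy()]
#'   for coordinates, [glance()] for the fit summary, [autoplot()] to plot.
#' @export
#' @examples
#' pts <- matrix(rnorm(20), 10, 2)
#' fit <- nmds(dist(pts), k = 2, n_restarts = 5, seed = 7)
#' glance(fit)
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-6,
                 seed = 1L) {
  m <- as_dissimilarity_matrix(d)
  n <- nrow(m)
  check_that(k >= 1 && is_whole(k), "`k` must be a positive integer.")
  check_that(n >= k + 1, "NMDS needs at least k + 1 samples.")
  check_that(n_restarts >= 1, "`n_restarts` must be >= 1.")

  pair <- which(lower.tri(m), arr.ind = TRUE)
  delta <- m[pair]

  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1) metric_start(m, k) else matrix(rnorm(n * k), n, k)
      run <- nmds_single(x0, pair, delta, max_iter, tol)
      if (is.null(best) || run$stress < best$stress) best <- run
    }
  })

  colnames(best$conf) <- paste0("NMDS", seq_len(k))
  structure(
    list(
      points = dplyr::bind_cols(
        tibble(sample_id = rownames(m)),
        as_tibble(best$conf, .name_repair = "minimal")
      ),
      stress = best$stress,
      converged = best$converged,
      n_restarts = as.integer(n_restarts),
      seed = as.integer(seed),
      stress_trace = best$trace
    ),
    class = "amendr_nmds"
  )
}

# One majorization run from configuration x0.
nmds_single <- function(x0, pair, delta, max_iter, tol) {
  x <- scale(x0, scale = FALSE) # center
  n <- nrow(x)
  i <- pair[, 1]
  j <- pair[, 2]
  dvec <- config_distances(x, i, j)
  s <- stress1(delta, dvec)
  trace <- s
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    dhat <- monotone_disparities(delta, dvec)
    x_new <- guttman_update(x, i, j, dvec, dhat, n)
    d_new <- config_distances(x_new, i, j)
    s_new <- stress1(delta, d_new)
    if (s_new > s + 1e-15) {
      # disparity refit can in principle let normalized stress tick up;
      # reject the step so the trace stays non-increasing
      converged <- TRUE
      break
    }
    improved <- (s - s_new) > tol * max(s, .Machine$double.eps)
    x <- x_new
    dvec <- d_new
    s <- s_new
    trace <- c(trace, s)
    if (!improved) {
      converged <- TRUE
      break
    }
  }
  list(conf = x, stress = s, converged = converged, trace = trace)
}

config_distances <- function(x, i, j) {
  sqrt(rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2))
}

stress1 <- function(delta, dvec) {
  dhat <- monotone_disparities(delta, dvec)
  sqrt(sum((dhat - dvec)^2) / sum(dvec^2))
}

# Isotonic (PAVA) fit of configuration distances against the dissimilarity
# rank order; primary tie approach via distance tie-break.
monotone_disparities <- function(delta, dvec) {
  ord <- order(delta, dvec)
  fit <- isoreg(dvec[ord])$yf
  out <- numeric(length(dvec))
  out[ord] <- fit
  out
}

# Guttman transform for the current disparities.
guttman_update <- function(x, i, j, dvec, dhat, n) {
  w <- ifelse(dvec > 0, dhat / dvec, 0)
  b <- matrix(0, n, n)
  b[cbind(i, j)] <- -w
  b[cbind(j, i)] <- -w
  diag(b) <- -rowSums(b)
  scale(b %*% x / n, scale = FALSE)
}

# Classical (metric) MDS start; pads with small noise if the eigen-start is
# rank-deficient in k dimensions.
metric_start <- function(m, k) {
  x <- suppressWarnings(cmdscale(stats::as.dist(m), k = k))
  if (ncol(x) < k) {
    x <- cbind(x, matrix(rnorm(nrow(m) * (k - ncol(x)), sd = 1e-4),
      nrow(m), k - ncol(x)
    ))
  }
  x
}

#' @export
print.amendr_nmds <- function(x, ...) {
  k <- ncol(x$points) - 1
  cat(
    "<amendr_nmds> ", nrow(x$points), " samples in ", k, " dimensions\n",
    "  stress-1 = ", signif(x$stress, 5),
    "  (", x$n_restarts, " restarts, seed ", x$seed,
    if (x$converged) ", converged" else ", NOT converged", ")\n",
    sep = ""
  )
  invisible(x)
}
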