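#' Simulate a seeded OTU count table with metadata
#'
#' Draws one sample per substrate bin x incubation x replicate from a
#' Dirichlet-multinomial model: the per-sample composition is Dirichlet with
#' mean given by the spec's base composition (after substrate and perturbation
#' fold-changes) and concentration `spec$concentration`; counts are multinomial
#' at a library size drawn uniformly from `spec$library_size_range`. Output is
#' bit-reproducible for a fixed spec (including its seed); the session RNG
#' state is left untouched.
#'
#' @param spec a [community_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{otu}{tibble, `sample_id` plus one integer column per OTU
#'       (`otu_001`, ...); one row per sample.}
#'     \item{metadata}{tibble with `sample_id`, `substrate_bin`, `incubation`,
#'       `is_control`.}
#'   }
#' @export
#' @examples
#' spec <- community_spec(20, 2, c("background", "steel"), seed = 42)
#' sim <- simulate_otu_table(spec)
#' dplyr::glimpse(sim$metadata)
simulate_otu_table <- function(spec) {
  check_that(inherits(spec, "community_spec"), "`spec` must be a community_spec.")
  grid <- tidyr::expand_grid(
    substrate_bin = spec$substrate_bins,
    incubation = spec$incubations,
    replicate = seq_len(spec$n_samples_per_group)
  )
  otu_ids <- otu_id_labels(spec$n_otus)

  counts <- with_local_seed(spec$seed, {
    t(vapply(seq_len(nrow(grid)), function(i) {
      mu <- mean_composition(spec, grid$substrate_bin[i], grid$incubation[i])
      p <- rdirichlet1(spec$concentration * mu)
      size <- sample_library_size(spec$library_size_range)
      as.numeric(rmultinom(1, size = size, prob = p))
    }, numeric(spec$n_otus)))
  })
  colnames(counts) <- otu_ids

  sample_id <- sprintf(
    "s%03d_%s_i%d_r%d", seq_len(nrow(grid)),
    grid$substrate_bin, grid$incubation, grid$replicate
  )
  list(
    otu = dplyr::bind_cols(
      tibble(sample_id = sample_id),
      as_tibble(counts, .name_repair = "minimal")
    ),
    metadata = tibble(
      sample_id = sample_id,
      substrate_bin = grid$substrate_bin,
      incubation = as.integer(grid$incubation),
      is_control = FALSE
    )
  )
}

#' Simulate sequencing negative-control samples
#'
#' Low-depth samples in which the spec's `contaminant_otus` are guaranteed a
#' relative abundance of at least 0.05% (in fact at least 0.1% by a
#' deterministic floor count) and all other OTUs are zero. At typical
#' negative-control depths a single stray read already exceeds the 0.05%
#' cutoff, so the non-contaminant background is necessarily zero; stray reads
#' in real controls are exactly what the filter is designed to flag. With no
#' `contaminant_otus` the controls are all-zero rows and the downstream filter
#' removes nothing. Used to exercise [filter_contaminants()].
#'
#' @param spec a [community_spec()] with non-empty `contaminant_otus` if
#'   contamination is to be detectable downstream.
#' @param n_controls number of control samples (>= 1).
#' @param depth sequencing depth of each control (default 2000 reads; negative
#'   controls are shallow because they amplify residual DNA only).
#' @return a list with `otu` (control count table over the same OTU universe)
#'   and `metadata` (all rows `substrate_bin = "control"`, `is_control = TRUE`).
#' @export
simulate_control_samples <- function(spec, n_controls, depth = 2000L) {
  check_that(inherits(spec, "community_spec"), "`spec` must be a community_spec.")
  check_that(
    is.numeric(n_controls) && length(n_controls) == 1 && n_controls >= 1 &&
      is_whole(n_controls),
    "`n_controls` must be a positive integer."
  )
  check_that(depth >= 10, "`depth` must be at least 10 reads.")
  n <- spec$n_otus
  cont <- spec$contaminant_otus
  otu_ids <- otu_id_labels(n)

  # Deterministic floor guarantees every contaminant clears the 0.05% control
  # cutoff in every control sample; the remaining depth is a multinomial draw
  # over the contaminants with unequal weights so control profiles vary.
  floor_count <- ceiling(0.001 * depth)
  counts <- with_local_seed(spec$seed + 1L, {
    t(vapply(seq_len(n_controls), function(i) {
      base <- numeric(n)
      if (length(cont)) {
        base[cont] <- floor_count
        rest <- depth - sum(base[cont])
        w <- rgamma(length(cont), shape = 2)
        base[cont] <- base[cont] +
          as.numeric(rmultinom(1, size = rest, prob = w / sum(w)))
      }
      base
    }, numeric(n)))
  })
  colnames(counts) <- otu_ids
  sample_id <- sprintf("control_%02d", seq_len(n_controls))
  list(
    otu = dplyr::bind_cols(
      tibble(sample_id = sample_id),
      as_tibble(counts, .name_repair = "minimal")
    ),
    metadata = tibble(
      sample_id = sample_id,
      substrate_bin = "control",
      incubation = NA_integer_,
      is_control = TRUE
    )
  )
}

#' Canonical five-incubation succession fixture
#'
#' A packaged synthetic community emulating a pulsed organic-matter amendment
#' in a five-deployment colonization series: substrate-linked OTUs
#' differentiate background water, carbonate, silica, mixed-sediment and steel
#' samples throughout; designated "bloom" OTUs spike in incubation 3 (the
#' amendment deployment); a designated methanogen-like OTU spikes in
#' incubation 4; and incubations 1, 2 and 5 share the unperturbed composition,
#' so incubation 5 returns close to the pre-amendment community. Two
#' contaminant OTUs are reserved for the negative controls.
#'
#' The fixture is regenerated deterministically from the seed; the copy under
#' `inst/extdata/` is byte-identical to `succession_fixture()` written with
#' [write_otu_table()].
#'
#' @param seed integer seed (default 1105).
#' @return a list with `otu`, `metadata`, `controls` (control count table),
#'   `control_metadata`, and `spec` (the generating [community_spec()]).
#' @export
succession_fixture <- function(seed = 1105L) {
  spec <- community_spec(
    n_otus = 60L,
    n_samples_per_group = 2L,
    substrate_bins = c("background", "carbonate", "silica", "mixed", "steel"),
    incubations = 1:5,
    dominance = 0.3,
    substrate_effect = tibble(
      otu  = c(1L, 6L, 2L, 3L, 4L, 5L),
      bin  = c(
        "background", "background", "carbonate", "silica", "mixed", "steel"
      ),
      fold = c(3, 8, 12, 12, 12, 10)
    ),
    perturbation_profile = tibble(
      incubation = c(3L, 3L, 4L),
      otu        = c(7L, 8L, 9L),
      fold       = c(25, 25, 20)
    ),
    contaminant_otus = c(59L, 60L),
    library_size_range = c(5000L, 47000L),
    concentration = 400,
    seed = as.integer(seed)
  )
  sim <- simulate_otu_table(spec)
  ctrl <- simulate_control_samples(spec, n_controls = 3L)
  list(
    otu = sim$otu, metadata = sim$metadata,
    controls = ctrl$otu, control_metadata = ctrl$metadata,
    spec = spec
  )
}

#' OTUs with designated roles in the succession fixture
#'
#' @return named list of OTU id character vectors: `dominant`, `bloom`
#'   (incubation-3 spike), `methanogen` (incubation-4 spike), `contaminant`.
#' @export
succession_fixture_roles <- function() {
  ids <- otu_id_labels(60L)
  list(
    dominant = ids[1],
    bloom = ids[7:8],
    methanogen = ids[9],
    contaminant = ids[59:60]
  )
}

otu_id_labels <- function(n) sprintf("otu_%03d", seq_len(n))

# One Dirichlet draw by gamma normalization.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # pathological only for vanishing concentrations; fall back to the mean
    return(alpha / sum(alpha))
  }
  g / s
}

sample_library_size <- function(range) {
  if (range[1] == range[2]) return(range[1])
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}
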