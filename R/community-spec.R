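#' Specification of a synthetic amplicon community
#'
#' Describes the generative model used by [simulate_otu_table()] and
#' [simulate_control_samples()]: a Dirichlet-multinomial count model whose mean
#' composition carries a designated dominant OTU, substrate-linked fold-changes,
#' and incubation-linked (perturbation) fold-changes. The simulator emulates
#' the structure of low-diversity deep-aquifer colonization surveys: one OTU
#' dominating most samples, library sizes spanning roughly 5,000-47,000 reads,
#' and contaminant OTUs present in sequencing negative controls.
#'
#' The base mean composition assigns `dominance` to OTU 1 and splits the
#' remaining mass over OTUs `2..n_otus` with a geometric decay (ratio 0.95),
#' so the designated dominant OTU always has expected relative abundance at
#' least `dominance` before effects are applied. Fold-changes multiply the mean
#' and the composition is renormalized, which keeps it a valid simplex point
#' under any combination of effects.
#'
#' @param n_otus number of OTUs (positive integer).
#' @param n_samples_per_group replicate samples per substrate bin x incubation
#'   cell (positive integer).
#' @param substrate_bins character vector of substrate bin labels, a subset of
#'   `substrate_bins()` excluding `"control"`.
#' @param incubations integer vector of incubation numbers (subset of 1:5).
#' @param dominance expected relative abundance of the dominant OTU (OTU 1),
#'   a fraction in (0, 1).
#' @param substrate_effect data frame with columns `otu` (integer index in
#'   `1..n_otus`), `bin` (a label in `substrate_bins`) and `fold` (> 0):
#'   multiplicative fold-change applied to that OTU's mean abundance in samples
#'   of that bin.
#' @param perturbation_profile data frame with columns `incubation`, `otu`,
#'   `fold`: fold-changes applied in the matching incubation (e.g. a
#'   heterotroph bloom after an organic-matter pulse).
#' @param contaminant_otus integer indices of OTUs seeded into negative
#'   controls.
#' @param library_size_range length-2 integer vector, `min <= max`, both >= 1;
#'   library sizes are drawn uniformly from this range.
#' @param concentration Dirichlet concentration scalar (> 0); larger values
#'   give less compositional overdispersion between replicate samples.
#' @param seed integer seed; all generators are bit-reproducible given the
#'   spec.
#'
#' @return an object of class `community_spec`.
#' @seealso [simulate_otu_table()], [simulate_control_samples()],
#'   [succession_fixture()]
#' @export
#' @examples
#' spec <- community_spec(
#'   n_otus = 40, n_samples_per_group = 3,
#'   substrate_bins = c("background", "carbonate"),
#'   substrate_effect = data.frame(otu = 2, bin = "carbonate", fold = 10)
#' )
#' sim <- simulate_otu_table(spec)
#' sim$otu
community_spec <- function(n_otus,
                           n_samples_per_group,
                           substrate_bins,
                           incubations = 1L,
                           dominance = 0.2,
                           substrate_effect = NULL,
                           perturbation_profile = NULL,
                           contaminant_otus = integer(),
                           library_size_range = c(5000L, 47000L),
                           concentration = 50,
                           seed = 1L) {
  check_that(
    is.numeric(n_otus) && length(n_otus) == 1 && n_otus >= 2 && is_whole(n_otus),
    "`n_otus` must be a single integer >= 2."
  )
  check_that(
    is.numeric(n_samples_per_group) && n_samples_per_group >= 1 &&
      is_whole(n_samples_per_group),
    "`n_samples_per_group` must be a positive integer."
  )
  check_that(
    is.character(substrate_bins) && length(substrate_bins) >= 1 &&
      !anyDuplicated(substrate_bins) &&
      all(substrate_bins %in% setdiff(SUBSTRATE_BINS, "control")),
    paste0(
      "`substrate_bins` must be distinct labels from: ",
      paste(setdiff(SUBSTRATE_BINS, "control"), collapse = ", ")
    )
  )
  check_that(
    all(incubations %in% 1:5) && !anyDuplicated(incubations),
    "`incubations` must be distinct integers in 1..5."
  )
  check_that(
    is.numeric(dominance) && length(dominance) == 1 &&
      dominance > 0 && dominance < 1,
    "`dominance` must be a fraction in (0, 1)."
  )
  check_that(
    is.numeric(library_size_range) && length(library_size_range) == 2 &&
      all(library_size_range >= 1) &&
      library_size_range[1] <= library_size_range[2] &&
      is_whole(library_size_range),
    "`library_size_range` must be (min, max) positive integers with min <= max."
  )
  check_that(
    is.numeric(concentration) && length(concentration) == 1 && concentration > 0,
    "`concentration` must be a positive scalar."
  )
  check_that(
    is.numeric(seed) && length(seed) == 1 && is_whole(seed),
    "`seed` must be a single integer."
  )

  substrate_effect <- validate_effect_table(
    substrate_effect, c("otu", "bin", "fold"), n_otus, substrate_bins
  )
  perturbation_profile <- validate_effect_table(
    perturbation_profile, c("incubation", "otu", "fold"), n_otus,
    incubations = incubations
  )
  check_that(
    all(contaminant_otus %in% seq_len(n_otus)),
    "`contaminant_otus` indices must lie in 1..n_otus."
  )

  structure(
    list(
      n_otus = as.integer(n_otus),
      n_samples_per_group = as.integer(n_samples_per_group),
      substrate_bins = substrate_bins,
      incubations = as.integer(sort(incubations)),
      dominance = dominance,
      substrate_effect = substrate_effect,
      perturbation_profile = perturbation_profile,
      contaminant_otus = as.integer(contaminant_otus),
      library_size_range = as.integer(library_size_range),
      concentration = concentration,
      seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

# Normalize/validate a fold-change table (NULL -> empty tibble).
validate_effect_table <- function(x, cols, n_otus, bins = NULL,
                                  incubations = NULL) {
  if (is.null(x)) {
    x <- as_tibble(setNames(
      lapply(cols, function(cl) if (cl == "bin") character() else numeric()),
      cols
    ))
    return(x)
  }
  check_that(
    is.data.frame(x) && all(cols %in% names(x)),
    paste0("Effect table must have columns: ", paste(cols, collapse = ", "))
  )
  x <- as_tibble(x)[cols]
  check_that(
    all(x$otu %in% seq_len(n_otus)),
    "Effect table references an OTU index outside 1..n_otus."
  )
  check_that(all(x$fold > 0), "Fold-changes must be > 0.")
  if (!is.null(bins)) {
    check_that(
      all(x$bin %in% bins),
      "Effect table references a bin not present in `substrate_bins`."
    )
  }
  if (!is.null(incubations)) {
    check_that(
      all(x$incubation %in% incubations),
      "Perturbation profile references an incubation not in `incubations`."
    )
  }
  x
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec>\n")
  cat("  OTUs:", x$n_otus, " dominant-OTU share:", x$dominance, "\n")
  cat(
    "  bins:", paste(x$substrate_bins, collapse = ", "),
    " incubations:", paste(x$incubations, collapse = ","), "\n"
  )
  cat(
    "  replicates/group:", x$n_samples_per_group,
    " library sizes:", paste(x$library_size_range, collapse = "-"), "\n"
  )
  cat(
    "  substrate effects:", nrow(x$substrate_effect),
    " perturbations:", nrow(x$perturbation_profile),
    " contaminants:", length(x$contaminant_otus), "\n"
  )
  cat("  concentration:", x$concentration, " seed:", x$seed, "\n")
  invisible(x)
}

#' Closed vocabulary of substrate bins
#'
#' Sample groupings used throughout: water samples are `"background"`,
#' polyurethane foam `"PUR"`, the pooled calcite/dolomite/HVD group
#' `"carbonate"`, glass wool `"silica"`, mixed siliciclastic sediments
#' `"mixed"`, low-carbon steel `"steel"`, degraded sponge material
#' `"organic"`, and sequencing negative controls `"control"`.
#'
#' @return character vector of valid `substrate_bin` labels.
#' @export
substrate_bins <- function() SUBSTRATE_BINS

# Expected (mean) composition for one sample: base simplex point with the
# dominant OTU share, modified by matching fold-changes, renormalized.
mean_composition <- function(spec, bin, incubation) {
  n <- spec$n_otus
  w <- 0.95^(seq_len(n - 1) - 1)
  base <- c(spec$dominance, (1 - spec$dominance) * w / sum(w))
  eff <- spec$substrate_effect
  if (nrow(eff)) {
    hit <- eff$bin == bin
    base[eff$otu[hit]] <- base[eff$otu[hit]] * eff$fold[hit]
  }
  per <- spec$perturbation_profile
  if (nrow(per)) {
    hit <- per$incubation == incubation
    base[per$otu[hit]] <- base[per$otu[hit]] * per$fold[hit]
  }
  base / sum(base)
}
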