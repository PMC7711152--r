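# Umbrella pipeline: simulate (optional) -> filter -> transform -> community
# statistics -> amendment model, with a run report that records every resolved
# parameter, seed and removal so the run can be reproduced exactly.

#' Build a pipeline configuration
#'
#' Assembles (and validates the shape of) the configuration consumed by
#' [run_pipeline()]. Either `simulate` is given (synthetic data are generated)
#' or `otu_path`/`metadata_path` (and optionally `controls_path`) point at
#' tab-separated inputs.
#'
#' @param simulate `NULL`, or a list of arguments for [community_spec()] plus
#'   optionally `n_controls` (default 3).
#' @param otu_path,metadata_path,controls_path input files, used when
#'   `simulate` is `NULL`.
#' @param filter list: `singletons` (logical), `threshold` (dataset-wide
#'   relative-abundance threshold), `control_cutoff`, `rule` (`"max"` or
#'   `"mean"`).
#' @param stats list: `group_col` (metadata column for grouping), `k`,
#'   `n_restarts`, `n_permutations`, `per_incubation` (logical: repeat the
#'   ANOSIM by group within each incubation).
#' @param amendment `NULL` or a list overriding the amendment-model defaults
#'   (`n_sponges`, `mean_mass`, `carbon_fraction`, `nitrogen_fraction`,
#'   `well_diameter`, `diffusion_coeff`, `near_offset`, `far_offset`,
#'   `water_volume_l`, `t_days`, `cells_per_ml`).
#' @param seed global seed used for every stochastic stage.
#' @param out_dir optional directory; when set, tables, the dissimilarity
#'   matrix and the report are written there.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            otu_path = NULL, metadata_path = NULL,
                            controls_path = NULL,
                            filter = list(),
                            stats = list(),
                            amendment = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  check_that(
    !is.null(simulate) || (!is.null(otu_path) && !is.null(metadata_path)) ||
      !is.null(amendment),
    paste(
      "Provide `simulate`, `otu_path` + `metadata_path`, or an",
      "amendment-only configuration."
    )
  )
  filter <- utils::modifyList(
    list(singletons = TRUE, threshold = 1e-4, control_cutoff = 5e-4,
         rule = "max"),
    filter
  )
  stats <- utils::modifyList(
    list(group_col = "substrate_bin", k = 2, n_restarts = 20,
         n_permutations = 999, per_incubation = TRUE),
    stats
  )
  check_that(
    is.numeric(seed) && length(seed) == 1 && is_whole(seed),
    "`seed` must be a single integer."
  )
  structure(
    list(
      simulate = simulate, otu_path = otu_path,
      metadata_path = metadata_path, controls_path = controls_path,
      filter = filter, stats = stats, amendment = amendment,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order -- simulate, filter (singletons, rare
#' OTUs, contaminants), transform (relative abundance then fourth root),
#' community statistics (Bray-Curtis, NMDS, ANOSIM, SIMPER, alpha diversity),
#' amendment model -- and returns a run report. Two runs with an identical
#' configuration produce identical reports.
#'
#' @param config a [pipeline_config()] or path to a YAML config file.
#' @return object of class `amendr_report`: a list with `version`, `config`,
#'   `filter_log`, `alpha`, `stats` (NMDS summary + coordinates, ANOSIM
#'   results, SIMPER overall table) and `amendment` (budget, source strength,
#'   diffusion report, scenario durations, per-cell rates), plus the processed
#'   tables under `data`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  check_that(inherits(config, "pipeline_config"), "`config` must be a pipeline_config.")

  report <- list(
    version = as.character(utils::packageVersion("amendr")),
    config = unclass(config)
  )

  # --- data stage -----------------------------------------------------------
  has_data <- !is.null(config$simulate) || !is.null(config$otu_path)
  otu <- metadata <- controls <- filtered <- d <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    n_controls <- sim_args$n_controls %||% 3L
    sim_args$n_controls <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    spec <- do.call(community_spec, sim_args)
    sim <- simulate_otu_table(spec)
    otu <- sim$otu
    metadata <- sim$metadata
    controls <- if (length(spec$contaminant_otus) || n_controls > 0) {
      simulate_control_samples(spec, n_controls)$otu
    }
  } else if (!is.null(config$otu_path)) {
    otu <- read_otu_table(config$otu_path)
    metadata <- read_sample_metadata(config$metadata_path)
    controls <- if (!is.null(config$controls_path)) {
      read_otu_table(config$controls_path)
    }
  }

  if (has_data) {
    # --- filter stage -------------------------------------------------------
    filtered <- otu
    if (isTRUE(config$filter$singletons)) {
      filtered <- remove_singletons(filtered)
    }
    filtered <- filter_rare_otus(filtered, threshold = config$filter$threshold)
    if (!is.null(controls)) {
      controls_kept <- controls[names(controls) %in% names(filtered)]
      filtered <- filter_contaminants(
        filtered, controls_kept,
        cutoff = config$filter$control_cutoff, rule = config$filter$rule
      )
    }
    report$filter_log <- filter_log(filtered)

    # --- transform + alpha --------------------------------------------------
    report$alpha <- alpha_diversity(filtered)
    rel4 <- fourth_root(relative_abundance(filtered))

    # --- community statistics -----------------------------------------------
    md <- metadata[match(filtered$sample_id, metadata$sample_id), ]
    keep <- !md$is_control
    rel_stats <- rel4[keep, ]
    md_stats <- md[keep, ]
    groups <- md_stats[[config$stats$group_col]]
    d <- bray_curtis_dist(rel_stats)

    ord <- nmds(d,
      k = config$stats$k, n_restarts = config$stats$n_restarts,
      seed = config$seed
    )
    global_anosim <- anosim_test(d, groups,
      n_permutations = config$stats$n_permutations, seed = config$seed
    )
    sim_res <- simper(rel_stats, groups)

    per_inc <- NULL
    if (isTRUE(config$stats$per_incubation) &&
      "incubation" %in% names(md_stats)) {
      per_inc <- dplyr::bind_rows(lapply(
        sort(unique(md_stats$incubation)),
        function(i) {
          sel <- which(md_stats$incubation == i)
          g <- droplevels(as.factor(groups[sel]))
          if (nlevels(g) < 2 || any(table(g) < 2)) return(NULL)
          fit <- anosim_test(
            stats::as.dist(as.matrix(d)[sel, sel]), g,
            n_permutations = config$stats$n_permutations, seed = config$seed
          )
          dplyr::mutate(tidy(fit), incubation = i, .before = 1)
        }
      ))
    }

    report$stats <- list(
      nmds = glance(ord),
      nmds_points = ord$points,
      anosim = tidy(global_anosim),
      anosim_per_incubation = per_inc,
      simper_overall = sim_res$overall,
      simper_top = dplyr::slice_head(
        dplyr::group_by(sim_res$contributions, .data$comparison),
        n = 5
      )
    )
  }

  # --- amendment model ------------------------------------------------------
  if (!is.null(config$amendment)) {
    am <- utils::modifyList(
      list(
        n_sponges = 5L, mean_mass = 0.37, carbon_fraction = 0.4744,
        nitrogen_fraction = 0.1615, well_diameter = 0.086,
        diffusion_coeff = 1.06e-9, near_offset = 0.25, far_offset = 2.0,
        water_volume_l = 10.6, t_days = c(37, 74), cells_per_ml = 4.1e6
      ),
      config$amendment
    )
    budget <- sponge_budget(
      am$n_sponges, am$mean_mass, am$carbon_fraction, am$nitrogen_fraction
    )
    n_areal <- areal_source_strength(budget$carbon_mol, am$well_diameter)
    model <- plane_source_model(
      n_areal,
      diffusion_coeff = am$diffusion_coeff,
      well_diameter = am$well_diameter, near_offset = am$near_offset,
      far_offset = am$far_offset, water_volume_l = am$water_volume_l
    )
    diff_rep <- diffusion_report(model, am$t_days)
    sched <- incubation_schedule()
    dur_low <- scenario_duration(sched, "midpoint3_to_midpoint5")
    dur_high <- scenario_duration(sched, "deploy3_to_mid_recovery3_4")
    report$amendment <- list(
      budget = budget,
      n_areal = n_areal,
      diffusion = diff_rep,
      durations = tibble(
        scenario = c("midpoint3_to_midpoint5", "deploy3_to_mid_recovery3_4"),
        days = c(dur_low, dur_high)
      ),
      rates = tibble(
        scenario = c("lower_bound", "upper_bound"),
        carbon_mol = c(min(diff_rep$closed_form_mol),
                       max(diff_rep$trapezoid_mol)),
        duration_days = c(dur_low, dur_high),
        fmol_c_per_cell_per_day = c(
          per_cell_rate(min(diff_rep$closed_form_mol), dur_low,
            am$cells_per_ml, am$water_volume_l
          ),
          per_cell_rate(max(diff_rep$trapezoid_mol), dur_high,
            am$cells_per_ml, am$water_volume_l
          )
        )
      )
    )
  }

  report$data <- list(
    otu = otu, metadata = metadata, controls = controls, filtered = filtered
  )
  report <- structure(report, class = "amendr_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (has_data) {
      write_otu_table(filtered, file.path(config$out_dir, "otu_filtered.tsv"))
      write_sample_metadata(metadata, file.path(config$out_dir, "metadata.tsv"))
      write_dissimilarity(d, file.path(config$out_dir, "bray_curtis.tsv"))
    }
    write_run_report(report, file.path(config$out_dir, "run_report.yml"))
  }
  report
}

#' Write a run report as structured text
#'
#' Serializes the report (minus the bulky data tables) to YAML: resolved
#' config, removal ledger, statistic outputs with seeds, and amendment-model
#' conventions. The file contains no timestamps, so identical runs produce
#' identical reports.
#'
#' @param report an `amendr_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  check_that(inherits(report, "amendr_report"), "`report` must be an amendr_report.")
  slim <- unclass(report)
  slim$data <- NULL
  slim <- rapply(slim, function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, classes = "data.frame", how = "replace")
  yaml::write_yaml(slim, path)
  invisible(path)
}

#' @export
print.amendr_report <- function(x, ...) {
  cat("<amendr_report> amendr", x$version, "\n")
  if (!is.null(x$data$otu)) {
    cat("  samples:", nrow(x$data$otu), " OTUs kept:",
        ncol(x$data$filtered) - 1, "\n")
    cat("  OTUs removed:", nrow(x$filter_log), "\n")
  }
  if (!is.null(x$stats)) {
    cat("  NMDS stress:", signif(x$stats$nmds$stress, 4),
        " ANOSIM R:", signif(x$stats$anosim$statistic, 4),
        " p:", signif(x$stats$anosim$p_value, 3), "\n")
  }
  if (!is.null(x$amendment)) {
    cat("  diffused carbon (mol):",
        paste(signif(x$amendment$diffusion$closed_form_mol, 3),
              collapse = ", "), "\n")
    cat("  per-cell rates (fmol C/cell/day):",
        paste(signif(x$amendment$rates$fmol_c_per_cell_per_day, 3),
              collapse = ", "), "\n")
  }
  invisible(x)
}
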