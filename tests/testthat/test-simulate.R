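test_that("identical spec and seed give byte-identical tables", {
  spec <- community_spec(
    n_otus = 25, n_samples_per_group = 3,
    substrate_bins = c("background", "carbonate", "steel"),
    incubations = 1:2, contaminant_otus = c(3, 7), seed = 17
  )
  a <- simulate_otu_table(spec)
  b <- simulate_otu_table(spec)
  expect_identical(a, b)
  expect_identical(
    simulate_control_samples(spec, 4),
    simulate_control_samples(spec, 4)
  )
  # and the session RNG stream is untouched
  set.seed(1)
  before <- .Random.seed
  invisible(simulate_otu_table(spec))
  expect_identical(.Random.seed, before)
})

test_that("spec validation names the violated requirement", {
  ok <- list(
    n_otus = 10, n_samples_per_group = 2, substrate_bins = "background"
  )
  expect_error(
    do.call(community_spec, c(ok, list(dominance = 1.2))),
    "dominance"
  )
  expect_error(
    do.call(community_spec, c(ok, list(library_size_range = c(100, 10)))),
    "library_size_range"
  )
  expect_error(
    do.call(community_spec, c(ok, list(
      substrate_effect = data.frame(otu = 99, bin = "background", fold = 2)
    ))),
    "OTU index"
  )
  expect_error(
    do.call(community_spec, c(ok, list(
      substrate_effect = data.frame(otu = 2, bin = "granite", fold = 2)
    ))),
    "bin"
  )
  expect_error(
    do.call(community_spec, c(ok, list(contaminant_otus = 11))),
    "contaminant"
  )
})

test_that("counts sum to library sizes drawn inside the configured range", {
  spec <- community_spec(
    n_otus = 30, n_samples_per_group = 20,
    substrate_bins = c("background", "silica"),
    library_size_range = c(5000, 47000), seed = 3
  )
  sim <- simulate_otu_table(spec)
  m <- as.matrix(sim$otu[-1])
  sizes <- rowSums(m)
  expect_true(all(sizes >= 5000 & sizes <= 47000))
  expect_true(all(m == round(m) & m >= 0))
  expect_identical(sim$otu$sample_id, sim$metadata$sample_id)
})

test_that("dominant OTU's mean relative abundance matches the generative mean", {
  # Monte-Carlo against the specified mean: dominance 0.5, no effects,
  # 200 samples
  spec <- community_spec(
    n_otus = 30, n_samples_per_group = 200,
    substrate_bins = "background", dominance = 0.5, seed = 99
  )
  rel <- relative_abundance(simulate_otu_table(spec)$otu)
  expect_lt(abs(mean(rel$otu_001) - 0.5), 0.05)
})

test_that("empirical mean composition converges to the Dirichlet mean", {
  spec <- community_spec(
    n_otus = 12, n_samples_per_group = 500,
    substrate_bins = "carbonate", dominance = 0.3,
    substrate_effect = data.frame(otu = 2, bin = "carbonate", fold = 5),
    concentration = 40, seed = 7
  )
  rel <- as.matrix(relative_abundance(simulate_otu_table(spec)$otu)[-1])
  target <- amendr:::mean_composition(spec, "carbonate", 1L)
  se <- apply(rel, 2, stats::sd) / sqrt(nrow(rel))
  expect_true(all(abs(colMeans(rel) - target) <= 3 * se + 1e-12))
})

test_that("substrate fold-changes shift the affected OTU between bins", {
  spec <- community_spec(
    n_otus = 20, n_samples_per_group = 25,
    substrate_bins = c("background", "carbonate"),
    substrate_effect = data.frame(otu = 2, bin = "carbonate", fold = 10),
    seed = 21
  )
  sim <- simulate_otu_table(spec)
  rel <- relative_abundance(sim$otu)
  in_bin <- sim$metadata$substrate_bin == "carbonate"
  expect_gt(mean(rel$otu_002[in_bin]), 4 * mean(rel$otu_002[!in_bin]))
})

test_that("control samples carry the planted contaminants above the cutoff", {
  spec <- community_spec(
    n_otus = 50, n_samples_per_group = 2,
    substrate_bins = "background", contaminant_otus = c(3, 7), seed = 5
  )
  ctrl <- simulate_control_samples(spec, n_controls = 6)
  rel <- as.matrix(relative_abundance(ctrl$otu)[-1])
  expect_true(all(rel[, c(3, 7)] >= 0.0005))
  expect_true(all(rel[, -c(3, 7)] == 0))
  expect_true(all(ctrl$metadata$is_control))
  expect_error(simulate_control_samples(spec, 0), "n_controls")
})

test_that("empty contaminant list yields controls that remove nothing", {
  spec <- community_spec(
    n_otus = 15, n_samples_per_group = 2,
    substrate_bins = "background", seed = 5
  )
  ctrl <- simulate_control_samples(spec, n_controls = 2)
  sim <- simulate_otu_table(spec)
  filtered <- filter_contaminants(sim$otu, ctrl$otu)
  expect_identical(removed_otus(filtered), character())
  expect_identical(names(filtered), names(sim$otu))
})

test_that("succession fixture encodes bloom, methanogen spike and recovery", {
  fx <- succession_fixture()
  roles <- succession_fixture_roles()
  rel <- relative_abundance(fx$otu)
  inc <- fx$metadata$incubation

  mean_by_inc <- function(otu) {
    vapply(1:5, function(i) mean(rel[[otu]][inc == i]), numeric(1))
  }
  for (b in roles$bloom) {
    m <- mean_by_inc(b)
    expect_equal(which.max(m), 3)
    expect_true(all(m[3] > m[-3]))
  }
  meth <- mean_by_inc(roles$methanogen)
  expect_equal(which.max(meth), 4)

  comp <- function(i) colMeans(as.matrix(rel[inc == i, -1]))
  expect_lt(
    bray_curtis(comp(5), comp(1)),
    bray_curtis(comp(3), comp(1))
  )
})

test_that("packaged succession fixture files match deterministic regeneration", {
  fx <- succession_fixture()
  otu_path <- system.file("extdata", "succession_otu.tsv", package = "amendr")
  md_path <- system.file(
    "extdata", "succession_metadata.tsv", package = "amendr"
  )
  ctrl_path <- system.file(
    "extdata", "succession_controls.tsv", package = "amendr"
  )
  expect_equal(read_otu_table(otu_path), fx$otu, ignore_attr = TRUE)
  expect_equal(read_sample_metadata(md_path), fx$metadata, ignore_attr = TRUE)
  expect_equal(read_otu_table(ctrl_path), fx$controls, ignore_attr = TRUE)
})
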