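# Bray-Curtis, ANOSIM and SIMPER.

test_that("Bray-Curtis matches hand values and its boundary cases", {
  expect_equal(bray_curtis(c(1, 0, 3), c(0, 2, 1)), 5 / 7)
  expect_equal(bray_curtis(c(2, 3), c(2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 4)), 1) # disjoint supports
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Bray-Curtis matrix agrees with vegan and is a valid dissimilarity", {
  skip_if_not_installed("vegan")
  withr::with_seed(2, {
    tbl <- random_otu_tbl(7, 30)
    d <- bray_curtis_dist(tbl)
    expect_equal(
      as.numeric(d),
      as.numeric(vegan::vegdist(as.matrix(tbl[-1]), "bray"))
    )
    m <- as.matrix(d)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  })
})

test_that("ANOSIM attains its extremes on maximal and null structure", {
  # all between-group distances strictly exceed all within-group distances
  m <- matrix(0.9, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  m[1:3, 1:3] <- 0.1
  m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  g <- rep(c("a", "b"), each = 3)
  fit <- anosim_test(m, g)
  expect_equal(fit$statistic, 1)

  # all distances equal -> R = 0 (mid-ranks make both means equal)
  flat <- matrix(0.5, 6, 6)
  diag(flat) <- 0
  expect_equal(anosim_test(flat, g)$statistic, 0)

  expect_error(anosim_test(m, c("a", "a", "a", "a", "a", "b")), "2 members")
})

test_that("exhaustive ANOSIM reproduces a brute-force enumeration over all 20 relabelings", {
  withr::with_seed(6, {
    pts <- rbind(matrix(rnorm(6), 3), matrix(rnorm(6, mean = 1.2), 3))
    rownames(pts) <- paste0("s", 1:6)
    d <- dist(pts)
    g <- rep(c("a", "b"), each = 3)
    fit <- anosim_test(d, g)
    expect_true(fit$exhaustive)
    expect_equal(fit$n_permutations, 20L)

    # independent oracle: enumerate all C(6,3) assignments directly
    m <- as.matrix(d)
    r <- matrix(0, 6, 6)
    r[lower.tri(r)] <- rank(m[lower.tri(m)], ties.method = "average")
    r <- r + t(r)
    big_m <- 15
    r_for <- function(members_a) {
      within <- outer(seq_len(6) %in% members_a, seq_len(6) %in% members_a,
        FUN = "=="
      )
      rw <- mean(r[within & lower.tri(r)])
      rb <- mean(r[!within & lower.tri(r)])
      (rb - rw) / (big_m / 2)
    }
    all_r <- apply(combn(6, 3), 2, r_for)
    r_obs <- r_for(1:3)
    expect_equal(fit$statistic, r_obs)
    expect_equal(fit$p_value, mean(all_r >= r_obs - 1e-12))
  })
})

test_that("ANOSIM matches the vegan R statistic and is seed-reproducible", {
  skip_if_not_installed("vegan")
  withr::with_seed(13, {
    tbl <- random_otu_tbl(12, 25)
    g <- rep(c("a", "b", "c"), each = 4)
    d <- bray_curtis_dist(tbl)
    mine <- anosim_test(d, g, seed = 5, exhaustive = "never")
    ref <- vegan::anosim(as.matrix(tbl[-1]), g,
      permutations = 99, distance = "bray"
    )
    expect_equal(mine$statistic, unname(ref$statistic))
    again <- anosim_test(d, g, seed = 5, exhaustive = "never")
    expect_identical(tidy(mine), tidy(again))
    # random-permutation estimator floor
    expect_gte(mine$p_value, 1 / (mine$n_permutations + 1))
  })
})

test_that("SIMPER decomposition is exact: contributions sum to the mean between-group Bray-Curtis", {
  withr::with_seed(31, {
    for (i in 1:20) {
      tbl <- random_otu_tbl(8, 15)
      rel <- relative_abundance(tbl)
      g <- rep(c("a", "b"), each = 4)
      res <- simper(rel, g)
      bc <- as.matrix(bray_curtis_dist(rel))
      expect_equal(
        res$overall$overall_dissimilarity,
        mean(bc[1:4, 5:8]),
        tolerance = 1e-9
      )
      expect_equal(sum(res$contributions$contribution_pct), 100,
        tolerance = 1e-6
      )
    }
  })
})

test_that("SIMPER matches hand-computed pairwise terms on a 2x2 toy table", {
  tbl <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    x = c(0.8, 0.6, 0.1, 0.2),
    y = c(0.2, 0.4, 0.9, 0.8)
  )
  res <- simper(tbl, c("A", "A", "B", "B"))
  # pairs: (a1,b1), (a1,b2), (a2,b1), (a2,b2); all row sums are 1 -> denom 2
  cx <- mean(c(0.7, 0.6, 0.5, 0.4) / 2)
  cy <- mean(c(0.7, 0.6, 0.5, 0.4) / 2)
  got <- res$contributions
  expect_equal(got$average[got$otu_id == "x"], cx)
  expect_equal(got$average[got$otu_id == "y"], cy)
  expect_equal(res$overall$overall_dissimilarity, cx + cy)

  # identical groups -> zero dissimilarity and zero contributions
  dup <- tibble::tibble(
    sample_id = c("p", "q", "r", "s"),
    x = c(0.5, 0.5, 0.5, 0.5), y = c(0.5, 0.5, 0.5, 0.5)
  )
  res0 <- simper(dup, c("A", "A", "B", "B"))
  expect_equal(res0$overall$overall_dissimilarity, 0)
  expect_true(all(res0$contributions$average == 0))
})

test_that("SIMPER agrees with vegan and dispatches all group pairs", {
  skip_if_not_installed("vegan")
  withr::with_seed(14, {
    tbl <- random_otu_tbl(9, 12)
    rel <- relative_abundance(tbl)
    g <- rep(c("a", "b", "c"), each = 3)
    res <- simper(rel, g)
    expect_setequal(
      res$overall$comparison,
      c("a vs b", "a vs c", "b vs c")
    )
    ref <- summary(vegan::simper(as.matrix(rel[-1]), g))$a_b
    mine <- res$contributions[res$contributions$comparison == "a vs b", ]
    expect_equal(
      mine$average[match(rownames(ref), mine$otu_id)],
      unname(ref$average),
      tolerance = 1e-10
    )
  })
  expect_error(
    simper(tiny_otu(), factor(c("a", "a", "b"), levels = c("a", "b", "c"))),
    "at least one sample"
  )
})
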