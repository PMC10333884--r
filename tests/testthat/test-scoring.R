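test_that("PES matches hand-evaluated cases and its bounds", {
  expect_equal(pes(10, 30), 0.5)
  expect_equal(pes(c(5, 8, 2), c(0, 0, 0)), -3)
  expect_equal(pes(c(4, 4, 9), c(4, 4, 9)), 0)
  expect_error(pes(0, 0), "exclude")
  expect_error(pes(-1, 2), "non-negative")
})

test_that("PES bounds, antisymmetry and scale invariance hold on random input", {
  withr::with_seed(101, {
    for (i in 1:50) {
      n <- sample(1:12, 1)
      wt <- round(runif(n, 0, 1000), 2)
      pm <- round(runif(n, 0, 1000), 2)
      keep <- wt + pm > 0
      wt <- wt[keep]; pm <- pm[keep]
      if (length(wt) == 0) next
      s <- pes(wt, pm)
      expect_lte(abs(s), length(wt))
      expect_equal(pes(pm, wt), -s)
      # per-datapoint scale invariance
      k <- runif(length(wt), 0.1, 10)
      expect_equal(pes(k * wt, k * pm), s)
    }
    # equality at the bound only when one side is all zero
    expect_equal(pes(rep(0, 4), runif(4, 1, 5)), 4)
  })
})

test_that("exact Mann-Whitney agrees with the permutation oracle", {
  expect_equal(mann_whitney_two_sided(c(5, 6, 7), c(1, 2, 3)), 0.1)
  expect_equal(mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3)), 1)
  withr::with_seed(202, {
    for (i in 1:25) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      pool <- sample(1:1000, n1 + n2)   # tie-free: exact branch applies
      x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
      expect_equal(mann_whitney_two_sided(x, y), oracle_mw_p(x, y),
                   tolerance = 1e-12)
    }
  })
  # antisymmetry of the score leaves the p-value unchanged
  x <- c(10, 50, 80); y <- c(20, 30, 100, 400)
  expect_equal(mann_whitney_two_sided(x, y), mann_whitney_two_sided(y, x))
  # ties and large groups fall back to the corrected normal approximation
  expect_no_error(p <- mann_whitney_two_sided(rep(1:8, 3), rep(2:9, 3)))
  expect_true(p > 0 && p <= 1)
  expect_error(mann_whitney_two_sided(numeric(), 1:3), "non-empty")
})

test_that("classification applies the PES and p-value cutoffs", {
  expect_equal(classify_modulation(12, 9e-06), "enabling")
  expect_equal(classify_modulation(-14, 2e-07), "disabling")
  expect_equal(classify_modulation(1.2, 0.095), "not_significant")
  expect_equal(classify_modulation(5, 0.02), "not_significant")
  expect_equal(classify_modulation(5, 0.005, p_max = 0.001),
               "not_significant")
})

test_that("pair observations enumerate peptide x replicate datapoints", {
  design <- tibble::tibble(
    protein_ac = "P",
    tile_start = c(1L, 1L, 5L, 5L, 9L, 9L),
    tile_end = c(16L, 16L, 20L, 20L, 24L, 24L),
    variant = rep(c("wild_type", "phosphomimetic"), 3),
    site_position = rep(c(NA_integer_, 10L), 3),
    mut_offset = NA_integer_,
    peptide = c("W1", "M1", "W2", "M2", "W3", "M3"),
    wt_peptide = c("W1", "W1", "W2", "W2", "W3", "W3")
  )
  counts <- tidyr::crossing(
    bait_id = "b", replicate_id = c("r1", "r2", "r3"),
    peptide = c("W1", "M1", "W2", "M2", "W3", "M3")
  ) |> dplyr::mutate(norm_count = 100)
  pairs <- build_pair_observations(counts, design)
  expect_equal(nrow(pairs), 9L)   # 3 peptide pairs x 3 replicates

  # a wt-only observation is retained as (nc_wt, 0)
  counts2 <- dplyr::filter(counts, peptide != "M1")
  pairs2 <- build_pair_observations(counts2, design)
  expect_equal(sum(pairs2$nc_pm == 0), 3L)
  expect_equal(nrow(pairs2), 9L)

  # both-zero datapoints are excluded
  counts3 <- dplyr::filter(counts, !peptide %in% c("W1", "M1"))
  expect_equal(nrow(build_pair_observations(counts3, design)), 6L)

  # a phosphomimetic entry without a wild-type partner is an error
  broken <- dplyr::filter(design, peptide != "W1")
  expect_error(build_pair_observations(counts, broken), "integrity")
})

test_that("pes_scores aggregates and classifies per bait and site", {
  design <- tibble::tibble(
    protein_ac = "P",
    tile_start = c(1L, 1L), tile_end = c(16L, 16L),
    variant = c("wild_type", "phosphomimetic"),
    site_position = c(NA_integer_, 10L), mut_offset = NA_integer_,
    peptide = c("W1", "M1"), wt_peptide = "W1"
  )
  counts <- tidyr::crossing(bait_id = "b",
                            replicate_id = paste0("r", 1:4),
                            peptide = c("W1", "M1")) |>
    dplyr::mutate(norm_count = ifelse(peptide == "M1", 900, 100) +
                    10 * as.integer(factor(replicate_id)))
  res <- pes_scores(build_pair_observations(counts, design))
  expect_equal(res$n, 4L)
  expect_gt(res$pes, 2)
  expect_equal(res$classification,
               classify_modulation(res$pes, res$p_value))
  res_adj <- pes_scores(build_pair_observations(counts, design),
                        adjust = TRUE)
  expect_true("p_adj" %in% names(res_adj))
})

test_that("K_D parsing handles numbers, bounds and no-binding cells", {
  out <- parse_kd(c("134", "1,900", "<3", "n.b.", "0.200"))
  expect_equal(out$value, c(134, 1900, 3, NA, 0.2))
  expect_equal(out$bound, c("exact", "exact", "upper", "none", "exact"))
  expect_error(parse_kd("approx 5"), "non-parseable")
})

test_that("fold changes carry direction and propagate bounds", {
  fc <- fold_change(134, "<3")
  expect_equal(fc$direction, "enabling")
  expect_gte(fc$fold, 44)
  expect_equal(fold_change(7, 7)$direction, "neutral")
  nb <- fold_change(16, "n.b.")
  expect_equal(nb$direction, "disabling")
  expect_equal(nb$fold, Inf)
  # symmetric magnitude, opposite direction
  ab <- fold_change(134, 23); ba <- fold_change(23, 134)
  expect_equal(ab$fold, ba$fold)
  expect_setequal(c(ab$direction, ba$direction),
                  c("enabling", "disabling"))
})

test_that("concordance reproduces the benchmark panel verdicts", {
  panel <- read_affinity_panel()
  conc <- concordance(panel)
  expect_equal(conc$n_tested, 28L)   # minor-pocket rows excluded
  expect_equal(conc$n_pass, 18L)
  expect_equal(conc$n_agree, 14L)
  v <- tidy(conc)
  clathrin <- v[v$ligand == "HURP_832-846", ]
  expect_true(clathrin$pass && clathrin$agree)
  pip4p2 <- v[v$ligand == "PIP4P2_17-32", ]
  expect_true(pip4p2$pass && !pip4p2$agree)
  expect_equal(glance(conc)$agreement_fraction, 14 / 18)
  # stringent mode is exposed without a fixed expected count
  strict <- concordance(panel, p_max = 0.001)
  expect_lte(strict$n_pass, conc$n_pass)
})

test_that("affinity fold correlations use finite rows only", {
  panel <- read_affinity_panel()
  fc <- affinity_fold_correlation(panel)
  expect_equal(fc$n, 30L)   # bound and n.b. rows excluded
  expect_true(fc$rho > 0.5)
  pf <- pes_fold_correlation(panel)
  expect_equal(pf$n, 26L)
  expect_equal(pf$rho, 0.529, tolerance = 0.01)
})

test_that("regulator annotation joins kinases and summarises fractions", {
  results <- tibble::tibble(
    bait_id = "b", protein_ac = paste0("P", 1:4),
    site_position = 1:4, n = 5, pes = c(5, -4, 3, 6),
    p_value = c(0.001, 0.002, 0.001, 0.5),
    classification = c("enabling", "disabling", "enabling",
                       "not_significant")
  )
  sites <- tibble::tibble(
    protein_ac = paste0("P", 1:4), position = 1:4,
    kinases = c("CDK1", "PLK1;CDK1", "", "CK2"),
    phosphatases = c("", "PP2A", "", "")
  )
  ann <- annotate_regulators(results, sites)
  expect_equal(ann$kinases[1], "CDK1")
  summ <- summarise_regulators(ann)
  expect_equal(summ$n_significant, 3L)
  expect_equal(summ$fraction_with_kinase, 2 / 3)
})

test_that("modulated-site counting matches direct filtering", {
  withr::with_seed(33, {
    tab <- tibble::tibble(pes = runif(500, -10, 10),
                          p_value = runif(500))
  })
  out <- count_modulated(tab)
  expect_equal(out$n_modulated,
               sum(tab$p_value <= 0.01 & abs(tab$pes) >= 2))
  expect_equal(out$n_total, 500L)
  strict <- count_modulated(tab, p_max = 0.001)
  expect_lte(strict$n_modulated, out$n_modulated)
})
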