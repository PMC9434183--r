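toy_profiles <- function() {
  stages <- flower_stages()
  sim <- simulate_metabolite_table(n_compounds = 6, stages = stages,
                                   noise_cv = 0, seed = 42)
  sim
}

test_that("normalisation divides by fresh weight and internal standard", {
  sim <- toy_profiles()
  tab <- sim$profiles
  tab$fw_mg <- 1; tab$istd <- 1
  expect_equal(normalize_profiles(tab)$value, tab$value)
  tab2 <- tab; tab2$fw_mg <- 2
  expect_equal(normalize_profiles(tab2)$value, tab$value / 2)
  # with the generated factors, the noiseless signal is recovered exactly
  norm <- normalize_profiles(sim$profiles)
  one <- norm[norm$compound == sim$truth$compound[1], ]
  stage_means <- tapply(one$value, one$stage, mean)
  per_stage <- tapply(one$value, one$stage, function(v) diff(range(v)))
  expect_true(all(per_stage < 1e-9 * stage_means)) # replicates identical
})

test_that("missing normalisation factors are reported per sample", {
  sim <- toy_profiles()
  tab <- sim$profiles
  tab$fw_mg[3] <- NA
  expect_error(normalize_profiles(tab), "sample")
})

test_that("log2 stage means follow the log identity and z-score convention", {
  tab <- tidyr::expand_grid(compound = "x", stage = c("S1", "S2", "S3"),
                            replicate = 1:2)
  tab$value <- rep(c(1, 2, 4), each = 2)
  m <- log2_stage_means(tab)
  expect_equal(as.numeric(m[1, -1]), c(0, 1, 2))
  sc <- log2_stage_means(tab, scale_rows = TRUE)
  row <- as.numeric(sc[1, -1])
  expect_equal(mean(row), 0, tolerance = 1e-9)
  expect_equal(sd(row), 1, tolerance = 1e-9)
  # constant compound cannot be scaled
  tab$value <- 5
  expect_warning(sc2 <- log2_stage_means(tab, scale_rows = TRUE), "constant")
  expect_true(all(is.na(sc2[1, -1])))
})

test_that("relative abundances are ratios to the youngest stage mean", {
  tab <- tidyr::expand_grid(compound = "x", stage = factor(c("S1", "S2", "S3"),
                                                           c("S1", "S2", "S3")),
                            replicate = 1:2)
  tab$value <- rep(c(10, 20, 40), each = 2)
  rel <- relative_to_reference(tab)
  expect_equal(unique(rel$value[rel$stage == "S1"]), 1)
  expect_equal(sort(unique(rel$value)), c(1, 2, 4))
  # invariant under global rescaling of the compound
  tab2 <- tab; tab2$value <- tab2$value * 17
  expect_equal(relative_to_reference(tab2)$value, rel$value)
  # zero reference mean drops the compound
  tab$value[tab$stage == "S1"] <- 0
  expect_warning(rel0 <- relative_to_reference(tab), "Dropping")
  expect_equal(nrow(rel0), 0)
})

test_that("summary t-test reproduces published phase comparisons", {
  # fructose label accumulation: preanthesis vs anthesis differ,
  # anthesis vs postanthesis do not
  expect_lt(ttest_from_summary(437.16, 103.16, 3, 2378.80, 25.09, 3)$p, 0.05)
  expect_gt(ttest_from_summary(2378.80, 25.09, 3, 2418.67, 212.58, 3)$p, 0.05)
  # identical summaries
  out <- ttest_from_summary(5, 1, 3, 5, 1, 3)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # degenerate zero-spread cases
  expect_equal(ttest_from_summary(5, 0, 3, 5, 0, 3)$p, 1)
  expect_warning(z <- ttest_from_summary(5, 0, 3, 6, 0, 3), "Zero")
  expect_equal(z$p, 0)
})

test_that("welch and pooled variants are both available and differ", {
  w <- ttest_from_summary(588.81, 87.27, 3, 436.99, 8.60, 3, var_equal = FALSE)
  s <- ttest_from_summary(588.81, 87.27, 3, 436.99, 8.60, 3, var_equal = TRUE)
  expect_equal(s$df, 4)
  expect_lt(w$df, 4)
  expect_gt(w$p, s$p)
})

test_that("compact letters separate exactly the significantly different groups", {
  # three well-separated groups
  expect_equal(compact_letters(c(0, 100, 200), c(1, 1, 1), c(3, 3, 3)),
               c("a", "b", "c"))
  # all identical
  expect_equal(compact_letters(c(5, 5, 5), c(1, 1, 1), c(3, 3, 3)),
               c("a", "a", "a"))
  # published succinate pattern: anthesis peak, flanks equivalent
  expect_equal(compact_letters(c(137.83, 431.74, 155.27),
                               c(14.18, 27.73, 6.66), c(3, 3, 3)),
               c("a", "b", "a"))
  # chain pattern: a ~ b, b ~ c, but a != c must share no letter
  lt <- letters_pattern <- compact_letters(c(0, 2.2, 4.4), c(1, 1, 1), c(3, 3, 3))
  shared_ac <- intersect(strsplit(lt[1], "")[[1]], strsplit(lt[3], "")[[1]])
  if (ttest_from_summary(0, 1, 3, 4.4, 1, 3)$p < 0.05) {
    expect_equal(length(shared_ac), 0)
  }
})

test_that("replicate-level pairwise tests agree with the summary path", {
  set.seed(9)
  stages <- flower_stages()
  sim <- simulate_metabolite_table(n_compounds = 8, stages = stages,
                                   noise_cv = 0.15, seed = 9)
  norm <- normalize_profiles(sim$profiles)
  res <- pairwise_stage_ttests(norm, grouping = "phase")
  expect_true(all(c("mean", "se", "n", "letter", "bold") %in% names(res)))
  # recompute letters from the summary statistics of one compound
  one <- res[res$compound == res$compound[1], ]
  lt <- compact_letters(one$mean, one$se * sqrt(one$n), one$n)
  expect_equal(one$letter, lt)
})

test_that("identical groups earn a single letter; separated groups earn three and bold", {
  tab <- tidyr::expand_grid(compound = "x",
                            phase = c("preanthesis", "anthesis", "postanthesis"),
                            replicate = 1:3)
  tab$stage <- paste0(tab$phase, "_s")
  tab$value <- rep(c(10, 10.01, 9.99), times = 3)
  same <- pairwise_stage_ttests(tab, grouping = "phase")
  expect_true(all(same$letter == "a"))
  tab$value <- rep(c(10, 1000, 4000), each = 3) + rep(c(-1, 0, 1), times = 3)
  diff3 <- pairwise_stage_ttests(tab, grouping = "phase")
  expect_equal(sort(unique(diff3$letter)), c("a", "b", "c"))
  expect_true(all(diff3$bold))
})

test_that("heatmap clustering separates planted stage archetypes", {
  sim <- simulate_metabolite_table(
    n_compounds = 20, noise_cv = 0.05,
    archetype_probs = c(up = 0.5, down = 0.5, peak_at_anthesis = 0, flat = 0),
    seed = 31
  )
  norm <- normalize_profiles(sim$profiles)
  m <- log2_stage_means(norm, scale_rows = TRUE)
  mm <- as.matrix(m[, -1])
  rownames(mm) <- m$compound
  cut2 <- cutree(hclust(dist(mm), method = "complete"), k = 2)
  planted <- sim$truth$archetype[match(rownames(mm), sim$truth$compound)]
  tab <- table(cut2, planted)
  # each cluster is pure for one archetype
  expect_equal(sum(apply(tab, 1, max)), length(planted))
})
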