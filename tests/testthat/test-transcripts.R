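toy_counts <- function(seed = 21, n_genes = 200) {
  simulate_count_matrix(n_genes = n_genes, seed = seed)
}

test_that("low-count filtering is a strict less-than rule on the total", {
  m <- matrix(c(9, 0, 0, 0,
                5, 5, 0, 0,
                0, 0, 0, 11), nrow = 3, byrow = TRUE,
              dimnames = list(c("below", "at", "above"), NULL))
  suppressMessages({
    kept <- filter_low_counts(m, min_total = 10)
    expect_equal(rownames(kept), c("at", "above"))
    expect_equal(attr(kept, "removed"), "below")
    # min_total = 0 is the identity
    expect_equal(nrow(filter_low_counts(m, min_total = 0)), 3)
    # per-sample mode
    ps <- filter_low_counts(matrix(c(3, 3, 3, 3, 1, 9), 3, 2), min_total = 2,
                            per_sample = TRUE)
    expect_equal(nrow(ps), 2)
  })
})

test_that("planted near-zero genes are removed by the low-count rule", {
  sim <- simulate_count_matrix(n_genes = 1000, frac_low = 0.05, seed = 23)
  suppressMessages(kept <- filter_low_counts(sim$counts, 10))
  low_genes <- sim$truth$gene[sim$truth$low]
  expect_gt(length(low_genes), 10)
  expect_gt(mean(low_genes %in% attr(kept, "removed")), 0.95)
})

test_that("log-CPM matches its closed form and is scale invariant", {
  m <- matrix(c(0, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lc <- normalize_logcpm(m, prior = 0.5, lib_sizes = 1e6)
  expect_equal(lc["a", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["a", 1], -1, tolerance = 0.01)
  # doubling counts and library sizes leaves values unchanged up to the
  # (unscaled) pseudo-count
  lc2 <- normalize_logcpm(2 * m, prior = 0.5, lib_sizes = 2e6)
  expect_equal(lc2["b", 1], normalize_logcpm(m, 0.5, 1e6)["b", 1],
               tolerance = 0.01)
  # monotone in count at fixed library
  expect_gt(lc["b", 1], lc["a", 1])
  expect_error(normalize_logcpm(m, lib_sizes = 0), "positive")
})

test_that("noiseless quadratic genes pass the trend filter, flat null p-values are uniform", {
  stages <- flower_stages()
  ages <- rep(stages$age_days, each = 3)
  z <- scale(ages)[, 1]
  set.seed(25)
  n_null <- 400
  m <- rbind(
    quad1 = 5 + 0.5 * z + 0.8 * z^2,
    quad2 = 6 - 1.2 * z^2,
    matrix(rnorm(n_null * length(ages), mean = 5, sd = 0.3), n_null,
           dimnames = list(paste0("null", seq_len(n_null)), NULL))
  )
  fit <- trend_filter(m, ages, df = 3, fdr = 0.05)
  expect_true(all(fit$keep[1:2]))
  expect_gt(fit$F[1], 1e10) # noiseless fit: essentially infinite F
  null_p <- fit$p[-(1:2)]
  expect_gt(suppressWarnings(ks.test(null_p, "punif"))$p.value, 0.01)
  frac <- mean(null_p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_null))
})

test_that("trend filter refuses degenerate age designs", {
  m <- matrix(rnorm(20), 2, 10)
  expect_error(trend_filter(m, rep(1, 10)), "distinct ages")
})

test_that("stage contrasts are antisymmetric and control their null", {
  stages <- flower_stages()
  labels <- rep(as.character(stages$stage), each = 3)
  set.seed(27)
  m <- matrix(rnorm(300 * length(labels), 5, 0.5), 300,
              dimnames = list(paste0("g", 1:300), NULL))
  de <- stage_contrasts(m, labels, contrasts = list(c("S9", "S10")))
  de_flip <- stage_contrasts(m, labels, contrasts = list(c("S10", "S9")))
  expect_equal(de$t, -de_flip$t)
  expect_equal(de$p, de_flip$p)
  # identical populations: close to alpha raw, ~none after BH
  expect_lt(abs(mean(de$p <= 0.05) - 0.05), 0.05)
  expect_lt(mean(de$significant), 0.01)
  expect_error(stage_contrasts(m, labels, contrasts = list(c("S9", "S99"))),
               "missing")
})

test_that("planted differential genes are recalled across a contrast", {
  stages <- flower_stages()
  labels <- rep(as.character(stages$stage), each = 3)
  set.seed(28)
  n <- 500
  m <- matrix(rnorm(n * length(labels), 5, 0.3), n,
              dimnames = list(paste0("g", 1:n), NULL))
  de_idx <- 1:50
  m[de_idx, labels == "S10"] <- m[de_idx, labels == "S10"] + 2 # 4-fold in log2
  de <- stage_contrasts(m, labels, contrasts = list(c("S9", "S10")), fdr = 0.05)
  # with 3 replicates per side the unmoderated Welch test has ~4 df, so even
  # 4-fold genes cannot all survive BH; raw-level recall is near-complete
  # while BH recall equilibrates far lower
  expect_gt(mean(de$p[de_idx] <= 0.05), 0.9)
  expect_gt(mean(de$significant[de_idx]), 0.4)
  expect_lt(mean(de$p[-de_idx] <= 0.05), 0.10)
})

test_that("k-means separates planted anthesis step archetypes with opposite signs", {
  stages <- flower_stages()
  post <- as.integer(stages$phase != "preanthesis") # step at flower opening
  set.seed(29)
  up <- t(replicate(20, 1 + 3 * post + rnorm(8, 0, 0.1)))
  down <- t(replicate(20, 4 - 3 * post + rnorm(8, 0, 0.1)))
  m <- rbind(up, down)
  colnames(m) <- as.character(stages$stage)
  rownames(m) <- paste0("g", 1:40)
  cl <- kmeans_profiles(m, k = 2, stages = stages, seed = 7)
  planted <- rep(c("up", "down"), each = 20)
  tab <- table(cl$assignment$cluster, planted)
  expect_equal(sum(apply(tab, 1, max)), 40) # perfect separation
  expect_equal(sort(cl$anthesis_step$direction), c("down", "up"))
  expect_lt(prod(cl$anthesis_step$step), 0) # opposite signs
  # seeded rerun is identical
  cl2 <- kmeans_profiles(m, k = 2, stages = stages, seed = 7)
  expect_equal(cl$assignment, cl2$assignment)
  # k = 1 collapses to the global mean profile
  cl1 <- kmeans_profiles(m, k = 1, stages = stages, seed = 7)
  z <- t(scale(t(m)))
  expect_equal(as.numeric(cl1$centroids[1, -1]), colMeans(z), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(kmeans_profiles(m, k = 100, stages = stages), "exceeds")
})

test_that("the funnel retains planted trend genes and controls flat genes", {
  sim <- simulate_count_matrix(n_genes = 600, frac_null = 0.5, frac_low = 0,
                               dispersion = 0.05, seed = 31)
  suppressMessages(kept <- filter_low_counts(sim$counts, 10))
  lc <- normalize_logcpm(kept)
  fit <- trend_filter(lc, sim$samples$age_days, fdr = 0.05)
  truth <- sim$truth[match(fit$gene, sim$truth$gene), ]
  # strong trend genes should mostly be kept
  strong <- !truth$null & abs(truth$b2) + abs(truth$b1) > 0.3
  expect_gt(mean(fit$keep[strong]), 0.8)
  # flat genes kept only at roughly the FDR level
  expect_lt(mean(fit$keep[truth$null]), 0.1)
})
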