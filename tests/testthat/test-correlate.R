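test_that("duplicated variables correlate perfectly and p collapses to zero", {
  set.seed(2)
  x <- rnorm(12)
  res <- pairwise_pearson(data.frame(a = x, b = x, c = rnorm(12)))
  expect_equal(res$r["a", "b"], 1)
  expect_equal(res$p["a", "b"], 0)
  expect_equal(res$r, t(res$r))
  expect_equal(diag(res$r), setNames(rep(1, 3), c("a", "b", "c")))
})

test_that("closed-form p matches the t critical value at 24 samples", {
  # r = 0.4044 on n = 24 sits at the 5% critical point (df = 22)
  t <- 0.4044 * sqrt(22) / sqrt(1 - 0.4044^2)
  p <- 2 * pt(-t, 22)
  expect_equal(p, 0.05, tolerance = 0.01)
  # and the package reproduces that p for data with that exact correlation
  set.seed(4)
  x <- rnorm(24)
  e <- rnorm(24)
  e <- residuals(lm(e ~ x))
  y <- 0.4044 * scale(x)[, 1] + sqrt(1 - 0.4044^2) * scale(e)[, 1]
  res <- pairwise_pearson(data.frame(x = x, y = y))
  expect_equal(res$r["x", "y"], 0.4044, tolerance = 1e-6)
  expect_equal(res$p["x", "y"], p, tolerance = 1e-6)
})

test_that("closed-form p agrees with an exact permutation oracle on 6 samples", {
  # single draws differ by the t approximation's error at n = 6, so compare
  # the closed form with the exact (720-permutation) null over many toys
  set.seed(8)
  diffs <- replicate(30, {
    x <- rnorm(6)
    y <- 0.5 * x + rnorm(6)
    res <- pairwise_pearson(data.frame(x = x, y = y))
    abs(res$p["x", "y"] - oracle_permutation_p(x, y))
  })
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.15)
})

test_that("correlations are invariant under positive affine maps and flip sign", {
  set.seed(5)
  x <- rnorm(15); y <- 0.7 * x + rnorm(15)
  r0 <- pairwise_pearson(data.frame(x, y))$r["x", "y"]
  r_aff <- pairwise_pearson(data.frame(x = 3 * x + 2, y))$r["x", "y"]
  r_neg <- pairwise_pearson(data.frame(x = -2 * x + 1, y))$r["x", "y"]
  expect_equal(r_aff, r0, tolerance = 1e-12)
  expect_equal(r_neg, -r0, tolerance = 1e-12)
})

test_that("missing values restrict pairs and zero-variance variables warn", {
  set.seed(6)
  d <- data.frame(a = rnorm(10), b = rnorm(10), z = rep(1, 10))
  d$a[1:3] <- NA
  expect_warning(res <- pairwise_pearson(d), "Zero-variance")
  expect_equal(res$n_used["a", "b"], 7)
  expect_true(is.na(res$r["z", "b"]))
})

test_that("count summary enumerates possible, significant, and strong pairs", {
  set.seed(7)
  d <- as.data.frame(matrix(rnorm(24 * 10), 24, 10))
  res <- pairwise_pearson(d)
  cs <- count_summary(res)
  expect_equal(cs$n_possible, 45)
  # planted blocks: two groups of 4 variables tightly correlated
  base1 <- rnorm(24); base2 <- rnorm(24)
  blocks <- cbind(
    sapply(1:4, function(i) base1 + rnorm(24, 0, 0.1)),
    sapply(1:4, function(i) base2 + rnorm(24, 0, 0.1))
  )
  colnames(blocks) <- paste0("v", 1:8)
  resb <- pairwise_pearson(as.data.frame(blocks))
  csb <- count_summary(resb, r_hi = 0.65, r_lo = -0.65)
  expect_equal(csb$n_strong_pos, 2 * choose(4, 2)) # within-block pairs only
})

make_cor_result <- function(r, n = 24) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), n - 2)
  diag(p) <- NA
  structure(
    list(variables = colnames(r), r = r, p = p,
         n_used = matrix(n, nrow(r), ncol(r), dimnames = dimnames(r)),
         min_pairs = 3),
    class = "correlation_result"
  )
}

test_that("network construction honours thresholds, betweenness, and the handshake lemma", {
  # 3-variable chain: A~B and B~C strong, A~C weak
  vars <- c("A", "B", "C")
  r <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.9,
                0.1, 0.9, 1), 3, 3, dimnames = list(vars, vars))
  res <- make_cor_result(r)
  net <- build_network(res, r_min = 0.65)
  expect_equal(nrow(net$edges), 2)
  btw <- setNames(net$nodes$betweenness, net$nodes$id)
  expect_equal(btw[["B"]], 1)
  expect_equal(btw[["A"]], 0)
  expect_equal(btw[["C"]], 0)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  # r_min = 1 gives a valid empty network (strict threshold)
  empty <- build_network(res, r_min = 1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
  # ties at the threshold are excluded
  tied <- build_network(res, r_min = 0.9)
  expect_equal(nrow(tied$edges), 0)
})

test_that("betweenness on a star graph is maximal at the hub", {
  vars <- c("hub", paste0("leaf", 1:4))
  r <- matrix(0.3, 5, 5, dimnames = list(vars, vars))
  r["hub", ] <- r[, "hub"] <- 0.9
  diag(r) <- 1
  net <- build_network(make_cor_result(r), r_min = 0.65)
  btw <- setNames(net$nodes$betweenness, net$nodes$id)
  # star on 5 nodes: hub betweenness = choose(4, 2) = 6, leaves 0
  expect_equal(btw[["hub"]], 6)
  expect_true(all(btw[setdiff(names(btw), "hub")] == 0))
  # negative-edge selection is symmetric
  rneg <- -r; diag(rneg) <- 1
  netn <- build_network(make_cor_result(rneg), r_min = 0.65, sign = "negative")
  expect_equal(nrow(netn$edges), 4)
  expect_true(all(netn$edges$sign == "negative"))
})

test_that("transcript-metabolite networks link a gene to its driving metabolite", {
  stages <- flower_stages()
  info <- tidyr::expand_grid(stage = stages$stage, replicate = 1:3) |>
    dplyr::left_join(stages, by = "stage")
  set.seed(13)
  met <- matrix(rnorm(nrow(info) * 3), ncol = 3,
                dimnames = list(NULL, c("m1", "m2", "m3")))
  tr <- matrix(rnorm(nrow(info) * 2), ncol = 2,
               dimnames = list(NULL, c("g1", "g2")))
  tr[, "g1"] <- 2 * met[, "m1"] + 5 # noiseless linear function
  net <- transcript_metabolite_network(tr, met, info, phase = "preanthesis",
                                       r_min = 0.8)
  edge <- net$edges[(net$edges$source == "g1" & net$edges$target == "m1") |
                      (net$edges$source == "m1" & net$edges$target == "g1"), ]
  expect_equal(nrow(edge), 1)
  expect_equal(edge$r, 1, tolerance = 1e-12)
  expect_true(all(c("gene") %in% net$nodes$class[net$nodes$id %in% c("g1", "g2")]))
  # too-small phase subsets are refused
  pre_rows <- which(info$phase == "preanthesis")[1:2]
  expect_error(
    transcript_metabolite_network(tr[pre_rows, ], met[pre_rows, ],
                                  info[pre_rows, ], phase = "postanthesis",
                                  include_anthesis = FALSE),
    "3 samples"
  )
})
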