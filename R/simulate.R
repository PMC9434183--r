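# multiplicative lognormal noise with mean 1 and the given CV
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a stage-resolved metabolite abundance table
#'
#' Generates a compound-by-sample abundance table with the structure of a
#' floral developmental time course: 8 stages x 3 replicates by default,
#' ~130 compounds with class labels and smooth stage trends. Each compound
#' follows one of four trend archetypes on log2 scale -- `up` (rising with
#' age), `down`, `peak_at_anthesis` (a bump centred on the anthesis age), or
#' `flat` -- with a per-compound log2 fold range drawn up to `log2_range`.
#' Observed raw values are the trend signal times multiplicative lognormal
#' noise, times the sample's fresh weight and internal-standard response
#' (drawn with 10% CV around 30 mg and 1.0), so that [normalize_profiles()]
#' recovers the noiseless signal exactly at `noise_cv = 0`.
#'
#' @param n_compounds Number of compounds (>= 2).
#' @param stages Stage metadata from [flower_stages()].
#' @param n_replicates Replicates per stage.
#' @param archetype_probs Named probabilities over the archetypes
#'   `up`, `down`, `peak_at_anthesis`, `flat`.
#' @param log2_range Maximum log2 fold range of a trend.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param fw_mean Mean fresh weight per sample (mg).
#' @param fw_cv,istd_cv CV of fresh weight and internal-standard draws.
#' @param seed Integer seed.
#' @return A list with `profiles` (long tibble ready for
#'   [read_profile_table()]-style analysis) and `truth` (per-compound
#'   archetype, effect size, and the noiseless normalised signal parameters).
#' @export
simulate_metabolite_table <- function(n_compounds = 130,
                                      stages = flower_stages(),
                                      n_replicates = 3,
                                      archetype_probs = c(up = 0.3, down = 0.3,
                                                          peak_at_anthesis = 0.2,
                                                          flat = 0.2),
                                      log2_range = 2,
                                      noise_cv = 0.2,
                                      fw_mean = 30, fw_cv = 0.1, istd_cv = 0.1,
                                      seed = 1L) {
  if (n_compounds < 2) abort("`n_compounds` must be at least 2.")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  set.seed(seed)
  archetypes <- names(archetype_probs)
  truth <- tibble::tibble(
    compound = sprintf("cmp%03d", seq_len(n_compounds)),
    class = sample(compound_classes(), n_compounds, replace = TRUE),
    archetype = sample(archetypes, n_compounds, replace = TRUE,
                       prob = archetype_probs),
    effect = runif(n_compounds, 0.5, 1) * log2_range,
    base_log2 = runif(n_compounds, 2, 10)
  )
  truth$effect[truth$archetype == "flat"] <- 0
  ages <- stages$age_days
  u <- (ages - min(ages)) / diff(range(ages))
  anth_age <- stages$age_days[stages$phase == "anthesis"]
  trend_log2 <- function(archetype, effect) {
    switch(archetype,
      up = effect * u,
      down = -effect * u,
      peak_at_anthesis = effect * exp(-((ages - anth_age) / 1.5)^2),
      flat = rep(0, length(ages))
    )
  }
  samples <- tidyr::expand_grid(
    stage = stages$stage, replicate = seq_len(n_replicates)
  ) |>
    dplyr::left_join(stages, by = "stage") |>
    dplyr::mutate(
      fw_mg = fw_mean * lnoise(dplyr::n(), fw_cv),
      istd = lnoise(dplyr::n(), istd_cv)
    )
  profiles <- tidyr::expand_grid(compound = truth$compound,
                                 sample_idx = seq_len(nrow(samples)))
  profiles <- dplyr::bind_cols(
    profiles["compound"],
    samples[profiles$sample_idx, ]
  )
  signal <- purrr::map(seq_len(n_compounds), function(i) {
    2^(truth$base_log2[i] +
         trend_log2(truth$archetype[i], truth$effect[i]))
  })
  stage_idx <- match(profiles$stage, stages$stage)
  sig_mat <- do.call(rbind, signal) # compounds x stages
  profiles$signal <- sig_mat[cbind(rep(seq_len(n_compounds), each = nrow(samples)),
                                   stage_idx)]
  profiles$value <- profiles$signal * lnoise(nrow(profiles), noise_cv) *
    profiles$fw_mg * profiles$istd
  profiles <- profiles |>
    dplyr::left_join(truth[, c("compound", "class")], by = "compound") |>
    dplyr::select("compound", "class", "stage", "age_days", "phase",
                  "replicate", "value", "fw_mg", "istd")
  list(profiles = validate_profile_table(profiles), truth = truth)
}

#' Simulate an RNA-seq count matrix with developmental trends
#'
#' Counts are negative-binomial with per-gene mean
#' `lib_size/1e6 * exp(b0 + b1 * z + b2 * z^2)`, where `z` is the
#' standardised floret age, so non-null genes follow quadratic developmental
#' trends on the log scale. A fraction of genes are null (flat means), and a
#' further fraction are expressed near zero so the low-count filter has
#' planted targets.
#'
#' @param n_genes Number of genes.
#' @param stages Stage metadata from [flower_stages()].
#' @param n_replicates Replicates per stage.
#' @param frac_null Fraction of genes with flat means.
#' @param frac_low Fraction of genes expressed near zero (mean 0.1/sample).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param lib_sizes Per-sample library sizes; default 1e6 with 10% CV.
#' @param effect_log2 Maximum |log2| swing of non-null quadratic trends.
#' @param seed Integer seed.
#' @return A list with `counts` (integer matrix, genes x samples),
#'   `samples` (tibble of stage, age, replicate per column), and `truth`
#'   (per-gene coefficients and null/low flags).
#' @export
simulate_count_matrix <- function(n_genes = 2000,
                                  stages = flower_stages(),
                                  n_replicates = 3,
                                  frac_null = 0.3,
                                  frac_low = 0.05,
                                  dispersion = 0.1,
                                  lib_sizes = NULL,
                                  effect_log2 = 2,
                                  seed = 1L) {
  if (frac_null < 0 || frac_null > 1) abort("`frac_null` must be in [0, 1].")
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  set.seed(seed)
  samples <- tidyr::expand_grid(stage = stages$stage,
                                replicate = seq_len(n_replicates)) |>
    dplyr::left_join(stages, by = "stage")
  n_samples <- nrow(samples)
  lib <- lib_sizes %||% (1e6 * lnoise(n_samples, 0.1))
  z <- as.numeric(scale(samples$age_days))
  is_null <- runif(n_genes) < frac_null
  is_low <- !is_null & runif(n_genes) < frac_low / max(1 - frac_null, 1e-9)
  b0 <- log(2^runif(n_genes, 3, 9)) # baseline counts at lib 1e6
  b0[is_low] <- log(0.1) # ~0.1 counts per sample
  b1 <- ifelse(is_null, 0, runif(n_genes, -1, 1))
  b2 <- ifelse(is_null, 0, runif(n_genes, -1, 1))
  # rescale so the log2 swing over observed z is effect_log2 at most
  swing <- vapply(seq_len(n_genes), function(g) {
    eta <- b1[g] * z + b2[g] * z^2
    diff(range(eta))
  }, numeric(1))
  scale_f <- ifelse(swing > 0, (effect_log2 * log(2)) / swing, 1) *
    runif(n_genes, 0.5, 1)
  b1 <- b1 * scale_f
  b2 <- b2 * scale_f
  b1[is_low] <- 0; b2[is_low] <- 0
  mu <- exp(outer(b1, z) + outer(b2, z^2) + b0) # genes x samples, per-1e6 scale
  mu <- sweep(mu, 2, lib / 1e6, `*`)
  counts <- matrix(
    rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
    nrow = n_genes
  )
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(counts) <- paste(samples$stage, samples$replicate, sep = "_")
  truth <- tibble::tibble(
    gene = rownames(counts),
    b0 = b0, b1 = b1, b2 = b2,
    null = is_null, low = is_low
  )
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate measured mass-isotopologue distributions
#'
#' For each metabolite, draws the labelling pattern as i.i.d. binomial
#' labelling of the tracer carbons at the true enrichment, convolves it with
#' the natural-abundance pattern of the full elemental formula (the same
#' forward model the correction inverts), adds truncated-normal measurement
#' noise, and renormalises to sum 1.
#'
#' @param formulas Tibble with columns `metabolite`, `formula` (Hill
#'   notation), optionally `n_tracer` (default: all carbons).
#' @param enrichment True fractional enrichments, recycled across rows.
#' @param noise_sd Additive noise sd on each measured fraction.
#' @param abundances Natural isotope abundances.
#' @param seed Integer seed.
#' @return A list with `mids` (tibble with m0...mk columns, ready for
#'   [correct_mids()]) and `truth` (metabolite, enrichment).
#' @export
simulate_mid_data <- function(formulas, enrichment, noise_sd = 0,
                              abundances = natural_abundances(), seed = 1L) {
  set.seed(seed)
  if (!all(c("metabolite", "formula") %in% names(formulas))) {
    abort("`formulas` needs columns `metabolite` and `formula`.")
  }
  n <- nrow(formulas)
  enrichment <- rep_len(enrichment, n)
  if (any(enrichment < 0 | enrichment > 1)) {
    abort("Enrichments must be in [0, 1].")
  }
  rows <- purrr::map(seq_len(n), function(i) {
    counts <- parse_formula(formulas$formula[i])
    n_c <- if ("C" %in% names(counts)) counts[["C"]] else 0L
    if (is.na(n_c) || n_c < 1) {
      abort(sprintf("Formula '%s' has no carbon.", formulas$formula[i]))
    }
    n_tracer <- if ("n_tracer" %in% names(formulas)) formulas$n_tracer[i] else n_c
    cm <- correction_matrix(formulas$formula[i], n_tracer, abundances)
    lab <- dbinom(0:n_tracer, n_tracer, enrichment[i])
    measured <- as.numeric(cm %*% lab)
    if (noise_sd > 0) {
      measured <- pmax(measured + rnorm(length(measured), 0, noise_sd), 0)
    }
    measured <- measured / sum(measured)
    c(list(metabolite = formulas$metabolite[i],
           formula = formulas$formula[i],
           n_tracer = n_tracer),
      setNames(as.list(measured), paste0("m", 0:n_tracer)))
  })
  mids <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  list(
    mids = mids,
    truth = tibble::tibble(metabolite = formulas$metabolite,
                           enrichment = enrichment)
  )
}

#' Simulate a radiolabel partitioning experiment
#'
#' Inverse of the flux estimation: given true per-class synthesis fluxes,
#' each replicate's class radioactivity is
#' `flux * specific_activity * duration_h` times multiplicative lognormal
#' noise; the metabolised total is the class sum, uptake is the metabolised
#' total divided by the metabolised fraction, and recovery is an independent
#' measured pass-through.
#'
#' @param true_fluxes Named vector of true fluxes (nmol hexose eq / gFW / h)
#'   per compound class; defaults to fluxes consistent with the reference
#'   partitioning percentages of [reference_inflorescence_14c()].
#' @param specific_activity Specific activity (Bq/nmol) of the tracer pool.
#' @param duration_h Labelling duration (hours).
#' @param n_replicates Number of replicates (default 5).
#' @param noise_cv CV of the multiplicative noise on class radioactivities.
#' @param metabolized_fraction Fraction of taken-up label that is metabolised.
#' @param recovery_mean,recovery_sd Distribution of the measured recovery.
#' @param seed Integer seed.
#' @return A list with `partitions` (replicate, class, bq), `totals`
#'   (replicate, uptake, metabolized, recovery) and `truth` (class, flux).
#' @export
simulate_14c_experiment <- function(true_fluxes = NULL,
                                    specific_activity = 7,
                                    duration_h = 5,
                                    n_replicates = 5,
                                    noise_cv = 0.3,
                                    metabolized_fraction = 0.95,
                                    recovery_mean = 0.58, recovery_sd = 0.04,
                                    seed = 1L) {
  if (specific_activity <= 0) abort("`specific_activity` must be positive.")
  if (duration_h <= 0) abort("`duration_h` must be positive.")
  set.seed(seed)
  if (is.null(true_fluxes)) {
    ref <- reference_inflorescence_14c()
    metab <- ref$totals$mean[ref$totals$quantity == "metabolized"]
    true_fluxes <- setNames(
      absolute_flux(ref$redistribution$mean_pct, metab,
                    specific_activity, duration_h),
      ref$redistribution$class
    )
  }
  if (any(true_fluxes < 0)) abort("True fluxes must be non-negative.")
  classes <- names(true_fluxes)
  partitions <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                                   class = classes)
  base_bq <- true_fluxes[partitions$class] * specific_activity * duration_h
  partitions$bq <- as.numeric(base_bq * lnoise(nrow(partitions), noise_cv))
  totals <- partitions |>
    dplyr::summarise(metabolized = sum(.data$bq), .by = "replicate")
  totals$uptake <- totals$metabolized / metabolized_fraction
  totals$recovery <- pmin(pmax(rnorm(n_replicates, recovery_mean, recovery_sd),
                               0), 1)
  list(
    partitions = partitions,
    totals = totals[, c("replicate", "uptake", "metabolized", "recovery")],
    truth = tibble::tibble(class = classes,
                           flux = as.numeric(true_fluxes))
  )
}
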