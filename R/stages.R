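#' Canonical developmental stages of Arabidopsis florets across anthesis
#'
#' The sampling design covers eight consecutive floret stages spanning the
#' transition from closed buds to senescing open flowers, with anthesis (the
#' moment the flower opens) at 11.50 days. Phases are derived from floret age:
#' stages younger than the anthesis age are `preanthesis`, the single stage at
#' the anthesis age is `anthesis`, and older stages are `postanthesis`.
#'
#' Stage labels follow the standard floral-stage nomenclature (S9 onward) but
#' are carried as metadata only: all computations in the package key on
#' `age_days` and `phase`, never on the label string. The age of the youngest
#' stage is reported ambiguously in the field (7.25 vs 7.29 days); it is
#' exposed here as data, defaulting to 7.25, rather than hard-coded elsewhere.
#'
#' @param ages Numeric vector of floret ages in days, strictly increasing.
#' @param anthesis_age Age (days) of the single stage at anthesis.
#' @param labels Character stage labels, same length as `ages`.
#'
#' @return A tibble with columns `stage` (factor, ordered as given),
#'   `age_days`, and `phase` (factor: preanthesis, anthesis, postanthesis).
#' @export
#' @examples
#' flower_stages()
flower_stages <- function(ages = c(7.25, 9.25, 10.25, 11.50, 13.25, 13.50, 14.25, 15.25),
                          anthesis_age = 11.50,
                          labels = paste0("S", seq(9, length.out = length(ages)))) {
  if (length(ages) != length(labels)) {
    abort("`ages` and `labels` must have the same length.")
  }
  if (is.unsorted(ages, strictly = TRUE)) {
    abort("Stage ages must be strictly increasing.")
  }
  if (sum(ages == anthesis_age) != 1L) {
    abort("Exactly one stage must sit at `anthesis_age`.")
  }
  phase <- dplyr::case_when(
    ages < anthesis_age ~ "preanthesis",
    ages == anthesis_age ~ "anthesis",
    TRUE ~ "postanthesis"
  )
  tibble::tibble(
    stage = factor(labels, levels = labels),
    age_days = ages,
    phase = factor(phase, levels = c("preanthesis", "anthesis", "postanthesis"))
  )
}

#' Pipeline configuration
#'
#' Bundles the thresholds and physical parameters used across the pipeline:
#' correlation thresholds for the metabolite (0.65), transcript (0.82), and
#' transcript-metabolite (0.80) networks, the significance level for
#' correlations, the FDR level of the developmental trend filter, the minimum
#' total count for transcript retention, natural 13C abundance and tracer
#' purity for isotopologue correction, and the feeding-solution specific
#' activity and incubation time for radiolabel flux estimation.
#'
#' @param r_metabolite Pearson threshold for metabolite-metabolite edges.
#' @param r_transcript_metabolite Pearson threshold for gene-metabolite edges.
#' @param r_transcript Pearson threshold for gene-gene edges.
#' @param p_correlation Two-sided significance level for correlations.
#' @param fdr_trend BH false-discovery level of the trend filter.
#' @param min_counts Minimum total read count for a gene to be retained.
#' @param c13_natural Natural abundance of 13C.
#' @param tracer_purity Isotopic purity of the fed tracer (fraction).
#' @param specific_activity Specific activity of the feeding solution,
#'   Bq per nmol hexose.
#' @param duration_h Labelling duration in hours.
#' @param seed Integer seed controlling every stochastic step.
#'
#' @return A list of class `flower_config`.
#' @export
flower_config <- function(r_metabolite = 0.65,
                          r_transcript_metabolite = 0.80,
                          r_transcript = 0.82,
                          p_correlation = 0.05,
                          fdr_trend = 0.05,
                          min_counts = 10,
                          c13_natural = 0.0107,
                          tracer_purity = 1,
                          specific_activity = 7,
                          duration_h = 5,
                          seed = 1L) {
  chk_fraction <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a single value in [0, 1].", nm))
    }
  }
  for (nm in c("p_correlation", "fdr_trend", "c13_natural", "tracer_purity")) {
    chk_fraction(get(nm), nm)
  }
  for (nm in c("r_metabolite", "r_transcript_metabolite", "r_transcript")) {
    x <- get(nm)
    if (!is.numeric(x) || x < 0 || x > 1) abort(sprintf("`%s` must be in [0, 1].", nm))
  }
  if (min_counts < 0) abort("`min_counts` must be non-negative.")
  if (specific_activity <= 0) abort("`specific_activity` must be positive.")
  if (duration_h <= 0) abort("`duration_h` must be positive.")
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")
  structure(
    list(
      r_metabolite = r_metabolite,
      r_transcript_metabolite = r_transcript_metabolite,
      r_transcript = r_transcript,
      p_correlation = p_correlation,
      fdr_trend = fdr_trend,
      min_counts = min_counts,
      c13_natural = c13_natural,
      tracer_purity = tracer_purity,
      specific_activity = specific_activity,
      duration_h = duration_h,
      seed = seed
    ),
    class = "flower_config"
  )
}

#' @export
print.flower_config <- function(x, ...) {
  cat("<flower_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# compound-class vocabulary shared by generators and readers
compound_classes <- function() {
  c("amino acid", "organic acid", "carbohydrate", "shikimate", "flavonoid",
    "glucosinolate", "polyamine", "hydroxycinnamate", "apocarotenoid",
    "hormone", "other")
}
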