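#' Normalise abundances by fresh weight and internal standard
#'
#' Divides every raw abundance by its sample's fresh weight and internal
#' standard response (`value / (fw_mg * istd)`), the standard correction for
#' tissue amount and instrument response drift.
#'
#' @param data Long profile table with `fw_mg` and `istd` columns.
#' @return The table with `value` replaced by the normalised value and an
#'   attribute `normalized = TRUE`.
#' @export
normalize_profiles <- function(data) {
  data <- validate_profile_table(data)
  for (col in c("fw_mg", "istd")) {
    if (!col %in% names(data)) {
      abort(sprintf("Normalisation needs column `%s`.", col))
    }
  }
  bad <- is.na(data$fw_mg) | is.na(data$istd)
  if (any(bad)) {
    samples <- unique(paste(data$stage[bad], data$replicate[bad], sep = "_"))
    abort(sprintf("Missing fw/istd for sample(s): %s.",
                  paste(samples, collapse = ", ")))
  }
  data$value <- data$value / (data$fw_mg * data$istd)
  attr(data, "normalized") <- TRUE
  data
}

#' Log2 stage means (heatmap matrix)
#'
#' Averages replicates within each compound-stage cell and takes log2 of the
#' mean (not the mean of logs, matching how stage averages are conventionally
#' displayed on heatmaps). With `scale_rows = TRUE` each compound row is
#' centred and scaled to unit variance, the usual heatmap convention;
#' constant rows cannot be scaled and become `NA` with a warning, as do
#' cells with non-positive means.
#'
#' @param data Long (normalised) profile table.
#' @param scale_rows Centre and unit-scale each compound row.
#' @return A wide tibble: `compound` plus one column per stage.
#' @export
log2_stage_means <- function(data, scale_rows = FALSE) {
  data <- validate_profile_table(data)
  means <- data |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     .by = c("compound", "stage"))
  nonpos <- !is.na(means$mean) & means$mean <= 0
  if (any(nonpos)) {
    warn(sprintf("%d compound-stage cell(s) with non-positive mean set to NA.",
                 sum(nonpos)))
    means$mean[nonpos] <- NA
  }
  means$mean[is.nan(means$mean)] <- NA
  means$log2_mean <- log2(means$mean)
  wide <- tidyr::pivot_wider(means[, c("compound", "stage", "log2_mean")],
                             names_from = "stage", values_from = "log2_mean")
  if (scale_rows) {
    m <- as.matrix(wide[, -1])
    rs <- apply(m, 1, sd, na.rm = TRUE)
    const <- is.na(rs) | rs == 0
    if (any(const)) {
      warn(sprintf("%d constant compound row(s) cannot be scaled; set to NA.",
                   sum(const)))
    }
    m <- t(scale(t(m)))
    m[const, ] <- NA
    wide[, -1] <- m
  }
  wide
}

#' Abundances relative to a reference stage
#'
#' Divides every replicate value by the mean abundance of that compound at
#' the reference stage (by default the youngest stage present), the transform
#' behind "fold change relative to young buds" boxplots. Compounds whose
#' reference mean is zero or missing are dropped with a warning.
#'
#' @param data Long profile table.
#' @param reference_stage Stage label to normalise against; default the first
#'   stage level (youngest).
#' @return The table with `value` replaced by the ratio.
#' @export
relative_to_reference <- function(data, reference_stage = NULL) {
  data <- validate_profile_table(data)
  stages <- if (is.factor(data$stage)) levels(data$stage) else sort(unique(data$stage))
  reference_stage <- reference_stage %||% stages[1]
  if (!reference_stage %in% data$stage) {
    abort(sprintf("Reference stage '%s' not present.", reference_stage))
  }
  ref <- data |>
    dplyr::filter(.data$stage == reference_stage) |>
    dplyr::summarise(ref_mean = mean(.data$value, na.rm = TRUE),
                     .by = "compound")
  bad <- ref$compound[is.na(ref$ref_mean) | ref$ref_mean == 0]
  if (length(bad)) {
    warn(sprintf("Dropping compound(s) with zero/missing reference mean: %s.",
                 paste(bad, collapse = ", ")))
  }
  out <- data |>
    dplyr::inner_join(ref[!ref$compound %in% bad, ], by = "compound") |>
    dplyr::mutate(value = .data$value / .data$ref_mean) |>
    dplyr::select(-"ref_mean")
  out
}

#' Two-sample t-test from summary statistics
#'
#' Compares two group means given only their summary statistics. The printed
#' dispersion can enter either as a per-replicate standard deviation
#' (`spread = "sd"`, the default) or directly as the standard error of the
#' mean (`spread = "se"`). With `var_equal = TRUE` (default) a pooled
#' two-sample Student t is used (`df = n1 + n2 - 2`); otherwise Welch's t
#' with Welch-Satterthwaite degrees of freedom. The pooled/sd default is the
#' configuration that reproduces published compact-letter patterns computed
#' from summary tables of this design (see the methods vignette).
#'
#' @param m1,m2 Group means.
#' @param s1,s2 Group dispersions (sd or se, per `spread`).
#' @param n1,n2 Group sizes (>= 2).
#' @param spread How `s1`, `s2` are interpreted: `"sd"` or `"se"`.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' ttest_from_summary(437.16, 103.16, 3, 2378.80, 25.09, 3)
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2,
                               spread = c("sd", "se"), var_equal = TRUE) {
  spread <- match.arg(spread)
  if (any(c(s1, s2) < 0)) abort("Dispersions must be non-negative.")
  if (any(c(n1, n2) < 2)) abort("Group sizes must be at least 2.")
  # per-group variance of the mean
  v1 <- if (spread == "sd") s1^2 / n1 else s1^2
  v2 <- if (spread == "sd") s2^2 / n2 else s2^2
  if (v1 + v2 == 0) {
    if (m1 == m2) {
      return(tibble::tibble(t = 0, df = n1 + n2 - 2, p = 1))
    }
    warn("Zero dispersion with unequal means: p = 0.")
    return(tibble::tibble(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (var_equal) {
    # pooled variance from the per-group sds
    sd1 <- sqrt(v1 * n1); sd2 <- sqrt(v2 * n2)
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Compact letter display for pairwise group comparisons
#'
#' Assigns letters to groups so that any two groups sharing no letter differ
#' significantly and any two groups that are not significantly different
#' share at least one letter, using the insert-and-absorb algorithm. Letters
#' are consecutive starting at "a", ordered by first group membership.
#'
#' @param means,spreads,n Vectors of group means, dispersions and sizes.
#' @param alpha Significance level for "different".
#' @inheritParams ttest_from_summary
#' @return Character vector of letter strings, one per group.
#' @export
#' @examples
#' compact_letters(c(137.83, 431.74, 155.27), c(14.18, 27.73, 6.66), c(3, 3, 3))
compact_letters <- function(means, spreads, n, alpha = 0.05,
                            spread = c("sd", "se"), var_equal = TRUE) {
  spread <- match.arg(spread)
  k <- length(means)
  if (k < 2) abort("At least two groups are required.")
  if (length(spreads) != k || length(n) != k) {
    abort("`means`, `spreads` and `n` must have the same length.")
  }
  different <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- ttest_from_summary(means[i], spreads[i], n[i],
                              means[j], spreads[j], n[j],
                              spread = spread, var_equal = var_equal)$p
      different[i, j] <- different[j, i] <- !is.na(p) && p < alpha
    }
  }
  letters_from_difference(different)
}

# insert-and-absorb on a symmetric logical "significantly different" matrix
letters_from_difference <- function(different) {
  k <- nrow(different)
  cols <- list(rep(TRUE, k)) # membership columns
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!different[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1]] <- b
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(cols[[ci]] <= cols[[cj]]) && any(cols[[ci]] < cols[[cj]])) {
            keep[ci] <- FALSE
          }
        }
      }
      cols <- cols[keep]
      cols <- unique(cols)
    }
  }
  # order columns by first member, assign letters
  first <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first)]
  lab <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) col[g], logical(1)))],
          collapse = "")
  }, character(1))
  lab
}

#' Pairwise group t-tests with compact letters per compound
#'
#' For each compound, groups the replicate-level values by stage or phase,
#' computes group means, standard errors and sizes, runs every pairwise
#' two-sample t-test on the replicate data, and assigns compact letters at
#' `alpha` plus a bold flag marking compounds where any pair is significant
#' at the stricter `alpha_strict`. Compounds with any group of fewer than
#' two replicates are skipped with a warning.
#'
#' @param data Long profile table; needs a `phase` column when
#'   `grouping = "phase"`.
#' @param grouping Group by `"phase"` (default; preanthesis / anthesis /
#'   postanthesis) or `"stage"`.
#' @param alpha Letter significance level.
#' @param alpha_strict Bold-flag significance level.
#' @param var_equal Pooled (Student, default) or Welch pairwise tests.
#' @return A tibble with one row per compound and group: `mean`, `se`, `n`,
#'   `letter`, `bold`.
#' @export
pairwise_stage_ttests <- function(data, grouping = c("phase", "stage"),
                                  alpha = 0.05, alpha_strict = 0.01,
                                  var_equal = TRUE) {
  grouping <- match.arg(grouping)
  data <- validate_profile_table(data)
  if (!grouping %in% names(data)) {
    abort(sprintf("Grouping column `%s` not present.", grouping))
  }
  data$group <- data[[grouping]]
  groups <- if (is.factor(data$group)) {
    intersect(levels(data$group), unique(as.character(data$group)))
  } else {
    unique(as.character(data$group))
  }
  skipped <- character()
  out <- data |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$compound) |>
    dplyr::group_map(function(d, key) {
      stats_tbl <- d |>
        dplyr::summarise(
          mean = mean(.data$value),
          sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
          n = dplyr::n(),
          .by = "group"
        )
      stats_tbl <- stats_tbl[match(intersect(groups, as.character(stats_tbl$group)),
                                   as.character(stats_tbl$group)), ]
      if (nrow(stats_tbl) < 2 || any(stats_tbl$n < 2)) {
        skipped <<- c(skipped, as.character(key$compound))
        return(NULL)
      }
      lett <- compact_letters(stats_tbl$mean, stats_tbl$sd, stats_tbl$n,
                              alpha = alpha, spread = "sd",
                              var_equal = var_equal)
      kk <- nrow(stats_tbl)
      pmin_all <- 1
      for (i in seq_len(kk - 1)) {
        for (j in (i + 1):kk) {
          p <- ttest_from_summary(stats_tbl$mean[i], stats_tbl$sd[i], stats_tbl$n[i],
                                  stats_tbl$mean[j], stats_tbl$sd[j], stats_tbl$n[j],
                                  spread = "sd", var_equal = var_equal)$p
          pmin_all <- min(pmin_all, p)
        }
      }
      tibble::tibble(
        compound = key$compound,
        group = as.character(stats_tbl$group),
        mean = stats_tbl$mean,
        se = stats_tbl$sd / sqrt(stats_tbl$n),
        n = stats_tbl$n,
        letter = lett,
        bold = pmin_all < alpha_strict
      )
    }) |>
    dplyr::bind_rows()
  if (length(skipped)) {
    warn(sprintf("Skipped compound(s) with a group of < 2 replicates: %s.",
                 paste(skipped, collapse = ", ")))
  }
  out
}
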