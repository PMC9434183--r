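as_gene_matrix <- function(x, nonnegative = FALSE) {
  if (is.data.frame(x)) {
    gene_col <- intersect(c("gene", "gene_id"), names(x))[1]
    if (!is.na(gene_col)) {
      genes <- x[[gene_col]]
      x <- as.matrix(x[, setdiff(names(x), gene_col)])
      rownames(x) <- genes
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.numeric(x)) abort("Values must be numeric.")
  if (nonnegative && any(x < 0, na.rm = TRUE)) abort("Counts must be non-negative.")
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  x
}

as_count_matrix <- function(counts) as_gene_matrix(counts, nonnegative = TRUE)

#' Remove genes with too few reads
#'
#' Drops genes whose total read count across all samples falls below
#' `min_total` (strictly: a gene with exactly `min_total` reads is kept).
#' A per-sample mode is available in which every sample must individually
#' reach the threshold.
#'
#' @param counts Genes-by-samples count matrix, or a data frame with a
#'   `gene` column followed by sample columns.
#' @param min_total Minimum total count for retention.
#' @param per_sample If `TRUE`, require `min_total` in every sample instead
#'   of in the total.
#' @return The filtered count matrix, with attribute `removed` holding the
#'   dropped gene ids.
#' @export
filter_low_counts <- function(counts, min_total = 10, per_sample = FALSE) {
  m <- as_count_matrix(counts)
  if (min_total < 0) abort("`min_total` must be non-negative.")
  keep <- if (per_sample) {
    apply(m, 1, function(x) all(x >= min_total))
  } else {
    rowSums(m) >= min_total
  }
  removed <- rownames(m)[!keep]
  inform(sprintf("Removed %d / %d gene(s) below %d counts.",
                 length(removed), nrow(m), min_total))
  out <- m[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Log2 counts-per-million normalisation
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)`, the standard
#' moderated log-CPM transform. Library sizes default to column sums.
#'
#' @inheritParams filter_low_counts
#' @param prior Pseudo-count stabilising the log at zero counts.
#' @param lib_sizes Optional per-sample library sizes.
#' @return A genes-by-samples numeric matrix of log2-CPM values.
#' @export
normalize_logcpm <- function(counts, prior = 0.5, lib_sizes = NULL) {
  m <- as_count_matrix(counts)
  lib <- lib_sizes %||% colSums(m)
  if (any(lib <= 0)) abort("Library sizes must be positive.")
  t(log2(t(m + prior) / (lib + 2 * prior) * 1e6))
}

#' Developmental-trend filter
#'
#' Fits each gene's log-CPM profile to a smooth polynomial basis of floret
#' age (3 df by default) by least squares and tests it against the
#' intercept-only model with an F-test, under the assumption that real
#' developmental changes are smooth and gradual while noise is not.
#' P-values are BH-adjusted across genes; genes with `q <= fdr` are kept.
#'
#' @param logcpm Genes-by-samples matrix of log2-CPM values.
#' @param ages Per-sample floret age in days.
#' @param df Degrees of freedom of the polynomial basis.
#' @param fdr BH false-discovery threshold for the keep flag.
#' @return An object of class `trend_fit`: a tibble with one row per gene
#'   (`F`, `p`, `q`, `keep`) carrying the fitted coefficients as an
#'   attribute. [tidy()] returns the tibble, [glance()] the funnel counts.
#' @export
trend_filter <- function(logcpm, ages, df = 3, fdr = 0.05) {
  m <- as.matrix(logcpm)
  if (ncol(m) != length(ages)) abort("`ages` must match the sample columns.")
  if (length(unique(ages)) < df + 2) {
    abort(sprintf("Need at least %d distinct ages for a %d-df basis.", df + 2, df))
  }
  X <- cbind(1, stats::poly(ages, df))
  qr_x <- qr(X)
  n <- ncol(m)
  fitted <- t(qr.fitted(qr_x, t(m)))
  coefs <- t(qr.coef(qr_x, t(m)))
  rss1 <- rowSums((m - fitted)^2)
  rss0 <- rowSums((m - rowMeans(m))^2)
  df2 <- n - df - 1
  fstat <- ((rss0 - rss1) / df) / (rss1 / df2)
  p <- pf(fstat, df, df2, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- tibble::tibble(
    gene = rownames(m),
    F = fstat,
    p = p,
    q = q,
    keep = q <= fdr
  )
  attr(out, "coefficients") <- coefs
  attr(out, "df") <- c(df1 = df, df2 = df2)
  class(out) <- c("trend_fit", class(out))
  out
}

#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trend_fit")
  attr(out, "coefficients") <- NULL
  attr(out, "df") <- NULL
  out
}

#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_kept = sum(x$keep),
    df1 = attr(x, "df")[["df1"]],
    df2 = attr(x, "df")[["df2"]]
  )
}

#' Differential expression between developmental stages
#'
#' For each requested pair of stages, tests every gene with a two-sample
#' Welch t-test on log-CPM values and adjusts p-values by BH within the
#' contrast. Moderated-variance machinery is deliberately not used: the
#' funnel's structure (which genes survive which comparison), not a specific
#' shrinkage estimator, is what this stage provides.
#'
#' @param logcpm Genes-by-samples matrix of log2-CPM values.
#' @param stages Per-sample stage labels (character or factor).
#' @param contrasts List of length-2 character vectors of stage labels;
#'   defaults to all consecutive stage pairs in factor order.
#' @param fdr BH threshold for the `significant` flag.
#' @return A tibble: `gene`, `contrast`, `estimate` (mean difference,
#'   second minus first), `t`, `df`, `p`, `q`, `significant`.
#' @export
stage_contrasts <- function(logcpm, stages, contrasts = NULL, fdr = 0.05) {
  m <- as.matrix(logcpm)
  if (ncol(m) != length(stages)) abort("`stages` must match sample columns.")
  lev <- if (is.factor(stages)) levels(stages) else unique(as.character(stages))
  stages <- as.character(stages)
  if (is.null(contrasts)) {
    lev <- lev[lev %in% stages]
    contrasts <- purrr::map(seq_len(length(lev) - 1), ~ c(lev[.x], lev[.x + 1]))
  }
  purrr::map_dfr(contrasts, function(ctr) {
    if (!all(ctr %in% stages)) {
      abort(sprintf("Stage(s) missing from data: %s.",
                    paste(setdiff(ctr, stages), collapse = ", ")))
    }
    a <- m[, stages == ctr[1], drop = FALSE]
    b <- m[, stages == ctr[2], drop = FALSE]
    if (ncol(a) < 2 || ncol(b) < 2) {
      abort("Each side of a contrast needs at least 2 replicates.")
    }
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var) / ncol(a)
    vb <- apply(b, 1, stats::var) / ncol(b)
    t <- (mb - ma) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ncol(a) - 1) + vb^2 / (ncol(b) - 1))
    p <- 2 * pt(-abs(t), df)
    q <- p.adjust(p, method = "BH")
    tibble::tibble(
      gene = rownames(m),
      contrast = paste(ctr[1], ctr[2], sep = " vs "),
      estimate = mb - ma,
      t = t, df = df, p = p, q = q,
      significant = q <= fdr
    )
  })
}

#' K-means clustering of standardised stage profiles
#'
#' Z-scores each gene's stage-mean profile and clusters the profiles with
#' k-means (multiple restarts, seeded). For each cluster, the change of the
#' centroid across the onset of anthesis (last preanthesis stage to the
#' anthesis stage) is reported, so clusters with sudden and opposite
#' behaviour at flower opening can be read off directly.
#'
#' @param stage_means Genes-by-stages matrix (or data frame with a `gene`
#'   column) of per-stage mean expression.
#' @param k Number of clusters.
#' @param stages Stage metadata as from [flower_stages()], used to locate
#'   the anthesis boundary; columns must match its `stage` labels where
#'   present.
#' @param seed Integer seed for the restarts.
#' @param nstart Number of random restarts.
#' @return A list of class `profile_clusters`: `assignment` tibble
#'   (gene, cluster), `centroids` tibble (cluster by stage), and
#'   `anthesis_step` tibble (cluster, step, direction).
#' @export
kmeans_profiles <- function(stage_means, k = 6, stages = flower_stages(),
                            seed = 1L, nstart = 25) {
  m <- as_gene_matrix(stage_means)
  if (k < 1) abort("`k` must be at least 1.")
  if (k > nrow(m)) abort("`k` exceeds the number of genes.")
  rs <- apply(m, 1, sd)
  const <- is.na(rs) | rs == 0
  if (any(const)) {
    warn(sprintf("Dropping %d constant profile(s) before clustering.", sum(const)))
    m <- m[!const, , drop = FALSE]
  }
  z <- t(scale(t(m)))
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = nstart)
  centroids <- tibble::as_tibble(km$centers, .name_repair = "minimal")
  centroids <- dplyr::bind_cols(tibble::tibble(cluster = seq_len(k)), centroids)
  # anthesis step: last preanthesis column -> anthesis column
  anth <- as.character(stages$stage[stages$phase == "anthesis"])
  pre_last <- as.character(utils::tail(stages$stage[stages$phase == "preanthesis"], 1))
  step <- if (all(c(anth, pre_last) %in% colnames(km$centers))) {
    km$centers[, anth] - km$centers[, pre_last]
  } else {
    rep(NA_real_, k)
  }
  structure(
    list(
      assignment = tibble::tibble(gene = rownames(z),
                                  cluster = as.integer(km$cluster)),
      centroids = centroids,
      anthesis_step = tibble::tibble(
        cluster = seq_len(k),
        step = as.numeric(step),
        direction = dplyr::case_when(
          is.na(step) ~ NA_character_,
          step > 0 ~ "up",
          step < 0 ~ "down",
          TRUE ~ "flat"
        )
      ),
      tot_withinss = km$tot.withinss
    ),
    class = "profile_clusters"
  )
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("<profile_clusters> %d genes in %d clusters\n",
              nrow(x$assignment), nrow(x$centroids)))
  invisible(x)
}

#' @method tidy profile_clusters
#' @export
tidy.profile_clusters <- function(x, ...) x$assignment

#' @method glance profile_clusters
#' @export
glance.profile_clusters <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$centroids),
    n_genes = nrow(x$assignment),
    tot_withinss = x$tot_withinss
  )
}
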