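#' Default natural isotope abundances
#'
#' Isotope mass-shift distributions for the elements that occur in derivatised
#' metabolite fragments measured by GC-MS. Each element maps to a numeric
#' vector of fractional abundances indexed by mass shift (+0, +1, +2, ...).
#' Values are the standard terrestrial abundances; the 13C abundance is
#' configurable because it is the one the correction is most sensitive to.
#'
#' @param c13 Natural abundance of 13C.
#' @return Named list of mass-shift probability vectors.
#' @export
natural_abundances <- function(c13 = 0.0107) {
  if (c13 < 0 || c13 >= 0.5) abort("`c13` must be in [0, 0.5).")
  list(
    C  = c(1 - c13, c13),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    Si = c(1 - 0.04685 - 0.03092, 0.04685, 0.03092),
    S  = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425),
    P  = 1
  )
}

#' Parse an elemental formula in Hill notation
#'
#' @param formula A string such as `"C6H12O6"` or `"C19H37NO4Si2"`.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  if (length(formula) != 1 || !is.character(formula) || is.na(formula)) {
    abort("`formula` must be a single string.")
  }
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(formula) || paste(parts, collapse = "") != formula) {
    abort(sprintf("Cannot parse formula '%s'.", formula))
  }
  elements <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(counts, elements, sum)
  storage.mode(out) <- "integer"
  setNames(as.integer(out), names(out))
}

# n-fold self-convolution of a short probability vector
conv_pow <- function(d, n) {
  out <- 1
  for (i in seq_len(n)) out <- conv_vec(out, d)
  out
}

conv_vec <- function(a, b) {
  if (length(a) == 1) return(a * b)
  if (length(b) == 1) return(b * a)
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(b)) {
    idx <- seq_along(a) + i - 1L
    out[idx] <- out[idx] + a * b[i]
  }
  out
}

element_count <- function(counts, element) {
  if (element %in% names(counts)) counts[[element]] else 0L
}

as_element_counts <- function(formula) {
  if (is.character(formula)) parse_formula(formula) else {
    counts <- formula
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      abort("Element counts must be a named vector.")
    }
    counts
  }
}

#' Natural-abundance mass-shift distribution of a molecule
#'
#' Computes the mass-isotopologue distribution an unlabeled molecule exhibits
#' purely from natural heavy-isotope abundance: the convolution of every
#' atom's isotope-shift distribution.
#'
#' @param formula Hill-notation string or named element-count vector.
#' @param abundances Named list of per-element mass-shift distributions, as
#'   returned by [natural_abundances()].
#' @param max_shift Optional truncation length; if supplied the returned
#'   vector has `max_shift + 1` entries (which may then sum to less than 1).
#' @return Numeric vector of fractions starting at shift 0.
#' @export
#' @examples
#' natural_mid("C1") # c(0.9893, 0.0107)
natural_mid <- function(formula, abundances = natural_abundances(),
                        max_shift = NULL) {
  counts <- as_element_counts(formula)
  missing <- setdiff(names(counts)[counts > 0], names(abundances))
  if (length(missing)) {
    abort(sprintf("No isotope abundances for element(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- 1
  for (el in names(counts)) {
    if (counts[[el]] > 0) out <- conv_vec(out, conv_pow(abundances[[el]], counts[[el]]))
  }
  if (!is.null(max_shift)) {
    out <- out[seq_len(max_shift + 1)]
    out[is.na(out)] <- 0
  }
  out
}

#' Natural-abundance correction matrix
#'
#' Column `j + 1` holds the mass-shift distribution of the molecular species
#' carrying `j` tracer carbons: `j` carbons fixed as 13C (at the stated tracer
#' purity), the remaining carbons and all heteroatoms at natural abundance.
#' Columns are truncated to the measured window of `n_tracer + 1` masses, so
#' each column sums to at most 1.
#'
#' @inheritParams natural_mid
#' @param n_tracer Number of carbon positions that can carry tracer label.
#' @param purity Isotopic purity of the tracer (probability that a labeled
#'   position actually carries 13C).
#' @param n_rows Number of measured mass channels (rows); defaults to
#'   `n_tracer + 1`, but more rows may be supplied when the measured MID
#'   extends beyond the tracer window.
#' @return A `n_rows x (n_tracer + 1)` matrix.
#' @export
correction_matrix <- function(formula, n_tracer = NULL,
                              abundances = natural_abundances(), purity = 1,
                              n_rows = NULL) {
  counts <- as_element_counts(formula)
  n_c <- element_count(counts, "C")
  if (is.na(n_c) || n_c < 1) abort("Formula must contain at least one carbon.")
  n_tracer <- n_tracer %||% n_c
  if (n_tracer < 1 || n_tracer > n_c) {
    abort("`n_tracer` must be between 1 and the carbon count.")
  }
  if (purity < 0 || purity > 1) abort("`purity` must be in [0, 1].")
  n_rows <- n_rows %||% (n_tracer + 1)
  if (n_rows < n_tracer + 1) abort("`n_rows` must be at least `n_tracer + 1`.")
  m <- matrix(0, n_rows, n_tracer + 1)
  for (j in 0:n_tracer) {
    resid <- counts
    resid[["C"]] <- n_c - j
    base <- natural_mid(resid, abundances)
    lab <- if (j == 0) 1 else conv_pow(c(1 - purity, purity), j)
    col <- conv_vec(lab, base)
    keep <- seq_len(min(length(col), n_rows))
    m[keep, j + 1] <- col[keep]
  }
  m
}

#' Correct a measured mass-isotopologue distribution
#'
#' Deconvolves natural heavy-isotope contributions from a measured MID by
#' non-negative least squares against the [correction_matrix()], then
#' renormalises. Non-negative least squares is used rather than a plain matrix
#' inverse followed by clipping because clipping breaks the sum-to-one
#' guarantee under measurement noise. The mean fractional enrichment is the
#' carbon-weighted average `E = sum(j * x_j) / n_tracer`.
#'
#' @param measured Numeric fraction vector of length `n_tracer + 1`
#'   (M+0 ... M+n), non-negative and summing to 1 (tolerance 1e-6).
#' @inheritParams correction_matrix
#' @return A list of class `mid_correction` with elements `corrected`
#'   (fractions summing to 1), `enrichment`, and `residual_norm`.
#' @export
#' @examples
#' correct_mid(c(0.9893, 0.0107), "C1")$enrichment # 0
correct_mid <- function(measured, formula, n_tracer = length(measured) - 1L,
                        abundances = natural_abundances(), purity = 1) {
  if (any(measured < 0) || any(is.na(measured))) {
    abort("Measured fractions must be non-negative and complete.")
  }
  if (abs(sum(measured) - 1) > 1e-6) {
    abort("Measured fractions must sum to 1 (tolerance 1e-6).")
  }
  if (length(measured) < n_tracer + 1) {
    abort("`measured` must cover at least `n_tracer + 1` mass channels.")
  }
  if (length(measured) > n_tracer + 1) {
    # channels beyond the tracer window carry no labelling information;
    # drop them so zero-padded inputs correct identically
    extra <- sum(measured[-seq_len(n_tracer + 1)])
    if (extra > 1e-6) {
      warn(sprintf("Dropping %.3g measured fraction beyond M+%d.", extra, n_tracer))
    }
    measured <- measured[seq_len(n_tracer + 1)]
    measured <- measured / sum(measured)
  }
  cm <- correction_matrix(formula, n_tracer, abundances, purity)
  fit <- pracma::lsqnonneg(cm, as.numeric(measured))
  x <- fit$x
  resid_norm <- sqrt(sum((cm %*% x - measured)^2))
  if (sum(x) <= 0) abort("Degenerate correction: all corrected fractions zero.")
  x <- x / sum(x)
  structure(
    list(
      corrected = x,
      enrichment = sum((seq_along(x) - 1L) * x) / n_tracer,
      residual_norm = resid_norm
    ),
    class = "mid_correction"
  )
}

#' @export
print.mid_correction <- function(x, ...) {
  cat("<mid_correction> E =", format(x$enrichment, digits = 6),
      " residual =", format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

#' Amount of tracer-derived carbon in a metabolite pool
#'
#' Converts a pool size and a mean fractional enrichment into the labeled
#' amount: `pool_amount * enrichment`, in the units of `pool_amount`
#' (typically ng per mg fresh weight).
#'
#' @param pool_amount Non-negative pool size.
#' @param enrichment Mean fractional 13C enrichment in [0, 1].
#' @return `pool_amount * enrichment`.
#' @export
labeled_amount <- function(pool_amount, enrichment) {
  if (any(pool_amount < 0, na.rm = TRUE)) abort("`pool_amount` must be >= 0.")
  if (any(enrichment < 0 | enrichment > 1, na.rm = TRUE)) {
    abort("`enrichment` must be in [0, 1].")
  }
  pool_amount * enrichment
}

#' Correct a table of measured MIDs
#'
#' Data-frame interface over [correct_mid()]: takes one row per metabolite
#' with a Hill-notation formula, the number of tracer carbons, and measured
#' fraction columns `m0 ... mk`, and returns the corrected fractions, mean
#' enrichment, residual norm, and (when a `pool_amount` column is present)
#' the labeled amount.
#'
#' @param data Data frame with columns `metabolite`, `formula`,
#'   `n_tracer`, and `m0...mk` measurement columns; optionally `pool_amount`.
#' @inheritParams correction_matrix
#' @return A tibble, one row per metabolite, with `c0...ck` corrected
#'   fractions, `enrichment`, `residual_norm`, and optionally
#'   `labeled_amount`.
#' @export
correct_mids <- function(data, abundances = natural_abundances(), purity = 1) {
  required <- c("metabolite", "formula", "n_tracer")
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    abort(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  mid_cols <- grep("^m[0-9]+$", names(data), value = TRUE)
  if (!length(mid_cols)) abort("No measured MID columns (m0, m1, ...) found.")
  mid_cols <- mid_cols[order(as.integer(sub("^m", "", mid_cols)))]
  out <- purrr::pmap_dfr(
    list(data$metabolite, data$formula, data$n_tracer,
         seq_len(nrow(data))),
    function(met, formula, n_tracer, i) {
      measured <- as.numeric(data[i, mid_cols[seq_len(n_tracer + 1)]])
      res <- correct_mid(measured, formula, n_tracer, abundances, purity)
      row <- tibble::tibble(metabolite = met,
                            enrichment = res$enrichment,
                            residual_norm = res$residual_norm)
      corr <- setNames(as.list(res$corrected),
                       paste0("c", seq_along(res$corrected) - 1L))
      dplyr::bind_cols(row, tibble::as_tibble(corr))
    }
  )
  if ("pool_amount" %in% names(data)) {
    out$labeled_amount <- labeled_amount(data$pool_amount, out$enrichment)
  }
  out
}
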