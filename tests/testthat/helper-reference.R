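# Published per-phase 13C label-accumulation summaries (mean, printed
# dispersion, n = 3) for the metabolites whose compact-letter patterns are
# used as cross-checks, with the letters as printed.
reference_label_rows <- function() {
  tibble::tibble(
    metabolite = c("Fru", "Succinate", "Fumarate", "Glc", "Citrate"),
    mean_pre   = c(437.16, 137.83, 69.86, 1.71e5, 588.81),
    sd_pre     = c(103.16, 14.18, 6.24, 1.47e4, 87.27),
    mean_anth  = c(2378.80, 431.74, 316.96, 4.84e5, 276.14),
    sd_anth    = c(25.09, 27.73, 33.09, 1.71e4, 0.04),
    mean_post  = c(2418.67, 155.27, 220.42, 3.74e5, 436.99),
    sd_post    = c(212.58, 6.66, 9.16, 4.62e4, 8.60),
    letters    = list(c("a", "b", "b"), c("a", "b", "a"), c("a", "b", "c"),
                      c("a", "b", "c"), c("a", "b", "c"))
  )
}
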