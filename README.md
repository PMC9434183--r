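# anthoflux

Isotope flux quantification, stage-profile statistics, and correlation
networks for multi-omics studies of flower anthesis.

When a flower opens, its metabolism is rearranged wholesale: sugars are
imported, broken down and resynthesised, amino-acid pools swing, and
thousands of transcripts step up or down at the transition. Quantifying
that rearrangement takes several kinds of computation that usually live in
scattered scripts:

* **¹⁴C flux estimation** — a whole inflorescence fed uniformly labelled
  glucose partitions radioactivity over compound classes (CO₂, amino acids,
  organic acids, hexose phosphates, sucrose, fructose, protein, starch,
  cellulose). The redistribution fraction of class *c* is
  `100·Bq_c / metabolized`, and the absolute synthesis flux is
  `J_c = (Bq_c) / (SA·t)` in nmol hexose equivalents gFW⁻¹ h⁻¹, where `SA`
  is the specific activity of the precursor pool (isotopic dilution) and
  `t` the feeding time.
* **¹³C enrichment** — a measured mass-isotopologue distribution `M` is the
  convolution of tracer labelling with natural heavy-isotope abundance.
  anthoflux solves `M ≈ C·x` by non-negative least squares, where column
  *j* of `C` is the mass-shift pattern of the species with *j* fixed ¹³C
  atoms, and reports the mean enrichment `E = Σ j·x_j / n_C`.
* **Stage profiles** — normalisation by fresh weight and internal standard,
  log₂ stage means for heatmaps, relative-to-youngest-stage ratios, and
  pairwise t-tests with compact letter displays (letters differ ⇔ groups
  differ at P < 0.05; bold at P < 0.01).
* **Correlation networks** — all-pairs Pearson r with exact-t p-values,
  counts of significant/strong pairs, and thresholded networks (r > 0.65
  metabolite, 0.80 gene–metabolite, 0.82 gene–gene) with degree and
  betweenness centrality, exported as GraphML and edge CSV.
* **Transcript funnel** — low-count filtering (< 10 reads total), log₂-CPM,
  a smooth 3-df polynomial trend filter on floret age (F-test, BH), stage
  contrasts, and k-means clustering of standardised stage profiles with an
  anthesis-step summary.

A seeded synthetic-data generator reproduces each experimental design
(8 stages × 3 replicates, ~130 compounds; NB counts; MIDs; 5-replicate ¹⁴C
partitions), so the whole pipeline is testable against known ground truth.
It is intended for plant physiologists and metabolomics/transcriptomics
analysts working with stage-resolved floral (or other developmental)
datasets.

## Worked example

Recompute absolute fluxes from the packaged reference ¹⁴C partitioning
(metabolised label 1.29×10⁷ Bq gFW⁻¹, feeding solution at 7 Bq nmol⁻¹ for
5 h):

```r
library(anthoflux)

ref  <- reference_inflorescence_14c()
met  <- ref$totals$mean[ref$totals$quantity == "metabolized"]
flux <- absolute_flux(ref$redistribution$mean_pct, met, 7, 5)
tibble::tibble(class = ref$redistribution$class,
               pct = ref$redistribution$mean_pct, flux = signif(flux, 4))
#> # A tibble: 9 × 3
#>   class           pct    flux
#>   <chr>         <dbl>   <dbl>
#> 1 CO2            0.1     369.
#> 2 amino acids    0.39   1437
#> 3 organic acids 35.3  130100
#> 4 hexoses-P     53.2  196200
#> 5 Suc            6.42  23660
#> 6 Fru            1.59   5860
#> 7 protein        0.57   2101
#> 8 starch         0.17    627.
#> 9 cellulose      2.23   8219
```

The sucrose-synthesis flux of ~2.37×10⁴ nmol gFW⁻¹ h⁻¹ is a lower bound:
the feeding-solution specific activity ignores dilution of the tracer in
the internal hexose-phosphate pool (see the methods vignette).

Compact letters from summary statistics — succinate label accumulation
peaks at anthesis and its flanking phases are equivalent:

```r
compact_letters(means = c(137.83, 431.74, 155.27),
                spreads = c(14.18, 27.73, 6.66), n = c(3, 3, 3))
#> [1] "a" "b" "a"
```

Correct a simulated isotopologue measurement and recover the planted
enrichment exactly:

```r
sim <- simulate_mid_data(
  tibble::tibble(metabolite = "succinate", formula = "C4H6O4"),
  enrichment = 0.35, noise_sd = 0, seed = 1
)
correct_mids(sim$mids)[, c("metabolite", "enrichment", "residual_norm")]
#> # A tibble: 1 × 3
#>   metabolite enrichment residual_norm
#>   <chr>           <dbl>         <dbl>
#> 1 succinate        0.35      2.02e-16
```

`run_pipeline(out_dir)` chains every stage on simulated data and writes all
artifacts (tables, GraphML networks, cluster assignments) to disk,
deterministically for a given `flower_config(seed = )`.

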