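# phytoaccum

Quantitative toolkit for soil–plant bioaccumulation surveys, built for
the standard multi-site biomonitoring design: a plant compartment (e.g.
fern fronds) and three substrate horizons (humus Oh, topsoil, subsoil)
sampled at tens of sites of contrasting bedrock and climate, with ~46
element concentrations (mg/kg dry mass) per compartment. It serves
environmental geochemists and plant ecologists who need the field's
standard indices computed reproducibly, with the conventions spelled
out and tested.

The core quantities:

* **Bioconcentration factor** — BcF = c_frond / c_substrate, per site,
  element and horizon; medians across sites classify elements as
  excluded (median BcF < 0.1 in every horizon) or accumulated.
* **Enrichment factor** — EF = (E/Al)_frond / (E/Al)_substrate, with Al
  as conservative lithogenic normalizer; graded on the six-class scale
  with breakpoints 1.5, 2, 5, 20, 40 (half-open intervals partitioning
  [0, ∞)).
* **Cerium anomaly** — Ce/Ce\* = Ce_N / (Pr_N² / Nd_N) on
  shale-normalized (PAAS) REE values; < 1 signals uptake from
  oxidizing, Ce-depleted solutions.
* **Robust summaries** — min/max/mean/SD/RSD/quartiles/median/unscaled
  MAD per element, plus the robust CV (100·MAD/median).
* **Association** — Spearman screening of frond chemistry against
  substrate chemistry and site factors (BH-adjusted), and Ward
  clustering on 1 − Pearson r distances of log10 medians, with Newick
  export, `tidy()`/`glance()` and `autoplot()`.
* **Synthetic surveys** — a fully seeded generator
  (log-normal concentrations, bedrock strata, coherent REEs,
  configurable frond–substrate coupling, injectable Ce anomalies) so
  every stage is testable end to end.

## Worked example

```r
library(phytoaccum)
library(dplyr)

study <- generate_study(synth_config(seed = 1))   # 35 sites, 46 elements
report <- accumulation_report(study)

report %>%
  filter(element %in% c("As", "Ce", "Na", "Rb", "Zn")) %>%
  select(element, verdict, bcf_humus, bcf_topsoil, bcf_subsoil,
         ef_humus, ef_class_humus)
#> # A tibble: 5 × 7
#>   element verdict     bcf_humus bcf_topsoil bcf_subsoil ef_humus ef_class_humus
#>   <chr>   <chr>           <dbl>       <dbl>       <dbl>    <dbl> <ord>
#> 1 As      excluder       0.0401      0.0321      0.0314    0.435 not_enriched
#> 2 Ce      accumulated    0.365       0.303       0.261     4.16  moderate
#> 3 Na      excluder       0.0374      0.0318      0.0284    0.412 not_enriched
#> 4 Rb      accumulated    1.85        1.43        1.31     19.5   severe
#> 5 Zn      accumulated    2.03        1.58        1.39     23.2   highly_severe
```

Reading the rows: As and Na have median BcFs below 0.1 in every horizon
— the plant excludes them. Rb and Zn couple strongly to the substrate
(median BcF > 1) and, once dust input is discounted by Al
normalization, are severely/highly severely enriched in the frond
relative to humus, so both are flagged accumulated. All values here are
recovered from synthetic data whose true couplings are configured in
`synth_config()`, which is exactly how the package's recovery tests
work.

The cerium anomaly of a median REE pattern (Ce 19.1, Pr 2.46, Nd 8.22
mg/kg) against the shipped PAAS table:

```r
n <- ree_normalize(c(Ce = 19.1, Pr = 2.46, Nd = 8.22),
                   ree_reference("PAAS-P2012"))
ce_anomaly(n[["Ce"]], n[["Pr"]], n[["Nd"]])
#> [1] 0.8115414
```

a negative anomaly (ratio < 1 − 0.10 band). And the robust CV of
structural carbon from the shipped reference summary table:

```r
c_row <- filter(frond_reference_stats(), element == "C")
round(100 * c_row$mad / c_row$median, 1)
#> [1] 1.1
```

`run_pipeline("out/")` executes the whole chain on a study and writes
every artifact (summary battery, indices and medians, REE patterns,
correlation screen, two dendrograms as Newick + JSON, the per-element
report, and a manifest with the config hash and seed) as CSV/JSON;
identical inputs give byte-identical files.

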