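---
title: "Soil-plant bioaccumulation analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-plant bioaccumulation analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoaccum)
library(dplyr)
```

## The problem

Biomonitoring surveys sample a plant compartment (here: fern fronds) and
its substrates (humus Oh, mineral topsoil, mineral subsoil) at tens of
sites across contrasting bedrocks and climates, measure several dozen
element concentrations in each, and ask two questions: which elements
does the plant *accumulate* or *exclude* relative to its substrate, and
which site factors (bedrock, elevation, potential evaporation, pH)
drive the variation? `phytoaccum` implements the standard quantitative
toolkit for that design: robust element summaries, bioconcentration and
enrichment factors, shale-normalized rare-earth patterns with cerium
anomalies, nutrient stoichiometry, Spearman screening and
correlation-distance Ward clustering — and a fully seeded synthetic
generator so the whole pipeline can be exercised and tested without any
field data.

All user-facing functions take and return tibbles keyed by `site_id`,
`element` and `compartment`, so pipelines compose with the pipe.

## The indices

**Bioconcentration factor.** For element E,

$$\mathrm{BcF} = c_{E,\mathrm{frond}} / c_{E,\mathrm{substrate}},$$

a unit-free ratio computed per site, element and horizon on
replicate-aggregated concentrations ([`bcf()`], [`compute_indices()`]).
Site-level values are condensed by the median ([`median_index()`]),
which also reports how many sites contributed and how many were dropped
as `NA`. A zero substrate concentration yields `NA` with a warning, not
infinity. The conventional reading of the median BcF: below 0.1 in
every horizon the plant *excludes* the element; medians above 1
indicate active accumulation.

**Enrichment factor.** Aluminium — essentially immobile, lithogenic,
and abundant in mineral dust — serves as the normalizer:

$$\mathrm{EF} = \frac{(E/\mathrm{Al})_\mathrm{frond}}
                    {(E/\mathrm{Al})_\mathrm{substrate}}.$$

EF discounts the fraction of the frond's element pool that is merely
adhering or incorporated soil dust; EF of Al itself is identically 1,
and both indices are invariant under any common unit change, so unit
conventions cannot alter conclusions (both properties are tested).

**The six-class scale.** EFs are graded not
enriched / slight / moderate / severe / highly severe / extreme with
breakpoints 1.5, 2, 5, 20, 40. Published interval notation shares its
endpoints between adjacent classes; we implement half-open intervals
$[a, b)$ with each shared endpoint assigned to the *upper* class. The
top class being "$\ge 40$" anchors that convention, and it is the only
reading under which the six classes form a true partition of
$[0, \infty)$ — the partition and monotonicity are tested on a dense
grid.

**Stoichiometry.** C:N, N:P and C:P mass ratios per site, with N- and
P-limitation flags from the N:P ratio at the conventional
wetland-ecology thresholds 14 and 16 (the literature the thresholds
come from gives them as mass ratios of aboveground tissue; both are
configurable, and the flags are mutually exclusive by construction).

## Robust summaries

[`summarize_element()`] reproduces the survey-report battery: min, max,
mean, SD (n−1), RSD = 100·SD/mean, quartiles, median and MAD. Two
conventions matter:

* the MAD is **unscaled** — the plain median of absolute deviations
  from the median, without the 1.4826 normal-consistency factor; that
  is the scale on which published survey tables report it relative to
  their quartiles;
* quartiles default to the linear-interpolation convention
  (`type = 7`); other statistics software uses slightly different
  conventions, so the type is an argument.

The robust coefficient of variation [`robust_cv()`] is
100·MAD/median — appropriate for tightly controlled quantities such as
structural carbon, where it evaluates to about 1.1% on the shipped
reference table.

The package ships a transcribed published summary table for lady-fern
fronds ([`frond_reference_stats()`], n = 35, 46 analytes) used in
fixture tests. It is deliberately kept verbatim: a handful of printed
rows are internally inconsistent (a mean exceeding the printed maximum,
a median below the first quartile), and
[`flag_summary_consistency()`] flags them rather than repairing them —
a reader must never silently "fix" published data. Note the resource
carries *summary rows only*: any statistic of per-sample derived
quantities (for instance the cohort mean and MAD of per-sample Ce/Ce\*
ratios in the original survey) requires the per-sample supplement of
that survey and is therefore documented here as supplement-dependent
rather than asserted numerically.

## Cerium anomalies

REE concentrations are normalized against a **named, versioned** shale
composition. Survey papers typically cite a PAAS source without
printing the values, so the package ships two canonical tables —
`PAAS-TM1985` (Taylor & McLennan 1985) and `PAAS-P2012` (Pourmand,
Dauphas & Ireland 2012, the default: the modern re-determination) — and
records the reference name in every output. Swapping references is an
explicit configuration change, never a silent default change; the
Ce/Ce\* ratio itself is invariant to rescaling the reference (tested),
so the choice mainly matters if normalized values are compared across
studies.

The anomaly uses geometric extrapolation from the lighter neighbours:

$$\mathrm{Ce}/\mathrm{Ce}^{*} =
  \frac{\mathrm{Ce_N}}{\mathrm{Pr_N^2}/\mathrm{Nd_N}},$$

so a flat or geometric normalized pattern gives exactly 1. Ratios below
1 (cerium depleted relative to its neighbours) are the signature of
uptake from oxidizing solutions, in which Ce(III) has been scavenged as
insoluble Ce(IV). "Significantly different from 1" is operationalized
as a symmetric band of ±0.10 around 1 by default — wider than typical
analytical error on the ratio, and configurable; users with replicate
chemistry can propagate their own analytical SD into a narrower band.
Only the Ce anomaly is computed; Eu or La-based alternatives are out of
scope.

```{r ce-example}
conc <- c(Ce = 19.1, Pr = 2.46, Nd = 8.22) # survey median pattern
n <- ree_normalize(conc, ree_reference("PAAS-P2012"))
ce_anomaly(n[["Ce"]], n[["Pr"]], n[["Nd"]])
```

## Correlation screening and clustering

Concentrations are roughly log-normal, so association work happens on
ranks and logs. [`spearman_screen()`] computes Spearman's rho with
two-sided p-values (large-sample t approximation — adequate for
continuous variables at survey n) for every target × predictor pair,
Benjamini–Hochberg adjustment across the screen (raw p always
reported), and conventional significance stars. Bedrock enters as 0/1
indicators so the sign of rho reads as enrichment on that bedrock.

Clustering input is the site × element matrix of log10-transformed
per-site medians. The phrase "log-transformed medians" admits two
readings; the default is log10 of the median, and `median_of_logs =
TRUE` gives the alternative (they coincide once replicates are
aggregated). Dissimilarity is $1 - r$ (Pearson), linkage is Ward's
method applied **directly to those dissimilarities** via the
Lance–Williams update — the "Ward.D" convention. On a non-Euclidean
dissimilarity this is mathematically loose (the within-cluster variance
interpretation does not hold, and merge heights can invert), but it is
exactly what the legacy statistics packages used in such surveys do, so
the package reproduces the procedure rather than the Euclidean-only
purist variant. Exact ties in the merge criterion are broken by the
lexicographically smallest pair of cluster labels, making the merge
history deterministic and invariant to input order (tested by
permutation). Trees serialize to Newick (via `ape`) and to a tidy merge
list; `tidy()`, `glance()` and `autoplot()` provide the broom/ggplot2
views.

```{r cluster-example}
study <- generate_study(synth_config(n_sites = 20, seed = 1))
tree <- cluster_elements(study$frond)
glance(tree)
```

## What the synthetic generator emulates — and what it does not

[`synth_config()`] fixes the study conditions: 35 sites, a bedrock
mixture of 7 sandstone / 6 phyllite / 9 granitoid / 10 paragneiss / 3
basic sites, elevations uniform on 275–925 m, potential evaporation
decreasing with elevation and binned into 50 mm/y classes, and 46
analytes whose frond geometric means are seeded from the shipped
reference medians back-solved through default couplings (illustrative
values, not ground truth). On top of that skeleton it generates:

* log-normal subsoil concentrations (geometric SD 1.8), multiplied by 4
  for the granite-affine elements Rb, Cs, Be, Tl, U on granitic sites;
* topsoil and humus as multiplicative horizon profiles (0.9 and 0.7 of
  subsoil), humus additionally enriched 3× in the deposition-affected
  metals Cd, Hg, Bi, Cu, Mo, Pb, Sb, Sn and depleted in Al (0.4×);
* fronds coupled to the **topsoil** (configurable) at a per-element
  true BcF with log-normal noise of geometric SD 1.3, three analytical
  replicates at geometric SD 1.02, REEs sharing a latent site factor
  with coherence 0.9, and an optional Ce multiplier that injects an
  anomaly of known size.

Everything is a deterministic function of the seed. The noise-free
limit (all geometric SDs 1, all multipliers 1) makes every downstream
index analytically predictable and is used as a closed-loop test of the
whole pipeline.

What it does **not** emulate: spatial autocorrelation, mechanistic soil
chemistry or rhizosphere processes, realistic inter-element correlation
beyond the REE block and the bedrock strata, censored values at real
detection limits, or sampling error of composite specimens. Passing
recovery tests on this generator therefore demonstrates that the
*pipeline* is unbiased and correctly wired under its stated model — not
that the model captures any particular landscape.

## Numerical and design choices

* **Detection limits**: `"<x"` strings are accepted and substituted by
  x/2 by default (configurable to x or `NA`); substitution happens at
  read time and is flagged per value, so zeros never reach the log
  transform (a zero there is a hard error by design).
* **Replicate aggregation**: median by default (robust to one bad
  digestion), mean available; single replicates pass through
  unchanged; mixed replicate counts aggregate what is available with a
  warning.
* **Evaporation classes** are scored by interval midpoints for
  correlation work, parsed insensitively to dash typography.
* **NA policy**: indices propagate `NA` rather than dropping rows
  silently; every median reports its contributing-site count.
* **Tolerances in tests**: deterministic identities are checked to
  near machine precision; stochastic recovery checks use a priori
  bands (±15% for median-BcF recovery at n = 35 and noise GSD 1.3,
  about 2.6 Monte-Carlo standard errors) or bounds derived from the
  observed Monte-Carlo standard error (Ce-injection recovery, 3 SE).
* **Problem sizes**: the test suite runs studies of 5–35 sites, 200–300
  sites for law-of-large-numbers checks, 1000 replicates for the
  null-calibration of the Spearman screen, and exhaustive clustering
  oracles up to 6 items — sizes chosen so the full suite completes in
  well under a minute while keeping every stochastic check comfortably
  powered.

## Known limitations

* Ward.D on 1 − r can produce height inversions; Newick exports carry
  them as-is.
* The Spearman screen treats each pair marginally; no multivariate or
  spatial model is fitted, and with many collinear site factors some
  significant correlations will be incidental — the adjustment controls
  FDR across the screen, nothing more.
* The enrichment-class scale and the excluder/accumulated cut-offs
  (median BcF < 0.1; median EF ≥ 10) are field conventions, not
  inferential statements.
* XLSX supplements are not read directly; export such files to CSV
  first.
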