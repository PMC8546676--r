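# perihg

Mercury methylation kinetics and methylator-community screening in
periphyton.

Periphyton — the attached biofilm of algae, cyanobacteria and heterotrophic
microbes coating submerged surfaces — is a hotspot for the microbial
production of monomethylmercury (MMHg), the neurotoxic, biomagnifiable form
of mercury. Field assays spike intact biofilm incubations with enriched
stable isotopes (inorganic ²⁰⁰Hg and MM¹⁹⁸Hg) and measure, after a single
time point, how much MM²⁰⁰Hg was produced and how much MM¹⁹⁸Hg was lost.
`perihg` turns those measurements, together with the accompanying molecular
data, into rate constants, speciation budgets, gene screens and community
statistics — with a synthetic-data module that generates every input with
known ground truth, so the whole pipeline is testable without any raw field
data.

## The models at the core

**Kinetics.** Net MMHg production follows
d[MMHg]/dt = k_m [Hg(II)] − k_d [MMHg], with methylation and demethylation
rate constants k_m, k_d (day⁻¹). With isotope spikes the initial product
pools are zero, so single-time-point estimators are

    k_m = −ln(1 − [MM²⁰⁰Hg]_t / [²⁰⁰Hg(II)]₀) / t
    k_d = −ln([MM¹⁹⁸Hg]_t / [MM¹⁹⁸Hg]₀) / t

with detection-limit censoring of the product tracer, replicate
summarisation (mean ± sd/√n over detected replicates), and one-way ANOVA +
Tukey HSD between sites. The full coupled model is also available in closed
form, which lets you quantify how much the single-time-point estimate
underestimates k_m when demethylation is fast.

**HgcA screening.** Predicted proteins with profile-search bit scores ≥ 100
are HgcA candidates; those scoring ≥ 164 *and* carrying one of six
conserved cap-helix 8-mers (NVWCAAGK, NVWCASGK, NVWCAGGK, NIWCAAGK,
NIWCAGGK, NVWCSAGK) are complete-confidence. Abundance is coverage-weighted
(gene copies × contig mean depth, summed per taxon). Taxonomy comes from two
routes — filtered best-bit-score similarity hits (E ≤ 1e-20, identity ≥ 40%,
coverage ≥ 80%) and smallest-clade placement on a reference tree — with a
consensus agreement percentage over candidates.

**Community.** 16S ASV tables are aggregated to relative abundance by rank,
rare taxa (< 2% mean) lumped, and sample structure tested with Bray–Curtis
dissimilarity, principal-coordinate analysis, and a seeded one-way PERMANOVA
(p = (1 + #{F* ≥ F}) / (1 + n_perm)).

## Worked example

```r
library(perihg)
library(dplyr)

# Simulate a three-site tracer experiment (triplicates, 4 ng/L spikes,
# 48 h, LOD 0.01 ng/L) and estimate rate constants
sim <- sim_tracer_experiment(seed = 1)
est <- estimate_rates(sim$samples)
summarize_site_rates(est)
#> # A tibble: 6 × 6
#>   site_id kind              mean        se n_detected n_total
#>   <chr>   <chr>            <dbl>     <dbl>      <int>   <int>
#> 1 flooded demethylation  2.14     0.228             3       3
#> 2 flooded methylation    0.00201  0                 1       3
#> 3 natural demethylation  1.46     0.125             3       3
#> 4 natural methylation   NA       NA                 0       3
#> 5 wetland demethylation  1.62     0.0767            3       3
#> 6 wetland methylation    0.00704  0.000248          3       3
```

Methylation is quantifiable in every wetland replicate but censored at the
detection limit in most replicates of the other two sites — the regime
these assays actually produce; demethylation is fast (~1.5–2 day⁻¹)
everywhere. Speciation bookkeeping on the example ambient survey:

```r
water <- filter(example_speciation(), matrix == "water")
percent_mmhg(water)
#> # A tibble: 3 × 5
#>   site_id matrix  mmhg   ihg pct_mmhg
#> 1 natural water   0.1   1.62     5.81
#> 2 flooded water   0.12  1.25     8.76
#> 3 wetland water   0.23  0.76    23.2

spike_fold_ratio(water, 4, "thg")
#> # A tibble: 1 × 4
#>   species spike_conc ambient_mean  fold
#> 1 thg              4         1.36  2.94
```

The wetland's water column carries 23.2% of its total mercury as MMHg, and
the 4 ng/L spike is about 3-fold ambient total mercury. The full pipeline —
rates, budget, HgcA screen, consensus taxonomy, community ordination and
PERMANOVA — runs in one call and writes every stage table plus a run log:

```r
report <- run_pipeline("perihg_out", seed = 1)
nrow(report$candidates)          # 24 HgcA candidates survive screening
report$consensus$agreement_pct   # 83.3% similarity/tree agreement
glance(report$permanova_site)    # site effect p = 0.001
```

A thin command-line front end with the same stages lives at
`inst/cli/perihg.R` (`simulate`, `rates`, `budget`, `screen-hgca`,
`taxonomy`, `community`, `run`).

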