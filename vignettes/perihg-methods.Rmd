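---
title: "Methods: tracer kinetics, HgcA screening and community profiling in periphyton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer kinetics, HgcA screening and community profiling in periphyton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perihg)
library(dplyr)
```

perihg analyses isotope-tracer mercury transformation assays in periphyton
(attached freshwater biofilms) together with the molecular data that
characterise the methylating community: HgcA protein screens of assembled
metagenomes, dual-route taxonomy of the candidates, and 16S ASV community
profiles. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The kinetic model

Net monomethylmercury (MMHg) production in a closed incubation follows the
two-compartment first-order system

$$\frac{d[\mathrm{MMHg}]}{dt} = k_m\,[\mathrm{Hg^{II}}] - k_d\,[\mathrm{MMHg}],$$

with $k_m$ the methylation and $k_d$ the demethylation rate constant (both
day^-1^). Enriched-isotope spikes decouple the two directions: a
^200^Hg(II) spike starts with no MM^200^Hg, and a MM^198^Hg spike starts
with no ^198^Hg(II). `simulate_coupled_tracers()` solves the full system
analytically per tracer pool — each pool of total $T$ relaxes to the
equilibrium $T k_m/(k_m+k_d)$ at rate $k_m+k_d$, conserving $T$ exactly.

With a single end-point measurement, the back-reaction on each product is
dropped, which makes the model integrable per direction:

$$k_m = -\ln\!\left(1 - \frac{[\mathrm{MM^{200}Hg}]_t}{[\mathrm{^{200}Hg^{II}}]_0}\right)\Big/\,t,
\qquad
k_d = -\ln\!\left(\frac{[\mathrm{MM^{198}Hg}]_t}{[\mathrm{MM^{198}Hg}]_0}\right)\Big/\,t.$$

`estimate_km()`/`estimate_kd()` are the exact inverses of
`simulate_simplified_tracers()`; a round-trip test holds to 1e-12 over
$k_m t \in (0, 5)$ and $k_d t \in (0, 10)$. Applied to data generated by the
*coupled* model, the $k_m$ estimator is biased low whenever $k_d > 0$,
because demethylation removes part of the newly formed MM^200^Hg before it
is measured: at $k_m = 5.9\times10^{-3}$, $k_d = 1.78$, $t = 2$ d the
estimate is $\approx 1.6\times10^{-3}$ day^-1^. Single-time-point rate
"potentials" of this kind are therefore conservative; the package exposes
both forward models so the bias can be quantified for any parameter set.

Conventions and edge cases:

* Time is in days; a 48-h incubation is `t_days = 2`.
* A product tracer at or below the MMHg detection limit (default 0.01
  ng L^-1^) is a **non-detect**: the replicate is flagged, excluded from
  site means by default (`nondetect_as_zero = TRUE` selects the
  include-as-zero policy), and always counted in `n_total`.
* A measured product at or above the spike is rejected as physically
  impossible (the logarithm is undefined).
* An apparent MM^198^Hg *gain* would give $k_d < 0$; the estimate is clamped
  to 0 with a warning since the decay model presumes net loss.
* Site means use the standard error $s/\sqrt{n}$ over detected replicates.
* Site comparison uses one-way ANOVA (`stats::aov`); pairwise contrasts use
  Tukey's HSD at $\alpha = 0.05$. Tukey was chosen because it controls the
  family-wise error of all pairwise site contrasts, the comparison actually
  displayed; sites with fewer than two detected replicates are excluded
  with a warning since they carry no within-group variance.

## Speciation bookkeeping

Inorganic Hg is not measured directly; `ihg_by_subtraction()` fills
IHg = THg − MMHg and refuses negative results. `percent_mmhg()` computes
100·MMHg/THg at full precision, reconstructing THg as MMHg + IHg when
needed; rounding to one decimal is presentation-only. Because upstream
tables are themselves rounded, recomputed percentages can differ from
published ones in the last decimal; the package treats such differences as
upstream rounding, not as errors. `spike_fold_ratio()` reports the
unrounded ratio of a spike to the across-site mean ambient concentration.

## HgcA screening

Candidate identification consumes profile-search scores (full-sequence bit
scores by default) rather than re-running the profile HMM: the
contribution here is the classification, not the search. Thresholds:

* score ≥ 164 **and** a conserved cap-helix motif → `complete`;
* score ≥ 100 otherwise → `partial` (alignment is convincing but the motif
  region is missing, typically because the contig is too short);
* score < 100 → `rejected`.

Both thresholds are inclusive. The motif set is the six discrete 8-mers
(`hgca_motifs()`); matching is exact because the variants are enumerated,
not a degenerate pattern. A score ≥ 164 without a motif is demoted to
`partial` with a warning rather than trusted blindly. Abundance is
coverage-weighted: one gene copy × its contig's mean read depth, summed by
assigned taxon, with relative fractions alongside. merA/merB are counted
from EC annotations (1.16.1.1 / 4.99.1.2), zeros reported explicitly.

## Dual-route taxonomy and consensus

Similarity assignment filters hits at E ≤ 1e-20, identity ≥ 40% and query
coverage ≥ 80% (inclusive), then takes the best bit score per query; ties
across taxa fall back to the rank-wise lowest common ancestor, so an
ambiguous query may be assigned at order but not family. Tree assignment
walks from the query leaf to the smallest ancestral clade containing at
least one reference leaf (other query leaves are invisible during this
inspection); unanimity of the reference leaves at a rank assigns that rank,
a mixed clade leaves it unassigned. The Newick topology is used rooted as
written — no re-rooting is attempted because none is specified upstream,
and the smallest-ancestral-clade rule is one deliberate formalisation of
"placed within a distinct clade"; the test suite pins it to an exhaustive
clade-enumeration oracle on small random trees.

`consensus_compare()` scores agreement at a single configurable rank
(default family). Both-routes-unassigned counts as agreement; a
disagreement keeps the similarity label flagged *hypothetical* — the
sequence-similarity route yields a label the phylogeny cannot corroborate.
Comparing at one fixed rank (rather than the deepest rank both routes
reached) keeps the statistic interpretable; coarser or finer comparisons
are one `rank =` away.

## Community profiling

`relative_abundance()` aggregates ASV counts by lineage at a rank and
normalises per sample; unassigned ASVs pool into `unclassified`.
`lump_rare()` merges taxa whose *mean* fraction is strictly below 2% into
`others` (a taxon at exactly 2% is kept). Bray–Curtis dissimilarity is
computed on relative abundances via `vegan::vegdist`. PCoA uses classical
scaling (`stats::cmdscale`); axes with non-positive eigenvalues are
dropped and explained fractions are taken over the positive eigenvalues
only, so they are non-increasing and sum to ≤ 1.

PERMANOVA is implemented in-package because the permutation contract
matters for reproducibility: the observed statistic is included in the
reference set, $p = (1 + \#\{F^\* \ge F\})/(1 + n_{perm})$, so the smallest
attainable p with 999 permutations is 1/1000, and the label permutations
are driven by an explicit seed, making results bit-reproducible. The
statistic equals `vegan::adonis2`'s pseudo-F (the suite asserts this), and
the test is one-way on a single factor at a time — with sites and
treatments crossed and balanced, one-way tests of each factor are the
transparent choice.

## Synthetic data: what it emulates, what it does not

The generators produce every input with known ground truth.

`sim_tracer_experiment()` draws per-replicate tracer measurements from the
coupled forward model (default) with multiplicative lognormal noise and
left-censoring at the detection limit; censored values are emitted as `NA`
with a flag, never as zeros. The noise is mean-unbiased
($\mu_{\log} = \log x - \sigma^2/2$, $\sigma^2 = \log(1+CV^2)$) because
analytical error in CVAFS-type determinations scales with concentration.
The default CV of 0.5 reflects field-scale replicate variability of intact
biofilm incubations; the default design is 3 sites × 3 replicates, 4
ng L^-1^ spikes, t = 2 d, LOD 0.01 ng L^-1^. The default site parameters
are coupled-model truths chosen to reproduce the observed assay regimes:
the wetland's product tracer reaches ≈ 4.7×10^-2^ ng L^-1^ (a
simplified-estimator yield of ≈ 5.9×10^-3^ day^-1^, detectable in every
replicate), while the natural and flooded sites produce near the detection
limit so that, at the default noise, methylation is detected in only a
subset of replicates. Demethylation sits near 1.8 day^-1^ everywhere with
natural and flooded apart.

`sim_hgca_fixture()` plants complete (motif + score ≥ 164) and partial
(motif-less, 100–163) HgcA proteins among decoys scoring below 100. Decoys
are composition-preserving shuffles of true sequences, so a chance exact
motif in a decoy is possible — a deliberate stress test; such a decoy still
fails on score. Protein lengths span 102–292 aa, matching partial genes on
short contigs. `sim_reference_tree()` builds family-monophyletic reference
clades and attaches queries either inside their family or into a
deliberately mixed clade (which the clade rule must leave unassigned).
`sim_asv_table()` draws Dirichlet-multinomial counts around site-specific
phylum profiles (Proteobacteria 36.3%, Cyanobacteria 26.8%, ten further
phyla) split over ASVs with fixed weights; treatments have no effect by
construction, so a treatment PERMANOVA is null while site tilts are
recoverable. Defaults: 27 samples (3 sites × 3 treatments × 3), depth
10,000, concentration 500.

What passing tests on these data do **not** show: real periphyton data have
compositional structure (correlated taxa, zero inflation) richer than a
Dirichlet-multinomial; real hmm scores are not uniform draws within a band;
real measurement error may include additive components near the detection
limit; and real trees have uncertainty the placement rule ignores.
Generator-based tests validate the *algorithms* under known truth, not the
field protocol.

## Problem sizes and determinism

Simulation-backed checks use deliberately modest sizes — 1000 triplicate
simulations for estimator recovery, 1000 null datasets × 99 permutations
for PERMANOVA calibration, trees of ≤ 12 leaves against the brute-force
clade oracle — chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error well inside the asserted tolerances. All
stochastic entry points take explicit integer seeds, and
`run_pipeline()` writes byte-identical outputs for identical seeds.

## Known limitations

* Single-time-point estimation cannot separate $k_m$ from sorption or
  availability kinetics; the reported constants are rate *potentials*
  conditioned on the simplified model, and no multi-point regression is
  provided.
* Replicate-level censoring plus detected-only averaging biases site means
  upward when detection is rare; `n_detected`/`n_total` are always
  reported so the reader can judge.
* The clade rule is a formalisation of an informal practice; other
  formalisations (e.g. requiring a support threshold) would need tree
  uncertainty the inputs do not carry.
* Coverage-weighted abundance assumes one gene copy per contig and equal
  recovery across taxa.
```{r teaser, eval = FALSE}
report <- run_pipeline("perihg_out", seed = 1)
report$site_rates
glance(report$permanova_site)
```
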