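---
title: "Multi-omics integration and hub-gene discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics integration and hub-gene discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixhub)
```

`omixhub` narrows differentially expressed genes (DEGs) of a paired
tumor/normal cohort to candidates whose expression change is concordant
with an upstream regulatory alteration — miRNA expression, promoter
methylation or DNA copy number — and then ranks candidates by their
topological position in protein–protein interaction (PPI) subnetworks.
This vignette records the statistical model, every tunable threshold with
its default and rationale, the synthetic-cohort design, and the numerical
conventions; it is the package's design document.

## Paired differential model

For a feature with tumor/normal sample pairs matched on `patient_id`, the
test statistic is built from within-patient differences
$d_i = y_i^{(T)} - y_i^{(N)}$ on a transformed scale (below). With $n$
pairs, per-feature sample variance $s^2$ on $n-1$ degrees of freedom, and a
scaled inverse-chi-square prior $s^2 \sim s_0^2\,\chi^{-2}_{d_0}$, the
posterior variance is

$$\tilde s^2 = \frac{d_0 s_0^2 + (n-1) s^2}{d_0 + n - 1},\qquad
\tilde t = \frac{\bar d}{\sqrt{\tilde s^2 / n}},$$

with two-sided p-values from a t distribution on $d_0 + n - 1$ degrees of
freedom. The prior $(d_0, s_0^2)$ is estimated by method of moments on the
log sample variances: writing
$e_g = \log s_g^2 - \psi(\tfrac{n-1}{2}) + \log\tfrac{n-1}{2}$, the excess
dispersion $\operatorname{var}(e) - \psi'(\tfrac{n-1}{2})$ determines $d_0$
through the inverse trigamma function (solved by Newton iteration) and
$s_0^2 = \exp\{\bar e + \psi(\tfrac{d_0}{2}) - \log\tfrac{d_0}{2}\}$. When
the observed dispersion does not exceed what sampling alone explains,
$d_0 = \infty$ and the pooled variance $\overline{s^2}$ — the maximum
likelihood scale in that limit — is used for every feature. `prior_df = 0`
recovers the ordinary paired t exactly, and the test suite verifies both
limits against independent oracles and against an established
empirical-Bayes implementation.

Assumptions: differences are approximately Gaussian on the analysis scale;
pairs are exchangeable; features are treated independently apart from the
shared variance prior. Unpaired samples are excluded from testing (they
still contribute to the correlation gates, which use all tumor samples).

**Scales.** Expression (RPKM/RPM-like, non-negative) is tested on
$\log_2(x + 1)$; the pseudocount of 1 guards zeros. Methylation beta
values, strictly inside $(0,1)$, are tested on $\log_2 \beta$ (pseudocount
0), so the "fold change" is a ratio of betas; gene-level betas are the
arithmetic mean of the gene's probes. Testing beta values with a
fold-change criterion is unusual — an M-value analysis is available by
passing a logit-transformed matrix with `log_transform = FALSE` — but the
ratio-of-betas reading is the package default so that one significance
rule (fold change ≥ 2, BH-adjusted P < 0.01) applies uniformly to all
three layers. Features constant across all pairs are reported `ns` rather
than failing the run.

## Copy-number calling

Segments (SEG, 1-based inclusive) are mapped onto genes (BED-like, 0-based
half-open) on a common half-open scale. A gene takes the `seg_mean` of the
overlapping segment; with several, the largest overlap wins and ties break
to the earlier segment start — a deterministic, auditable single-segment
provenance, in preference to an overlap-weighted mean. Five states per
gene and sample at log2-ratio thresholds −1.3 / −0.3 / 0.3 / 0.9
(homozygous deletion ≤ −1.3; heterozygous ≤ −0.3; gain ≥ 0.3; amplification
≥ 0.9; boundaries inclusive on the extreme side; diploid otherwise). These
are the conventional SNP-array cut points, and they are configuration, not
inference: real pipelines derive gene states from a dedicated
recurrence-modelling tool, and any thresholds can be supplied.

Recurrence is a deliberately simple stand-in for full genomic recurrence
modelling (background rate varying along the genome, arm-level events,
peel-off): per gene and per significant state (amplification, homozygous
deletion), a one-sided binomial tail against the cohort-wide rate of that
state, BH-corrected, reported at q < 0.01 when the gene's frequency
exceeds background. A zero background rate is floored at
$1/(2\,n_\text{samples}\,n_\text{genes})$ so a state seen only in planted
genes remains testable. This suffices for gene-level candidate selection;
it does not localize focal regions.

## Bimodal filtering

All gates, with defaults and boundary conventions:

| gate | default | boundary |
|---|---|---|
| DEG fold change | ≥ 2 | inclusive |
| DEG adjusted P | < 0.01 | strict |
| target-prediction support | ≥ 3 algorithms | inclusive |
| functional pair correlation | r < −0.1 | strict |
| functional pair P | < 0.05 | strict |
| dosage correlation | r > 0.5 | strict |
| dosage P | < 0.05 | strict |
| PPI interaction score | ≥ 0.4 | inclusive |
| hub rank cutoff | top 10, ≥ 2 metrics | ties kept |

Direction rules: up-regulated miRNA ↔ down-regulated target (and vice
versa); over-expressed ↔ hypomethylated, under-expressed ↔ hypermethylated;
over-expressed ↔ recurrently amplified, under-expressed ↔ recurrently
deleted. The miRNA candidate set is *not* restricted by the correlation
gate — candidates are defined by differential status and targeting alone,
and the correlation-gated "functional pairs" are a separate output — so
both the candidate-set overlap view and the functional-pair view are
available. The dosage gate defaults to r > 0.5 on the reasoning that a
copy-number change claimed to drive expression should explain a majority
variance share; the threshold is a plain argument for users who prefer a
permissive screen. Correlations use all tumor samples (not only paired
ones): regulatory coupling is a property of the tumors, and the larger n
stabilizes r. Pearson p-values use
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; zero-variance vectors give an
undefined record that is logged and excluded downstream rather than an
error.

## Network analysis

The PPI edge list keeps edges with score ≥ 0.4 between two DEGs (the score
is a filter, never a distance: all path computations are unweighted).
Self-loops and duplicate edges are dropped with a logged count; isolated
DEGs are excluded. Each candidate set seeds a subnetwork of seeds plus
first neighbors with all induced edges.

Centralities follow the conventions of the standard interactive
network-analysis tooling: degree is the incident-edge count; betweenness
is the unnormalized sum over unordered pairs (endpoints excluded) of the
fraction of shortest paths through the node; closeness for a node in a
connected component of size $n_c$ is $(n_c-1)/\sum d$ within the
component, 0 for isolated nodes. Ranks are dense (1 = best, ties share a
rank) and top-10 membership keeps ties at the cutoff: "top 10" is
underdetermined under ties and silently dropping tied nodes would make the
result order-dependent. A candidate in the top 10 of ≥ 2 of the three
metrics is a hub; a candidate in the degree top 10 of ≥ 2 subnetworks (and
not already a hub) is an additional key gene. Ranking is computed over all
subnetwork nodes, hub eligibility restricted to candidates; the full
ranked table is returned for inspection.

## Enrichment

Hypergeometric upper-tail over-representation of a query against GMT gene
sets, BH-corrected, reported below adjusted P < 0.05. The background
universe defaults to the genes on the expression matrix — the
platform-restricted universe is the defensible default; a genome-wide
background would overstate enrichment. Zero-overlap terms are tested
(P = 1) but never reported. No modified-score variant of the test is
applied.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates a paired cohort shaped like a mid-size
tumor study: 60 patients with tumor samples, the first 30 with matched
normals, 2,000 genes, 300 miRNAs, 4,000 CpG sites (about two per gene),
one copy-number segment table over 22 chromosomes, a miRNA→gene target
table with algorithm-support counts, a scored PPI edge list and full truth
labels. All randomness flows from one seed through a locally scoped
generator; equal configs give byte-identical outputs.

* **Expression** is log-normal: $\log_2$ values are a gene baseline
  $\mu_g \sim U(3,8)$ plus Gaussian noise (sd 0.3 by default, a typical
  residual spread for log-scale expression), exponentiated to keep
  RPKM/RPM non-negativity. Planted DE genes (10% of genes, half up) shift
  by ±2 log2 units in tumors.
* **miRNA repression pairs** couple a DE gene and an oppositely shifted DE
  miRNA through a shared per-patient latent factor (±0.5 per unit latent),
  giving a population tumor-side correlation near −0.73, so the planted
  anti-correlation survives the r < −0.1 gate with a wide margin.
* **Methylation** is generated on the logit scale and squashed into (0,1),
  matching the bounded nature of beta values; planted genes shift their
  sites by ∓2 logit units opposite to expression. Baseline betas of
  planted sites are kept in ranges (hyper: 0.15–0.30, hypo: 0.45–0.70)
  where a ±2 logit shift translates into a ≥ 2-fold beta ratio, so the
  uniform significance rule can detect them.
* **Copy number**: planted genes sit in their own segments with per-tumor
  dosage drawn from U(0.9, 1.8) (amplified) or −U(1.3, 2.2) (deleted), and
  tumor expression adds the dosage directly, giving a population
  expression–dosage correlation near 0.65. The gene shared by all three
  layers and the copy-number key gene draw from a wider range (up to
  |3.2|) so their r > 0.5 and r < −0.1 gates hold with a z-margin above 3
  rather than sitting near the threshold. Background segments (runs of up
  to 25 genes) get seg\_mean ∼ N(0, 0.05), far from any call boundary.
* **PPI graph**: a static power-law (fitness) background at edge density
  0.08 with exponent 2.3, plus a 30-leaf star for each key gene whose
  leaves are DE genes without planted regulation. The heavy tail matters:
  with a degree-homogeneous background, small subnetworks tie so heavily
  that a dense-rank top-10 admits most nodes and hub calling degenerates;
  power-law hubs give the rankings something to be selective against.
  Planted candidate genes are kept off the high-fitness head so that the
  only planted genes with high centrality are the deliberately star-wired
  key genes. One gene is planted in all three layers (down-regulated,
  hypermethylated, deleted, targeted by an up-regulated miRNA), making the
  triple intersection non-empty by construction.

What the simulator does **not** emulate: count noise and
sequencing-depth effects (no negative binomial, no library-size
variation), probe-level methylation chemistry, allele-specific or integer
copy number, correlated co-regulation beyond the planted pairs, batch
effects, and the topology of any real interactome beyond a heavy-tailed
degree distribution. Passing tests therefore demonstrate that the
pipeline's logic recovers signal under its own model assumptions — not
that those assumptions hold for any particular real cohort.

## Numerical choices and degenerate inputs

* BH adjustment validates p ∈ [0,1] and delegates to the standard step-up
  implementation; inverse trigamma is solved by Newton iteration to
  relative 1e-8.
* Zero-variance features: `t = 0, p = 1`, status `ns`; a zero-variance
  feature with a non-zero mean difference under a zero prior is an error,
  as the statistic is genuinely undefined.
* Largest-overlap ties in segment mapping break to the earlier start;
  sample order never affects results (verified by a reordering test).
* Empty seeds, empty queries, null cohorts: warn and propagate empty
  results; the full pipeline runs to completion on a cohort with no
  planted signal and reports zeros everywhere.
* Betweenness and closeness are validated exactly (to 1e-12) against a
  brute-force all-pairs shortest-path counting oracle on random graphs of
  up to 30 nodes; the test suite uses 50 such graphs, a size chosen so the
  cubic oracle stays fast while covering sparse and dense regimes.
* Test problem sizes: unit tests run on 300-gene cohorts; end-to-end
  recovery and type-I checks use the default 2,000-gene, 30-pair cohort
  (one cohort for the rate check, twenty seeds for the
  no-false-positives check) — large enough for stable rates, small enough
  to keep the suite under a minute of simulation time.

## Known limitations

The recurrence test ignores genomic position, so adjacent genes in one
altered segment are called independently. The methylation fold-change
criterion inherits the scale ambiguity discussed above. Hub calling with
dense ranks is sensitive to the degree-tie structure of small subnetworks;
in graphs with few distinct centrality values, "top 10" is generous by
construction. The enrichment stage tests user-supplied sets only — it
ships no pathway database, performs no term-graph propagation, and its
background should match how the query was derived.
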