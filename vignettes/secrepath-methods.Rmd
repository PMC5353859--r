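---
title: "secrepath: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{secrepath: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secrepath)
```

# The reconstruction data model

A secretory-pathway reconstruction is a curated catalogue: one row per
component (a protein participating in translocation, folding, transport,
quality control or regulation of secretion), annotated with

* **subsystems** — the interconnected sub-pathways: translocation,
  protein folding, protein transport, UPR, ERAD, plus the branch subsystems
  autophagy, apoptosis and ER stress (and `other`). A component may belong
  to several; subsystem counts therefore sum to more than the component
  count, never less. Golgi N-/O-glycosylation is deliberately outside the
  vocabulary — those systems are independent of this reconstruction's scope.
* **functional groups** and **protein complexes** — literature-defined sets
  sharing a function, and physical assemblies (OST, COPI, COPII, ESCRT-I,
  the proteasome are the canonical examples). These become first-class graph
  nodes, with `membership` edges to their member components.
* **evidence** (`verified` / `tentative`), a **core**-machinery flag, and a
  **partial**-annotation flag.

The catalogue file dialect is deliberately strict — UTF-8 TSV, header row,
";"-separated multi-value cells — because a testable dialect beats a
spreadsheet. Unknown subsystem labels are errors by default (fail-fast);
`allow_extra_labels = TRUE` is the escape hatch for extended vocabularies.
Node identifiers are case-preserved but always *compared*
case-insensitively: gene-symbol capitalisation drifts between mouse-style
(`Hspa5`), human-style (`HSPA5`) and database exports, and silent
non-matches are the costliest failure mode of network overlays. Isoprotein
nodes are declared in the catalogue (`kind = "isoprotein"`), never inferred.

`build_network()` materialises the graph; `drop_isolated = TRUE` removes
component nodes with no edge at all, mirroring network representations that
leave out components with no described interactions. The connected-component
count reported by `network_stats()` is computed on the full heterogeneous
graph; we treat published "connected components" counts as component-kind
nodes retained after dropping isolated ones, since sources rarely say
whether isoprotein duplicates were counted.

# Homology transfer

Transfer consumes standard 12-column alignment hit tables. Per reference
protein, the best hit is the lowest e-value (ties: higher bitscore, then
higher identity, then lexicographic subject id — fully deterministic).
Acceptance is tiered:

| tier | rule (defaults) |
|------|-----------------|
| high | identity > 80% |
| moderate | identity > 60% **and** bitscore > 50 **and** e-value ≤ 1e-5 |
| unmapped | anything else, and always pseudogene subjects |

Published methods sections sometimes quote a stricter identity cut (> 90%)
than the acceptance rules actually applied in the corresponding results
(> 80% plus a 60–80% tier); we default to the rules that describe what was
actually accepted and expose every threshold. "Significant e-value" is
undefined in most write-ups; 1e-5 is the conventional default here. One
target gene may serve several reference components — the transfer report
flags such many-to-one cases rather than silently inventing uniqueness, and
the target catalogue keeps the first occurrence (catalogue ids must be
unique).

# Expression

CPM is counts over library size times 1e6; with TMM normalisation the
scaling factors follow the weighted trimmed mean of M-values: reference =
sample whose upper-quartile count fraction is closest to the mean upper
quartile; per sample, log-ratios M and abundances A versus the reference
over genes positive in both; trim the extreme 30% of M and 5% of A; weight
the surviving M by inverse delta-method variances; normalise factors to
geometric mean 1. On clean data this reproduces edgeR's factors to ~1e-3
(verified in the tests, with edgeR as an independent oracle only).

"Detected CPM in at least two samples" is ambiguous as a filter; we read it
as CPM ≥ 1 in ≥ 2 samples — the common convention — and expose both numbers.
DE model fitting (GLM dispersion estimation, likelihood-ratio tests) is out
of scope by design: the package consumes per-gene `(gene, log2FC, p)`
tables, recomputes Benjamini–Hochberg FDR itself (step-up with
monotonisation; checked against a smallest-rejecting-level oracle), and
flags `up` / `down` (FDR < 0.05, p < 0.05, |log2FC| ≥ 2), `de_below_fold`
(significant by FDR but below the fold cut) and `not_expressed`.
`de_below_fold` exists because coordinated sub-fold shifts of whole
complexes are exactly what the overlay method detects.

Growth metrics: t~d~ = ln 2 / μ; μ is the least-squares slope of
ln(viable density) against time over a chosen window (the field reports μ
without stating a method; the log-linear fit is the default assumption).
Specific productivity uses the integral-of-viable-cell-density definition
q~P~ = ΔP / ∫X dt (trapezoidal), in pg/cell/h for titers in mg/L, densities
in cells/mL and hours — published q values computed by unstated formulas are
not reproduction targets. Published culture tables occasionally print
doubling times inconsistent with ln 2 / μ; only self-consistent rows serve
as worked examples in the tests.

# Clustering with AU support

Distances are 1 − Spearman ρ (average ranks for ties), so clustering sees
monotone co-regulation and is invariant to any increasing transform of a
gene's profile; constant genes are excluded with a warning. Whether to
cluster normalised counts or log-CPM is often left unstated in write-ups;
the pipeline defaults to log2(CPM + 1), configurable.

The tree is average linkage (UPGMA). Tie-breaking is deterministic and
documented (sorted labels, clusters indexed by lowest member, lowest (i, j)
pair first) because bootstrap reproducibility requires identical trees from
identical inputs; near-equal distances (equal in exact arithmetic,
differing in the last float bit between incremental and direct averaging)
are treated as ties for the same reason. The implementation is verified
against a from-scratch cross-pair-mean oracle and `stats::hclust`.

Bootstrap support resamples **samples** (columns) with replacement — the
observations over which correlations are computed — and scores each
observed internal node by the fraction of replicate trees containing the
identical leaf set (exact equality, no partial credit). The multiscale
bootstrap repeats this at resample sizes round(r · n) for
r = 0.5, 0.6, …, 1.4 (the conventional grid; minimum size 3) and fits, per
node, the scaling law

  qnorm(1 − BP~r~) = v·√r + c/√r

by weighted least squares (weights = binomial variance of the estimated
quantile via the delta method), reporting AU = 1 − Φ(v − c) with a standard
error from the fit covariance. The √r coefficient carries the
signed-distance signal — the bootstrap support of a real cluster *rises*
with the resample fraction — and the 1/√r coefficient the boundary-curvature
correction; this orientation reproduces the reference multiscale-bootstrap
implementation to four decimals on planted-module data. Genes constant
within a resample contribute ρ = 0 (distance 1) for that replicate. Nodes
with BP ∈ {0, 1} at every scale (or fewer than two scales strictly inside
(0, 1)) cannot be fit: they get AU = BP, SE = 0 and a degeneracy flag.

One structural consequence: the root node's leaf set is present in every
replicate tree at every scale, so the root is always degenerate with
AU = 1. Under the literal "maximal passing clusters" contract the root
therefore absorbs everything at any α ≤ 1; `significant_clusters()`
implements that contract (and α = 0 returns the root), but offers
`include_root = FALSE` — which the pipeline uses — for practical cluster
extraction.

# Regulator screening (Method 1)

Every gene in the transcriptome is scored against a seed functional cluster
by Σ~s∈seed~ ρ(g, s) (and Σ ρ², reported alongside: squared correlation
ranks strong anti-correlation with mixed-sign profiles). A self-regulated
transcription factor is expected to co-cluster with its targets, so the top
positive non-seed genes are regulator candidates and the most negative are
candidate repressors. Seed members are scored and *flagged* rather than
silently dropped, keeping the seed's internal coherence inspectable;
`|sum_rho| ≤ n_seed` with equality only for perfect monotone agreement.
Ranking ties break by gene id for determinism.

# Phenotype correlation (Method 2)

Per gene, both Spearman (monotone) and Pearson (linear) correlations against
each phenotype (growth rate, specific productivity). Significance uses the
adaptive band mean ± 2·SD of all non-missing per-gene correlations, clipped
to [−1, 1] — a published numeric threshold like 0.81 is the realisation of
this rule on one data set, never a constant to hard-code. Choices: the band
is computed separately per statistic and per phenotype (pooling across
phenotypes would let a strong phenotype inflate the other's threshold);
missing correlations are excluded, not imputed; sample SD (n − 1) is used —
at genome scale the difference from the population SD is negligible. Under
an i.i.d. Gaussian null the rule flags ≈ 4.6% of genes, which the tests
verify as 4–6%.

# Network overlay and complex enrichment (Method 3)

Nodes are coloured on a continuous blue–white–red gradient of log2FC
saturating at |log2FC| = 4, with ±2 as reference marks rather than clipping
points — reconciling the convention of colouring "by ±2-fold change" with
the need to show sub-fold coordinated shifts. Borders are thick exactly when
FDR < 0.05. Complex / functional-group nodes never carry expression colour.

Enrichment asks, per group and direction: are this group's members
over-represented among genes regulated in that direction? The 2×2 table is
{member, non-member} × {regulated-in-direction, not}, over the background of
network component nodes with a DE record (the "complete network" reading;
using all expressed genes instead would only make enrichment easier). The
default member criterion is sign(log2FC) matching the direction AND
FDR < 0.05, with **no fold-change magnitude condition** — a proteasome whose
subunits all shift −1.2-fold is the target signal — and `sign_only` is
available where DE significance is unavailable. The p-value is the
one-sided Fisher exact probability, computed directly as the hypergeometric
upper tail from log binomial coefficients and verified against both
brute-force enumeration and `stats::fisher.test`; one-sided because the
claim is enrichment of coordinated regulation. The negative logarithmic
transformation uses base 10. BH adjustment across the groups tested is
reported as `q` alongside raw p (raw p retained for comparability with
sources that report it alone).

# Synthetic data: the stated world

The generators exist so every method is testable offline, emulating the
statistical structure of the real inputs rather than their content:

* **Expression**: Gaussian latent-factor modules — gene g of module m is
  a~g~·f~m~ + ε with loadings in [0.8, 1.2], factor f~m~ ~ N(0, 1) per
  sample and noise sd 0.3 (≈ within-module ρ of 0.9, the coherence of a
  tightly co-regulated complex); background genes are independent N(0, 1);
  planted regulators are ±f~m~ plus noise sd 0.1. The demo world is 1000
  genes × 24 samples with four modules of 25 — sized like a subsystem-level
  analysis (a few hundred catalogue genes against a transcriptome-scale
  background) and running the full pipeline in minutes.
* **Counts**: per-gene baselines uniform on the log2 3–10 range, NB sampling
  with common dispersion 0.1 (a typical technical+biological BCV² for cell
  lines), library sizes uniform in 1–2 million.
* **Phenotypes**: a weighted combination of standardised planted-gene
  profiles plus noise; weights solve S·w = ρ (S = plant correlation matrix)
  and the noise variance is 1 − ρ′S⁻¹ρ, so population correlations equal the
  targets and incompatible targets are rejected rather than silently
  attenuated. Two independent genes cannot both carry |ρ| = 0.95 to one
  phenotype (feasibility bound 1/√2), so the demo plants one gene per
  phenotype (+0.95 to growth, −0.95 to productivity).
* **Toy reconstructions**: catalogues with requested complex/group
  structure, random interaction lists, and hit tables whose rows are drawn
  inside the acceptance regions of the requested tier (including pseudogene
  decoys with otherwise strong alignments, and partial flags).

Everything is deterministic under the mandatory seed (independent derived
streams per generator). What the generators do **not** emulate: batch
effects, count outliers, mean–variance trends, annotation errors, or the
long-tailed module-size distribution of real pathways — a green recovery
test establishes that the methods work under their own assumptions, not
that those assumptions hold for any particular data set.

# Numerical and degenerate-input policy

* BH: step-up with explicit monotonisation; NA p-values pass through.
* Fisher tail: log-space binomial coefficients; p capped at 1.
* UPGMA: near-ties (within 1e-12) resolved by the documented label order.
* Constant genes: excluded from distance matrices (warning), NA in
  correlation outputs, ρ = 0 within bootstrap resamples.
* Empty structures (empty networks, empty enrichment, header-only exports)
  round-trip losslessly.
* All file outputs are plain text (TSV / SIF / GraphML / Newick).

# Known limitations

* The bootstrap is over samples only; gene-level uncertainty (e.g. noisy
  ortholog assignment feeding the gene sets) is not propagated.
* AU support inherits the multiscale-bootstrap assumptions (smooth region
  boundaries); heavily tied data with tiny sample counts can leave many
  nodes degenerate.
* Enrichment treats genes as exchangeable; correlated members of a complex
  violate the independence behind the hypergeometric null, so q-values are
  best read comparatively.
* The pipeline's homology, expression and overlay stages are sequential and
  in-memory; genome-scale inputs fit comfortably, but nothing is chunked.
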