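---
title: "Methods: CIMP subtyping and core-hypermethylome discovery with cimpscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CIMP subtyping and core-hypermethylome discovery with cimpscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cimpscan` implements a genome-wide DNA-methylation analysis of matched
tumour/normal cohorts measured on 450K-style arrays, from raw
methylated/unmethylated intensities to CIMP (CpG island methylator
phenotype) subtypes, gene-level hypermethylation calls, and
frequency-based core-gene discovery. This vignette records the models,
the tunable parameters and their defaults, the numerical conventions,
and the design decisions taken where the procedure was genuinely open.

# Preprocessing model

Methylation at a CpG is summarised by the beta value
$\beta = M/(M+U+100)$, where $M$ and $U$ are the methylated and
unmethylated allele intensities. The offset of 100 stabilises the ratio
at low total intensity and bounds $\beta$ strictly below 1; it is
configurable (`offset`) but there is no reason to change it in normal
use.

Probe quality control removes, in order: control probes; probes whose
detection p-value exceeds `alpha` (default 0.05) in more than
`max_failure_fraction` of samples; X/Y-chromosome probes (sex
confounding in a mixed cohort); and probes flagged as cross-reactive.
The default `max_failure_fraction = 0` — remove a probe that fails in
*any* sample — is the strictest reading of a detection filter and is
deterministic; cohorts with many marginal samples may prefer a small
positive fraction. Each removed probe is attributed to the first rule
that caught it so the QC report's counts sum to the number removed, and
the filter is idempotent.

Per-sample intensity rescaling multiplies every intensity of sample $s$
by $f_s = \bar c / c_s$, where $c_s$ is the sample's mean internal
control intensity ($M+U$) and $\bar c$ the grand mean of the $c_s$.
Rescaling acts on intensities *before* beta computation; because the
offset is not rescaled, betas are not perfectly invariant under $f_s$ —
this is intentional and documented rather than hidden.

Batch (chip) effects are removed from the beta matrix with the ComBat
empirical-Bayes location–scale model (via the `sva` package): per-probe
standardisation, per-batch additive and multiplicative effect estimates
shrunk toward common priors, back-transformation, and clipping to
$[0,1)$. Two points matter in practice:

* the tissue factor should be passed as a protected covariate
  (`covariates = tissue`, as the pipeline does). Without it, ComBat
  treats the tumour–normal contrast as residual noise and we measured it
  compressing genuine per-gene deltas by up to ~30% when batches are
  unbalanced;
* batches confounded with biology cannot be fixed post hoc. The
  synthetic generator randomises chip membership for this reason; a real
  study should randomise its scan order.

With a single batch the function is the identity; a batch of size 1 is
an error because its variance is undefined.

# Differential methylation (SAM)

Per-probe differential methylation between the tumour and normal groups
uses the SAM relative difference $d_i = r_i/(s_i + s_0)$, with $r_i$ the
tumour-minus-normal mean difference, $s_i$ the pooled (or paired)
standard error, and the exchangeability factor $s_0$ damping probes
whose apparent significance rests on a tiny variance. The default $s_0$
follows the original SAM recipe: candidates are the 5%-step percentiles
of $s$ and the one minimising the coefficient of variation of the MAD of
$d$ across 100 $s$-quantile windows is chosen; `mode = "median"` is the
simpler fallback, and the value used is recorded in the pipeline
snapshot. The analysis runs unpaired by default (the groups are
contrasted as groups); a paired mode over matched differences is
provided since the cohort is matched.

The permutation FDR compares each observed $|d_i|$ threshold's observed
count against the mean count of permuted statistics at or above it, and
takes the minimum ratio over all thresholds at or below $|d_i|$,
monotonised and capped at 1. Permutations reassign labels (or flip signs
within pairs in paired mode) with a mandatory seed, 200 permutations by
default; when fewer distinct assignments exist than requested
permutations the enumeration is exhaustive and the estimate exact.
Threshold comparisons use a $10^{-9}$ relative tolerance so that
mirror-image assignments, which equal an observed statistic up to
floating-point noise, count as ties.

The `top_k` most differentially methylated probes by $|d|$ (two-sided —
hyper- and hypomethylation both inform subtype) feed the clustering;
ties break lexicographically by probe id for determinism. The default
`top_k = 2500` is sized to the synthetic cohort's ~2570 consistent-signal
(core) probes: a K much beyond that count lets probes from individual
tumours' stochastic backgrounds into the clustering space, where under
complete linkage a single background-heavy tumour can drift between
subclusters. On a real 450K cohort the conventional 20,000 is
appropriate and is a single configuration change.

# CIMP subtyping

Samples are clustered on the selected probes with Euclidean distance and
complete linkage. Published CIMP analyses cut the dendrogram visually;
`assign_cimp_labels()` fixes a reproducible surrogate:

1. cut the tree into two branches; the branch with the *lower* mean beta
   over the selected probes is normal-like;
2. tumours in the normal-like branch are CIMP-N (tumours
   indistinguishable from normal tissue); normals in the tumour-like
   branch are flagged and excluded downstream;
3. the tumour-like branch is cut into three subclusters by lowering the
   cut until its samples split in three, and the subclusters are ranked
   by decreasing mean beta: CIMP-H, CIMP-L, CIMP-N.

The ranking statistic (mean beta over selected probes) makes the label
order structural: CIMP-H $\ge$ CIMP-L $\ge$ CIMP-N by construction. A
tumour branch with fewer than three samples is an error rather than a
degenerate three-way split.

# Gene-level island calling

For each gene we pool its CpG-island and island-shore probes (shores are
within 2 kb of an island edge, shelves within 2–3 kb, open sea beyond;
1-based closed intervals, containment = distance 0). Genes with fewer
than `min_probes = 3` qualifying probes are excluded and reported — a
signed-rank test on fewer pairs is uninformative. Probes annotated to
several genes count for each of them; the array manifest does not give a
de-duplication rule and inventing one would silently drop signal.

Per (gene, tumour pair) the paired Wilcoxon signed-rank test is applied
to the per-probe beta differences: zero differences are dropped, tied
absolute differences receive average ranks, the exact null distribution
is used up to $n = 25$ non-zero differences (via the standard
signed-rank distribution for untied ranks, or an exact convolution over
doubled ranks when ties make the rank sum half-integral), and a normal
approximation with continuity and tie correction beyond. Two-sided
p-values are twice the smaller tail, capped at 1; exact p-values are
snapped to their $2^{-n}$ grid so they match direct enumeration
bit-for-bit.

P-values are Benjamini–Hochberg adjusted across genes *within each
tumour* by default (`adjust_scope = "per_tumour"`): each tumour's calls
feed an independent per-tumour count, so each tumour is its own family.
A `"global"` scope pooling all pairs is provided; both are recorded.

A gene is called **hyper**methylated in a pair when the adjusted p-value
is below `p_adj_max = 0.005` *and* the tumour-minus-normal mean beta
over its probes is at least `delta_min = 0.1`; hypomethylation uses the
mirrored criterion (downstream modules consume hyper calls only). The
delta threshold is not arbitrary: `scan_delta_threshold()` re-thresholds
the calls over a grid and selects the value maximising the difference in
mean per-tumour hyper counts between CIMP-H and CIMP-N tumours (ties to
the smallest delta). Only the delta criterion moves with the grid, so
the scan is cheap.

# Frequency scoring and core sets

Each gene is scored for the number and fraction of tumours in which it
was called hyper, per CIMP group and overall, with group sizes taken
after subtyping exclusions. A "core set" at threshold $t<1$ contains
genes hyper in *more than* a fraction $t$ of the group (strict, matching
the frequency-curve convention); at $t=1$ it is the genes hyper in
every tumour of the group. This boundary convention reconciles "more
than the specified percentage" with "in 100% of tumours" and makes the
sets nested in $t$.

# Clinical statistics

Association tests mirror standard clinical-table practice: Fisher's
exact test for binary variables, using the minimum-likelihood two-sided
definition (sum of hypergeometric probabilities no larger than the
observed table's; this is what published tables print, and the doubled
one-tail variant is available by flag), and Welch's unequal-variance
t-test computed from group means, SDs and sizes. Published tables often
*truncate* p-values to the printed decimals; `truncate_decimals()`
reproduces that convention for comparisons while full precision is kept
internally. The five-gene marker panel (CACNA1G, NEUROG1, RUNX3, SOCS1,
IGF2) classifies a tumour CIMP-H at $>3/5$ methylated markers, CIMP-L at
1–3/5, CIMP-N at 0/5, and `label_concordance()` reports per-class
agreement between clustering-derived and panel-derived labels.

# The synthetic cohort: what it emulates and what it does not

`generate_manifest()`/`generate_cohort()` produce a fully synthetic
matched cohort with known truth so every stage is testable without any
external download. Defaults define the package's reference study
conditions:

* **40 pairs**, split 35/15/50% into CIMP-H/L/N (mirroring the ~32/13/47
  of a ~90-pair clinical series), **2000 genes**, one island per gene
  with 12–18 island probes spaced 100 bp and 3–6 shore probes within
  2 kb, two shelf probes and one open-sea probe; 40 filler genes on
  chrX/chrY exercise the sex filter, ~1% of shelf/open-sea probes are
  flagged cross-reactive, and negative/internal control probes are
  appended.
* **A 132-gene core** hypermethylated in every CIMP-H tumour with
  per-gene effect $\Delta \sim N(0.35, 0.05)$ on the beta scale. Fifty
  of these are **pan-tumour** genes, hypermethylated in *every* tumour
  at 1.3$\times$ amplitude — the enlarged analogue of the handful of
  genes real cohorts show hypermethylated in >90% of all tumours. The
  remaining 82 core genes carry subtype amplitude multipliers
  **1 / 0.5 / 0.15** for CIMP-H/L/N.
* **Per-tumour stochastic background**: each tumour hypermethylates a
  log-normal number of additional non-core genes (group means 120/60/30,
  heavier tail in CIMP-N), at full amplitude. This reproduces the
  continuum of per-tumour counts with overlapping group ranges and no
  clean boundary.
* **Noise and technology**: a shared per-subject wobble (logit sd 0.08)
  and independent measurement noise (logit sd 0.10) are applied on the
  logit scale so betas stay in $(0,1)$ — additive beta noise would
  violate the bounds at the extremes. Betas convert to intensities via
  $M=\beta\,(T+100)$, $U=T-M$ with lognormal per-probe and per-sample
  total-intensity variation around $T=5000$, so `compute_beta()` inverts
  the construction exactly. Pairs share a chip (6 pairs per chip, chip
  membership randomised), with per-chip per-probe additive shifts
  (sd 0.02) for ComBat to remove; ~1% of probes carry detection
  failures. Marker-panel labels are drawn from a subtype-conditional
  misclassification table patterned on published panel-vs-clustering
  concordance, so the concordance module has realistic input.

Several defaults are coupled, deliberately:

* **Probe counts vs the signed-rank floor.** The exact signed-rank
  p-value over $n$ untied differences cannot go below $2^{1-n}$. With
  per-tumour BH across ~2000 genes and 130–260 significant genes per
  tumour, a gene needs $\ge$ 12–13 island+shore probes for its floor to
  clear an adjusted 0.005. Islands get 12–18 + 3–6 shore probes so that
  even after worst-case QC attrition a planted gene keeps $\ge$ 13 —
  otherwise perfect recall of the core would be arithmetically
  impossible, a discreteness effect worth knowing about on real data
  with small islands.
* **The CIMP-N multiplier 0.15 makes the delta scan peak at 0.1.** It
  places CIMP-N core deltas near 0.05: a 0.05 calling threshold admits
  those low-amplitude events in CIMP-N and shrinks the H–N separation,
  while thresholds of 0.1 and above exclude them and (up to ~0.25) cost
  nothing in CIMP-H, so 0.1 is the smallest maximiser — the synthetic
  analogue of selecting 0.1 as the most discriminating threshold.
* **Pan-tumour amplitude anchors the dendrogram.** Under complete
  linkage the normal branch must detach last, which requires the
  pan-tumour separation (shared by all tumours, CIMP-N included) to
  exceed the largest within-tumour-branch separation (CIMP-H vs CIMP-N
  on the graded core). The 50-gene pan set at 1.3$\times$ amplitude
  gives that inequality a ~40% margin.

What the generator does **not** emulate: Infinium I/II chemistry and
dye bias, copy-number or purity confounding, probe SNP artefacts,
spatially correlated (region-growing) methylation drift, and — by
design — tumour hypomethylation: all planted effects are gains, so
feature-fraction summaries of hypomethylated probe sets are exercised
on constructed inputs in the tests rather than on the cohort. Passing
the recovery tests therefore shows the pipeline's logic is correct
under the stated statistical structure, not that it is robust to every
artefact of real arrays.

# Problem sizes and determinism

The reference cohort (40 pairs, ~45,000 probes, 2000 genes, 200 SAM
permutations) runs end-to-end in about a minute on one CPU; the test
suite's exhaustive oracles (full $2^n$ sign enumerations, all 20
assignments of a 3v3 cohort, $O(n^3)$ linkage recomputation) are sized
to seconds. Every stochastic stage takes an explicit seed, and
`run_pipeline()` with a fixed configuration is bit-reproducible,
including the permutation FDR and the report bundle.

# Known limitations

* The dendrogram cut rule is a reproducible surrogate; it will not
  reproduce a visual cut on pathological tree shapes (e.g. a tumour
  branch whose first two splits isolate outlier samples).
* Per-tumour BH treats genes as exchangeable within a tumour; genes
  sharing probes (multi-gene annotations) are not independent.
* The signed-rank discreteness floor (above) means genes with few
  probes can never reach stringent adjusted thresholds; such genes are
  excluded by `min_probes` rather than silently reported as negative.
* ComBat on bounded beta values is used as published practice dictates;
  a logit-scale mode would avoid edge clipping but is deliberately off
  by default to match the common workflow.
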