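---
title: "Validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR reports a target gene's expression relative to reference genes
assumed constant across every sample and condition. When the biological
perturbation under study is strong — for example, a peripheral nerve
injury that remodels gene expression in sensory ganglia and spinal dorsal
horn over weeks — that assumption is exactly what must be tested. The
geNorm framework does so by exploiting a simple observation: the
expression *ratio* of two genuinely stable genes is the same in every
sample, whatever the biology does. Departure from a constant ratio is
therefore evidence of instability in at least one member of the pair.

## Model and statistics

**Relative quantities.** Cq is (minus) log expression in base (1 + *E*),
where *E* is the gene's fractional amplification efficiency. Each gene's
wells are rescaled to the gene's minimum observed Cq (its
highest-expressing well acts as internal control) and linearized as
RQ = (1 + *E*)^(Cq~min~ − Cq); technical replicates are then averaged
arithmetically on the RQ scale, in that order. Averaging Cq first instead
(a geometric mean on the linear scale) is available via
`relative_quantities(average = "cq")` but off by default. The anchor is
the per-gene minimum *well* Cq rather than the minimum sample mean; both
choices cancel from every ratio-based statistic downstream and only set
the reported RQ scale, on which the maximum RQ of each gene is 1 when the
minimum well sits in the minimum-mean sample.

**Pairwise variation and M.** For genes *j*, *k*, V(*j*, *k*) is the
sample standard deviation (n − 1 denominator) across samples of
log2(RQ~j~/RQ~k~). The M-value of *j* is the mean of V(*j*, *k*) over all
other candidates; in a two-gene panel both genes share the single V, which
is why a stepwise ranking must end at an undiscriminated pair. Log base 2
is the geNorm convention; the base uniformly scales every M, so it is
fixed so that published M-values remain comparable. The implementation
evaluates V through the covariance identity
sd(x − y)² = var(x) + var(y) − 2 cov(x, y) on the log2 matrix; the test
suite checks it to 1e-12 against literal double loops.

**CV.** The coefficient of variation, σ/μ of a gene's RQs, gates on a
different failure mode than M: per-sample scaling (RNA input, RT yield)
cancels in every ratio, so M is blind to it, while the CV is not. A gene
can pass M and still fail CV. The CV is computed on raw relative
quantities, not on normalized ones; `classify_stability()` applies both
gates and a gene is validated only if both pass.

**Cut-offs.** Heterogeneous panels (distinct conditions pooled, the
default) use M < 1.0 and CV < 0.50; homogeneous panels use 0.5 and 0.25.
Comparisons are strict: a gene at exactly the cut-off fails. This is the
conservative reading of boundary cases and makes the pass sets open.

**Ranking.** `rank_genes()` recomputes M on the remaining set, removes the
argmax, and records the step. Exact ties are broken by eliminating the
lexicographically last gene label and flagging the tie in the trace; any
deterministic rule would do, since real data essentially never ties, but
determinism makes traces byte-reproducible. The trace's `full_order`
stores genes most-stable-first — the tied final pair, then reverse
elimination order — because that is the inclusion order the normalization
factor needs.

**Number of reference genes.** NF~n~ is the per-sample geometric mean of
the *n* most stable genes' RQs; V(n, n+1) = sd across samples of
log2(NF~n~/NF~n+1~), for n = 2 … G − 1. The smallest *n* with
V < 0.15 is recommended; if none passes, all G genes are recommended.
`worst_pair_check()` repeats the construction from the *least* stable end
of the validated set, as a sensitivity check that even the worst validated
pair normalizes acceptably. With exactly two validated genes there is no
third to add, so the pairwise variation of the two genes themselves is
reported instead — a deliberate fallback, documented here because the
NF-based construction is undefined there.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_cq` | 30 | cycles | late amplification is unreliable (primer dimers, stochastic template counts) |
| `max_replicate_spread` | 0.5 | cycles | triplicate wells of a clean reaction agree within a fraction of a cycle; the replicate-outlier rule (iterative farthest-from-median removal) is this package's deterministic formalisation of "exclude doubtful curves" |
| `cutoff_policy()` | M < 1, CV < 0.5 | — | heterogeneous-panel conventions; 0.5/0.25 for homogeneous panels |
| `v_threshold` | 0.15 | log2 units | conventional acceptance level for V(n, n+1) |
| `sd_type` | `"sample"` | — | n − 1 denominator, matching the original geNorm implementation; `"population"` available for sensitivity checks |

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 7 candidate
genes (18S, RPL29, RPL13a, Actb, HPRT1, HMBS, GAPDH) with amplification
efficiencies between 0.70 and 0.89, seven condition groups (naive plus
post-surgery days 2–21) of 3 animals each, triplicate wells. Noise is
additive on the Cq (log-expression) scale, the standard qPCR error model,
with three components: per-well technical noise (SD 0.1 cycles, small
enough that clean triplicates pass the 0.5-cycle spread filter),
per-gene biological noise (SD 0.2 cycles), and a per-animal
sample-content shift common to all genes (SD 0.15 cycles), standing in
for RNA-input and RT-yield variation. These magnitudes are plausible
values for well-run assays, chosen once; the true variance components of
any particular instrument run are unknown. Condition effects are fixed
per-condition Cq shifts; `unstable_gene_effects()` ramps one gene
linearly from 0 to a peak (default 1.5 cycles), emulating progressive
regulation after injury. Baseline Cq values sit in the 10–25 range so
stable genes never trip the Cq ≤ 30 gate.

Not emulated: amplification curves and melting profiles (only Cq-level
data), inter-run calibration (the emulated design runs all samples of a
gene on one plate, making run effects gene-constant and cancelling them
in ratios), PCR inhibition, and correlated regulation of several genes.
Consequently, passing the simulation-based tests shows the *statistics
and decision rules* behave correctly under the stated error model — it
does not certify any particular wet-lab dataset, and real data with
co-regulated candidates would violate the independence the M-statistic
implicitly leans on.

## Numerical choices and degenerate inputs

* The covariance-identity route can produce tiny negative squared SDs
  from round-off; these are clamped to zero before the square root.
* Zero-variance inputs are legal: constant panels give exactly M = 0 and
  CV = 0 (verified in the tests), and noiseless dilution series fit with
  R² = 1 computed from residual sums of squares directly.
* Efficiency files auto-detect percent versus fraction at a threshold of
  1.5, since no plausible fractional efficiency exceeds 1.1 and no
  plausible percentage is below 50; estimated efficiencies slightly above
  1 (regression noise) are tolerated up to 1.1.
* Samples missing any gene after QC are dropped with a warning (or an
  error, by option): the pairwise statistics need a complete
  gene × sample matrix. A (sample, gene) group emptied by the Cq gate is
  an error naming the group, because silent loss of a measured pair would
  bias the panel.
* Dilution-series fits require ≥ 3 distinct dilutions and a negative
  slope (Cq must increase with dilution); ranking requires ≥ 3 genes and
  the V-series ≥ 3 genes and 2 samples.
* Report serialisation uses 6 significant digits, which the tests show
  preserves every pass/fail decision.

## Problem sizes used in the checks

The packaged checks run the study-shaped design (441 wells) across 100
simulation seeds for the two parameter-recovery properties, 50 random
matrices up to 8 genes × 25 samples for oracle equivalence, and 100
seeds for noisy efficiency recovery; the whole suite and the acceptance
script each complete in well under a minute on a single core.

## Known limitations

* M-value stability is relative to the panel: if most candidates co-vary,
  a truly unstable gene can look stable. Choosing candidates from
  unrelated pathways is the practitioner's responsibility.
* The CV gate assumes standardized sample processing; content shifts
  inflate every gene's CV and can reject genes for non-biological
  reasons.
* Per-condition ranking (one trace per timepoint) is available by
  subsetting the Cq table on its condition labels, but no acceptance
  anchors exist for it and the pooled panel is the primary analysis.
* No inter-plate calibrator handling and no absolute quantification.
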