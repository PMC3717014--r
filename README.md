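# refstab

Reference-gene stability validation for RT-qPCR.

Relative quantification by RT-qPCR stands or falls with its normalization:
target-gene expression is reported relative to one or more *reference*
("housekeeping") genes whose expression is assumed constant across all
samples and conditions. That assumption must be demonstrated, not assumed —
a reference gene that itself responds to the experimental condition biases
every downstream fold change. `refstab` implements the standard
geNorm-style validation workflow for a panel of candidate reference genes:

1. **Quality filtering** of well-level quantification-cycle (Cq) data: a
   Cq cap (default 30 cycles) and iterative removal of technical
   replicates whose spread exceeds a tolerance (default 0.5 cycles).
2. **Efficiency-corrected relative quantities.** For gene *g* with
   fractional amplification efficiency *E<sub>g</sub>*, each well's Cq is
   rescaled to the gene's lowest observed Cq (the internal control) and
   linearized:

   RQ = (1 + *E<sub>g</sub>*)^(Cq<sub>min</sub> − Cq),

   then technical replicates are averaged arithmetically. Efficiencies can
   be supplied per gene or estimated from serial-dilution curves
   (*E* = 10^(−1/slope) − 1).
3. **Stability statistics.** The geNorm M-value of gene *j* is the mean
   over the other candidates *k* of the standard deviation across samples
   of log2(RQ<sub>j</sub>/RQ<sub>k</sub>); the coefficient of variation is
   σ/μ of a gene's relative quantities. For a heterogeneous panel, genes
   with M < 1 and CV < 50% are validated (strict inequalities).
4. **Stepwise ranking.** The highest-M gene is eliminated and M recomputed,
   until two undiscriminable genes remain (tied best pair).
5. **How many reference genes?** With NF<sub>n</sub> the per-sample
   geometric mean of the *n* most stable genes' RQs, the pairwise variation
   V(n, n+1) = SD across samples of log2(NF<sub>n</sub>/NF<sub>n+1</sub>)
   is computed for increasing *n*; V < 0.15 means the added gene is not
   needed. A worst-validated-pair sensitivity check is also reported.

A seeded simulator (`simulate_cq()`) generates Cq datasets shaped like a
multi-timepoint nerve-injury study — 7 candidate genes, 7 condition groups
(naive plus 6 post-surgery timepoints) × 3 animals, triplicate wells, with
controllable technical/biological noise, per-animal content shifts, and
injectable condition-dependent instability — so the whole pipeline can be
exercised and power-checked without instrument data.

## Worked example

Simulate a study-shaped dataset in which GAPDH is given a progressive
condition effect ramping to 1.5 cycles, then validate the panel:

```r
library(refstab)
cfg <- sim_config()
sim <- simulate_cq(sim_config(condition_effects =
         unstable_gene_effects(cfg, "GAPDH", 1.5)), seed = 42)
fit <- ref_stability(sim$cq, sim$efficiencies)
fit
#> Reference-gene stability analysis
#>   7 gene(s) x 21 sample(s); heterogeneous panel (M < 1, CV < 50%)
#>    gene m_value    cv passes_m passes_cv validated
#>   HPRT1   0.283 0.142     TRUE      TRUE      TRUE
#>    HMBS   0.297 0.153     TRUE      TRUE      TRUE
#>  RPL13a   0.312 0.165     TRUE      TRUE      TRUE
#>     18S   0.313 0.116     TRUE      TRUE      TRUE
#>    Actb   0.315 0.170     TRUE      TRUE      TRUE
#>   RPL29   0.316 0.174     TRUE      TRUE      TRUE
#>   GAPDH   0.539 0.378     TRUE      TRUE      TRUE
#>   most stable pair: 18S, HMBS (tied)
#>   recommended number of reference genes: 2 (V threshold 0.15)
```

The destabilised gene is clearly the least stable (highest M, largest CV)
and is the first eliminated in the stepwise ranking, although at this
effect size it still clears the heterogeneous-panel gates. The V-series
shows a pair of stable genes suffices:

```r
fit$v_series
#> Pairwise variation V(n, n+1), threshold 0.15:
#>  n          v below_threshold
#>  2 0.06719153            TRUE
#>  3 0.05389757            TRUE
#>  4 0.04368138            TRUE
#>  5 0.03902155            TRUE
#>  6 0.07325954            TRUE
#> recommended number of reference genes: 2
```

`coef(fit)` returns the per-gene M and CV, `predict(fit)` the per-sample
normalization factors from the recommended gene set, and `plot(fit)` draws
the M, CV and V bar charts. `run_analyze()` writes the full delimited
report set (stability report, ranking trace, V series, QC log, summary),
and `inst/scripts/refstab` wraps analyze/simulate/efficiency as shell
subcommands.

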