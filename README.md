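# erenorm

Discovery and validation of **expressed repetitive elements (EREs)** as
reference targets for RT-qPCR normalization, with the full validation
pipeline — geNorm stability analysis, cross-experiment rank aggregation,
and normalization-bias comparison — implemented over synthetic data
generators with recorded ground truth.

## Why

Normalizing qPCR data against reference genes that are themselves regulated
silently rescales every fold change. Because one ERE primer pair amplifies
a repeat family present in the 3'UTRs of hundreds of transcripts, its
signal tracks the overall mRNA fraction and is far harder to perturb than
any single gene. This package provides the computational machinery to find
such targets in sequence data and to demonstrate, quantitatively, when they
outperform classic reference genes.

The core statistics, in the field's standard notation:

* **Relative quantity**: `Q[s,t] = F_t^(min_s' Cq[s',t] - Cq[s,t])`, with the
  amplification factor `F_t = 10^(-1/slope)` estimated from a standard
  dilution series.
* **geNorm**: pairwise variation `V_jk = sd_s(log2(Q[s,j]/Q[s,k]))`,
  stability `M_j = mean_{k≠j} V_jk`, ranking by stepwise exclusion of the
  argmax-M target, and `V(n/n+1) = sd_s(log2(NF_n/NF_{n+1}))` with a 0.15
  cutoff to choose the number of references (NF = geometric mean of the top
  n targets).
* **Rank aggregation**: consensus ordering minimising the weighted Spearman
  footrule `Φ(δ) = Σ_i Σ_t w̃_i(t)·|r_δ(t) - r_Li(t)|` by Borda count and by
  a cross-entropy Monte Carlo optimiser (never worse than Borda; verified
  against exhaustive search on small universes).
* **Discovery filters**: > 100 genomic copies, > 30 transcript hits,
  > 85 % mean conservation, with a self-contained k-mer seeded ungapped
  aligner and a conserved-region (primer template) finder.
* **Bias law**: on clean data,
  `FC_measured = FC_true(goi) / geomean_refs(FC_true(ref))` — the exact
  price of an unstable reference set.

## Worked example

The packaged demo chains every stage on a six-experiment emulation of a
zebrafish validation study (developmental time series, adult organs, two
morpholino and two compound treatments; 20-target panel of 10 EREs and 10
classic reference genes):

```r
library(erenorm)
res <- run_demo(seed = 1)

res$stability_test$summary
#>     group  n  median_M     iqr_M       sd_M
#> 1     ERE 60 0.1922035 0.1322376 0.09943414
#> 2 classic 60 0.3778281 0.2427443 0.30012980

head(res$consensus$consensus)
#> [1] "dna15ta1" "loopern4" "hatn10"   "dna11ta1" "cr1-1"    "tc1n1"

res$fold_changes[1:2, ]
#>    experiment   goi reference_set group_a group_b fold_change
#> 1 time_series zorba           ERE    t000    t008   19.353225
#> 2 time_series zorba       classic    t000    t008    2.213435
```

Reading this: the ERE family has the lower median M (0.19 vs 0.38 across
the six experiments, location p ≈ 1e-08) and the tighter spread (SD 0.10
vs 0.30, spread p ≈ 3e-04); the consensus ranking puts EREs in the top
positions; and the maternal `zorba`-like gene of interest, designed with a
true 20-fold drop after the first time point, is measured near 19-fold
under ERE normalization but shrinks to an apparent ~2-fold under the
classic reference set, whose members are themselves maternally elevated.
Every experiment's `V(2/3)` falls below 0.15, so two references suffice
throughout.

The same pipeline is laid out as a readable sequence of drivers under
`analysis/` (`01_simulate.R` … `06_compare.R`), each writing its tables
under `results/`:

```sh
Rscript analysis/01_simulate.R   # Cq datasets, dilution series, sequences
Rscript analysis/02_quantify.R   # efficiencies + relative quantities
Rscript analysis/03_stability.R  # geNorm ranking + V curves per experiment
Rscript analysis/04_aggregate.R  # Borda + cross-entropy consensus
Rscript analysis/05_discovery.R  # candidate-ERE filters on the sequence set
Rscript analysis/06_compare.R    # family comparison, fold changes, report
```

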