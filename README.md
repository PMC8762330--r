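# poolburden

Gene-based rare-variant association testing for **pooled DNA sequencing**.

When DNA from many individuals (here, pools of 12) is sequenced as one
library, individual genotypes are never observed: a pooled caller reports,
per variant and pool, the maximum-likelihood alternative-allele count
(**MLAC**, an integer in `[0, 2 × pool size]`). `poolburden` is for studies
that ask whether rare and low-frequency functional variants in a gene are
collectively associated with case/control status in that setting — the pool,
not the person, is the statistical unit. It provides:

* **Call-level QC** — strict phred-QUAL filtering (`> 100` by default),
  zeroing of single-pool ALT fractions below an empirically determined noise
  threshold (2.6% default), binomial maximum-likelihood MLAC estimation, and
  folded cohort MAF estimation from summed pool counts.
* **Seven qualifying-variant filters** — disruptive (stop-gain / stop-loss /
  splice-site, no frequency cutoff), missense+disruptive and
  damaging-consensus versions at MAF < 1% and < 5%, a synonymous-inclusive
  filter, and a regulatory filter for flagged non-coding variants
  (MAF < 1%). Damaging consensus = at least 2 of 6 predictors (SIFT,
  PolyPhen2, MutationTaster, MutationAssessor, LRT, FATHMM).
* **Pool-adapted gene tests** — a weighted-sum (WSS) burden statistic with
  control-estimated Madsen–Browning weights `w_j = sqrt(n q_j (1 - q_j))`,
  `q_j = (m_j^U + 1) / (2 n^U + 2)`, scored as the case-pool rank sum of
  pool scores `γ_p = Σ_j c_pj / w_j`; the C-alpha variance-component
  statistic `T = Σ_j [(y_j − n_j p0)² − n_j p0 (1 − p0)]`; and a hybrid
  Fisher combination `F = −ln p_WSS − ln p_Cα` whose null comes from **one
  shared set** of pool-label permutations, preserving the correlation
  between the two tests. P-values use the add-one estimator
  `(1 + #{T_b ≥ T_obs}) / (B + 1)` (floor `1/10001` at the default
  `B = 10000`), with automatic exact enumeration when the assignment space
  is small.
* **Meta-analysis** — fixed-effect inverse-variance pooling of per-cohort
  log odds ratios (Haldane 0.5 correction on zero cells) and random-effect
  (DerSimonian–Laird) pooling of Hedges' g standardized mean differences.
* **A synthetic-data generator** — genotypes under null / unidirectional /
  bidirectional / neutral-mix architectures, logistic liability with tuned
  prevalence, pooling, negative-binomial depth, read-level error and MLAC
  calling, with full ground truth for calibration and power studies.

Everything is tidyverse-shaped: functions take a data frame first, return
tibbles, and chain with the pipe; meta-analysis objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(poolburden)

fx <- make_fixture("discovery_disr_structure") # 49 case + 34 control pools of 12
qc <- run_qc(fx$variants, fx$design, analysis_config())
filter_summary(qc$variants, c("Disr", "MisDisr_01", "MisDisr_05"))
#>       filter n_snvs n_eligible_genes n_snvs_in_eligible_genes
#> 1       Disr     17                1                        8
#> 2 MisDisr_01     32               10                       32
#> 3 MisDisr_05     36               10                       36

run_gene_tests(qc$variants, fx$design,
  analysis_config(n_permutations = 10000, rng_seed = 1), filters = "Disr")
#>     gene filter n_snvs stat_wss     p_wss stat_calpha  p_calpha stat_hybrid
#> 1 GENE01   Disr      8     1976 0.8422158   -28.53912 0.5734427   0.7278164
#>    p_hybrid n_permutations      seed degenerate significant
#> 1 0.8306169          10000 536522583      FALSE       FALSE
```

Reading the output: the disruptive filter keeps 17 SNVs of which 8 land in
one gene with at least two qualifying variants, so exactly one (gene, filter)
pair is testable. For that gene, `stat_wss` is the case-pool rank sum (49
pools ranked among 83; its all-tie expectation is `49 × 84 / 2 = 2058`),
`stat_calpha` the overdispersion statistic, and the three p-values come from
10,000 shared pool-label permutations — this fixture's counts are drawn under
the null, so none is significant, as expected.

For a real analysis the entry points are `read_pool_design()`,
`read_variant_table()` (TSV dialects documented in the function help),
`run_qc()`, and `run_gene_tests()`; a thin CLI with the same stages is in
`exec/poolburden` (`filter`, `test`, `meta`, `simulate` subcommands). The
methods vignette (`vignettes/pooled-rare-variant-burden.Rmd`) derives the
statistics and records every numerical convention.

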