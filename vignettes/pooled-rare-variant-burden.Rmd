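---
title: "Gene-based rare-variant testing on pooled sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based rare-variant testing on pooled sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolburden)
```

## The setting

Pooled DNA sequencing mixes equimolar DNA from many individuals (here, pools
of 12) and sequences the mixture. Individual genotypes are unobservable; what
a pooled caller reports per variant and pool is a maximum-likelihood estimate
of the alternative-allele count, the **MLAC**, an integer between 0 and twice
the pool size. `poolburden` tests whether rare and low-frequency variants in a
gene are collectively associated with case/control status when the data
arrive in this aggregated form, and the pool — not the individual — is the
statistical unit.

The pipeline has four stages, each usable on its own:

1. **Call-level QC** (`run_qc()`): keep calls with phred quality strictly
   above `qual_min` (default 100); set to zero any single-pool ALT allele
   fraction strictly below an empirically determined noise threshold (default
   2.6%; a replication cohort sequenced on different chemistry would use its
   own, e.g. 2.4%); estimate the per-variant cohort minor-allele frequency
   from summed MLACs over total pooled chromosomes, folded to ≤ 0.5.
2. **Qualifying variants** (`apply_variant_filter()`): seven filters combine
   functional class, a damaging consensus over six in-silico predictors,
   regulatory-overlap flags, and strict MAF cutoffs at 1% and 5%.
3. **Gene-based tests** (`hybrid_test()`, `run_gene_tests()`): a pool-adapted
   weighted-sum burden statistic and the C-alpha variance-component
   statistic, each with a pool-label permutation null, combined by Fisher's
   statistic on a shared permutation set.
4. **Meta-analysis** (`fixed_effect_meta()`, `random_effect_smd_meta()`):
   fixed-effect inverse-variance pooling of per-cohort log odds ratios, and
   random-effect pooling of standardized mean differences for expression
   comparisons.

## The statistics

### Pool-adapted weighted-sum (WSS) burden statistic

Let $c_{pj}$ be the MLAC of variant $j$ in pool $p$, $n$ the total number of
individuals, and $n^U$, $m^U_j$ the number of control individuals and the
summed control-pool MLAC of variant $j$. Each variant is weighted by its
estimated frequency in controls, up-weighting the rarest:

$$q_j = \frac{m^U_j + 1}{2 n^U + 2}, \qquad
  w_j = \sqrt{n \, q_j (1 - q_j)}.$$

Each pool scores $\gamma_p = \sum_j c_{pj} / w_j$, and the statistic is the
sum of the case pools' ranks among all pool scores (average ranks on ties).
With pools of one individual and MLAC equal to genotype this reduces exactly
to the classical individual-level weighted-sum rank statistic, and the test
suite asserts that reduction against an independent reference implementation.
Large values indicate an excess of (rare-weighted) minor alleles in case
pools, so the test is one-sided upper. It is powerful when the associated
variants push in one direction.

### C-alpha variance-component statistic

With $p_0$ the proportion of case chromosomes, $n_j$ the total observed
copies of variant $j$ and $y_j$ the copies in case pools,

$$T = \sum_j \left[ (y_j - n_j p_0)^2 - n_j p_0 (1 - p_0) \right].$$

Each term compares the observed case/control split of a variant's copies with
its binomial expectation; risk and protective variants both inflate $T$, so
the test detects mixed-direction (bidirectional) architectures that wash out
of a burden statistic. Variants with $n_j = 0$ contribute nothing. The test
is one-sided upper on $T$.

### Permutation inference

Both statistics get their null from random reassignments of the case/control
labels to pools, preserving the number of case and control pools — the only
exchangeability the pooled design supports. The Monte-Carlo p-value uses the
add-one estimator

$$p = \frac{1 + \#\{b : T_b \ge T_{\mathrm{obs}}\}}{B + 1},$$

so no p-value is ever 0 and the attainable floor is $1/(B+1)$ ($1/10001$ at
the default $B = 10{,}000$). Ties count as exceedances, the conservative
convention. WSS weights are recomputed inside every permutation, because
relabelling changes the control set; a fixed-weight approximation would be
cheaper but biased, and is deliberately not offered as a default (or at all).
When the number of distinct label assignments is at most $B$ the engine
switches to exhaustive enumeration and reports the exact proportion instead
(the observed labelling is one of the enumerated assignments, so the
p-value is again positive).

### The hybrid (Fisher-combined) test

Genes differ in architecture, so neither component test dominates. The hybrid
statistic is

$$F = -\ln p_{\mathrm{WSS}} - \ln p_{C\alpha},$$

with both p-values computed from **one shared set** of pool-label
permutations. Because the two tests are correlated on the same data, $F$ has
no $\chi^2_4$ null; instead each permutation $b$ is assigned component
p-values by ranking its statistics within the same shared null
(self-inclusive, add-one convention), yielding null draws $F_b$ with the same
dependence structure as $F_{\mathrm{obs}}$, and
$p_{\mathrm{hybrid}} = (1 + \#\{F_b \ge F_{\mathrm{obs}}\})/(B+1)$. The
logarithms are natural; any monotone variant of $F$ gives identical
permutation p-values, so the choice only pins down the reported statistic
values.

### Two open choices, decided

The component tests are one-sided upper under permutation (case excess burden
for WSS, overdispersion for C-alpha), following the original formulations of
both tests; a two-sided C-alpha would halve sensitivity to the overdispersion
alternative the test exists for. The WSS statistic is the plain case rank
sum, not a standardized version: under permutation any location/scale
standardization is a monotone transform with the same p-value.

## Qualifying-variant filters

| Filter | Classes | MAF cutoff | Extra condition |
|---|---|---|---|
| `Disr` | stop-gain, stop-loss, splice-site | none | — |
| `MisDisr_01` | missense + disruptive | < 1% | — |
| `MisDisr_05` | missense + disruptive | < 5% | — |
| `DamDisr_01` | missense + disruptive | < 1% | damaging consensus |
| `DamDisr_05` | missense + disruptive | < 5% | damaging consensus |
| `SynMisDisr_01` | synonymous + missense + disruptive | < 1% | — |
| `Reg_01` | intronic, UTR3/5, up/downstream | < 1% | regulatory flag |

A missense variant reaches damaging consensus when at least two of six
predictors call it damaging (SIFT `D`; PolyPhen2 `D`/`P`; MutationTaster
`D`/`A`; MutationAssessor `M`/`H`; LRT `D`; FATHMM `D`); missing predictor
calls count as benign. MAF comparisons are strict (`< 0.01`, `< 0.05`),
matching the cutoffs' definitions, and inside the capped filters disruptive
variants must meet the cutoff too — only `Disr` is frequency-free, which is
appropriate when disruptive calls are so scarce that a frequency gate would
empty the filter. A gene is testable under a filter when it harbours at least
`min_snvs_per_gene` (default 2) qualifying SNVs after de-duplication by
`(chrom, pos, ref, alt)`.

Two conventions worth stating. First, a variant carries exactly one
functional class; when annotation sources disagree, upstream annotation
should resolve by severity (stop-gain > stop-loss > splice-site > missense >
synonymous > non-coding) before the table enters this package — annotation is
an input here, not something the package recomputes. Second, the "within 1 kb
of the transcript" condition of `Reg_01` is carried by the
`upstream`/`downstream` class tokens, not recomputed from coordinates, for
the same reason.

## Numerical and degenerate-input choices

* **QUAL and noise boundaries are strict** in opposite directions: a call at
  exactly `qual_min` is removed; a pool fraction at exactly the noise
  threshold is kept. The noise rule zeroes fractions *strictly below* the
  threshold so that a true singleton heterozygote in a 12-individual pool
  (expected fraction $1/24 \approx 4.2\%$) can never be erased by a 2.4–2.6%
  threshold.
* **Noise zeroing acts per pool-call**, not per variant; dropping whole
  variants whose every positive call is sub-threshold is a different policy
  a user can emulate by filtering on the QC MAF afterwards.
* **MLAC ties break toward the smaller count** — conservative against false
  positives on boundary read counts.
* **Missing pool calls** (absent or zero depth) are distinguished from
  observed zeros in the table (`.` on disk, `NA` in memory); the tests treat
  them as 0 copies, and `missingness_report()` quantifies how much data that
  convention hides. No imputation is attempted.
* **All-zero count matrices** are still well-defined (every pool score ties;
  the WSS statistic equals its expectation and all p-values are 1) and are
  flagged `degenerate` in the results.
* **Per-gene seeds** derive from the run seed and the `(filter, gene)` key by
  a deterministic string hash, so results are bitwise reproducible and
  independent of gene processing order.
* **Frequencies fold to the minor allele** over cases + controls combined by
  default; a `maf_subset = "controls"` switch estimates them in controls
  only.

## What the generator emulates — and what it does not

`sim_scenario()` + `simulate_pooled_study()` produce a full synthetic study:
true MAFs from a rare-skewed Beta (defaults `Beta(0.5, 99.5)`, mean 0.005);
Hardy–Weinberg genotypes; case/control status from a logistic liability model
$\mathrm{logit}\,P(\text{case}) = \beta_0 + \sum_j \beta_j g_j$ with
$\beta_0$ tuned to a prevalence of 0.001 (a generator convention, not a
disease claim); phenotype-homogeneous pools of 12; per-(pool, variant) depth
from a negative binomial with mean 360 and size 8 (the size is a knob — only
the mean and range of real depth distributions are typically reported, and
size 8 reproduces a plausibly wide range around a 360x mean); ALT reads
binomial with symmetric per-read error 0.5%; and MLACs called by the same
binomial maximum-likelihood rule the QC module uses. Architectures set the
sign pattern of $\beta$: `null` (all zero), `unidirectional` (all $+\beta$),
`bidirectional` (alternating $\pm\beta$), `neutral_mix` (half zero), with
magnitude `log(3)` by default.

Case and control genotype vectors are sampled *exactly* from the conditional
distributions $P(g \mid \text{case})$ and $P(g \mid \text{control})$ implied
by the liability model, using an exponentially tilted proposal with an exact
accept step (acceptance probability $1/(1+e^{x})$ with
$x = \beta_0 + \beta^\top g$, which is $\approx 1$ at rare prevalence). This
is distributionally identical to prospectively simulating a population and
keeping sampled cases and controls until the quotas fill, but costs a few
hundred draws per cohort instead of hundreds of thousands at prevalence
0.001.

The generator deliberately omits linkage disequilibrium between variants,
population structure, allele-specific or strand-biased sequencing error, and
read-level artefacts (no FASTQ/BAM is produced — the emulation target is the
MLAC contract, nothing deeper in the caller). Passing calibration and power
checks on this generator therefore demonstrates that the *statistical
machinery* is correct and well-calibrated under the stated sampling model; it
does not certify behaviour under stratification or correlated variants,
which real studies must address upstream (the study design this package
targets matches cases and controls on ancestry before pooling).

## Study layouts used by the built-in experiments

Calibration uses the `null_calibration` fixture: one synthetic cohort
(588 cases + 408 controls in 49 + 34 pools of 12) carrying 1,000 null genes
of 8 variants each — under the null, genes are independent of the phenotype,
so one cohort suffices and `gene_hybrid_scan()` tests each gene's full count
matrix at $B = 1{,}000$. Power for the effect architectures is instead
estimated over 500 independent single-gene replicate cohorts
(`replicate_gene_study()`), because a single cohort carrying hundreds of
strong-effect genes would saturate the liability model and distort every
gene's conditional architecture. The 8-variants-per-gene choice in the
calibration fixture and the $B$ and replicate counts above are the package's
own experiment sizes; the scenario defaults (pool layout, depth, error,
effect magnitude) are the study conditions themselves and are not varied
between experiments.

On these layouts the expected pattern — and what the test suite asserts — is
that the WSS burden test is at least as powerful as C-alpha under the
unidirectional architecture, the ordering reverses under the bidirectional
architecture, and the hybrid stays within a few points of the better
component in both, which is the point of combining them.

## Meta-analysis conventions

Per-cohort 2×2 allele-count tables yield $\log \mathrm{OR} = \ln(ad/bc)$ with
$\mathrm{se} = \sqrt{1/a + 1/b + 1/c + 1/d}$; when any cell is zero the
Haldane–Anscombe 0.5 is added to all four cells — with rare variants, zero
cells are routine, and this keeps every cohort in the pool rather than
silently dropping the most informative ones. Fixed-effect pooling weights by
inverse variance and reports Cochran's $Q$ and $I^2$. Expression comparisons
use Hedges' $g$ with the standard $1 - 3/(4\,df - 1)$ small-sample correction
and variance $(n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))$, pooled under
DerSimonian–Laird random effects; forcing $\tau^2 = 0$ reproduces
fixed-effect pooling exactly, which the tests assert. A single study falls
back to fixed-effect pooling with a warning rather than an error.

## A small end-to-end run

```{r example}
fx <- make_fixture("discovery_disr_structure")
qc <- run_qc(fx$variants, fx$design, analysis_config())
filter_summary(qc$variants, c("Disr", "MisDisr_01", "MisDisr_05"))

res <- run_gene_tests(
  qc$variants, fx$design,
  analysis_config(n_permutations = 2000, rng_seed = 1),
  filters = "Disr"
)
res
```

The fixture encodes the *structure* of a discovery-cohort disruptive-variant
scan — 17 disruptive SNVs of which 8 sit in a single testable gene — with
pool counts drawn under the null, so the filter counts are exact and the
p-values are unremarkable by construction.

```{r forest, fig.width = 5, fig.height = 3}
cohorts <- tibble::tibble(
  label = c("discovery", "replication", "array"),
  a = c(130L, 98L, 260L), b = c(1046L, 910L, 2336L),
  c = c(70L, 81L, 230L), d = c(746L, 927L, 2630L)
)
m <- meta_2x2(cohorts)
glance(m)
autoplot(m)
```

## Known limitations

* Covariate adjustment is out of scope: permutation of pool labels assumes
  pools are exchangeable under the null, which holds for matched designs but
  not for confounded ones.
* No asymptotic p-values are offered for C-alpha; with pools as the unit and
  recomputed weights, permutation is both the honest and the cheap option.
* Multiple-testing correction across genes and filters is intentionally left
  to the analyst; results only flag nominal `p < 0.05`.
* The variance of the MLAC estimate is ignored downstream (counts are treated
  as known integers), as in the upstream callers this emulates.
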