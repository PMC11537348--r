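---
title: "Host filtration and re-identification auditing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host filtration and re-identification auditing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostguard)
```

## The problem

Untargeted metagenomic sequencing of human-derived samples (tissue, skin,
saliva, feces) always captures some host DNA. Host reads that survive
computational filtration have two distinct failure consequences:

1. **Analytical artifacts.** Host reads from genomic regions missing in the
   filtering reference (an incomplete assembly, e.g. a reference lacking a
   complete Y chromosome) flow through to microbial classification, where
   they mismap onto low-complexity regions that microbial genomes share with
   the host. Because the leak is correlated with host genotype (e.g. sex),
   it manifests as spurious biological signal in abundance-based analyses.
2. **Privacy leakage.** Even a few hundred host reads scattered over known
   SNP sites are enough to match a "microbial" dataset to its donor in a
   genotyped cohort, via a genotype-likelihood score.

`hostguard` implements both sides at desk scale: an exact, oracle-verifiable
matching engine plus scoring and pipeline layers for host read removal, a
labeled read simulator that reproduces both failure mechanisms, a
benchmarking layer, and the full re-identification likelihood model for
auditing what leaked reads reveal.

## Matching statistics as the classification signal

For a read $x_{1..L}$ and a reference collection, the engine computes the
matching-statistics vector: $v_i$ is the length of the longest suffix of
$x_{1..i}$ that occurs exactly (no mismatches) on the forward or
reverse-complement strand of any reference record. Compressed-index tools
used at production scale report *pseudo-matching lengths* (PMLs), a fast
approximation of the same quantity; `hostguard` computes the exact value so
that every downstream number is deterministic and testable against a
brute-force oracle, and the scoring layer treats the two identically.

Properties the engine guarantees (and the test suite asserts):

* the ramp property $v_i \le v_{i-1} + 1$ and the prefix bound $v_i \le i$;
* exact agreement with a brute-force suffix-scan oracle on randomized cases;
* strand symmetry of the maximal match;
* `N` matches nothing, including another `N` — a conservative policy that
  prevents artificial runs through ambiguous bases.

Both strands are indexed because sequencing reads arrive from either strand.
All coordinates are 0-based with half-open intervals.

## Per-read scores and thresholds

A *run* is a maximal ramp segment ($v_i = v_{i-1} + 1$); its length is the
peak value in the segment, so one contiguous matching stretch of $k$ bases
yields exactly one run of length $k$. Three metrics condense a distribution
into a score:

* **maximum**: $\max_i v_i$;
* **average**: $\tfrac 1 L \sum_i v_i$;
* **custom**: $\dfrac{1}{2L}\Big(\max_i v_i + \big(\sum_{r \in R}
  \mathrm{len}(r)\big)\,\ln(|R|+1)\Big)$ with $R = \{r : \mathrm{len}(r) >
  w\}$, which magnifies scores of reads with several long matching
  stretches.

Default thresholds are derived from a theoretical host read of length 150
containing a single contiguous matching run of length 31:

```{r thresholds}
derive_theoretical_threshold("maximum", 150, 31)
derive_theoretical_threshold("average", 150, 31)   # 3.306 truncated
derive_theoretical_threshold("custom", 150, 31, w = 5)  # 0.175 rounded
```

Numerical conventions, fixed here once:

* the custom metric uses the **natural logarithm** — it is the only base
  that reproduces the 0.175 threshold from the stated theoretical read;
* run inclusion is **strict** ($\mathrm{len}(r) > w$; with $w = 5$ only
  runs of length ≥ 6 qualify);
* `1/2L` is read as $1/(2L)$, confirmed by threshold reproduction;
* classification compares the score to the threshold **at the threshold's
  stored precision** (3 decimals for the defaults), with `>=` declaring
  host. This makes the threshold-defining read itself classify as host even
  though its full-precision custom score (0.17495...) sits just below the
  rounded threshold.

### Metric choice at small index scale

The null score of an unrelated read depends on index size: for an i.i.d.
reference text of total length $T$ (both strands), the typical matching
length of a random read position is about $\log_4 T$. At the desk scales
used in this package's experiments ($T \sim 10^5$) that is ~8–9 bases, so
unrelated reads accumulate many runs above $w = 5$ and the average and
custom defaults — calibrated for the much smaller PML nulls observed on
production indexes — flag nearly everything. The maximum metric's null
($\approx \log_4(LT) \ll 31$) is insensitive to this, which is why the
package's synthetic benchmarks and examples score with
`scoring_config("maximum")`, and why `threshold_grid_search()` exists: it
recalibrates the custom threshold/run-length pair against labeled data for
whatever index is actually in use (default grid 0.145–0.200 by 0.005 ×
w = 2–12, 132 cells).

## Pipeline topologies

All methods begin with the 45-bp minimum length filter (adapter and quality
trimming are external-tool territory and are not re-implemented). Host
removal stages follow:

* **Method 1** — two alignment stages (one reference each), then an index
  stage over the aggregate reference set;
* **Method 2** — sequential alignment stages over every reference, then the
  aggregate index stage;
* **Method 3** — the aggregate index stage alone.

The alignment surrogate declares a read mapped when it shares an exact
substring of at least `seed_length` (default 31) bases with the stage
reference. This replaces a seed-chain-extend aligner with a deterministic
criterion of the same shape (an exact seed requirement); real aligner
behavior — tolerant of mismatches around the seed — is explicitly out of
scope, and the `method_config()`/`run_method()` boundary is where an
external aligner back-end could be plugged in.

For paired-end input, a pair survives only when **both** mates survive every
removal stage; single survivors are dropped and counted as orphans
(re-synchronization runs after every stage). Single-end input skips
re-synchronization; any mapped read is removed. Output preserves input
order, and every stage's counts reconcile: input = removed + orphaned +
surviving.

## What the simulator does and does not emulate

`generate_genome()` draws i.i.d. uniform bases; `simulate_reads()` places
reads uniformly on either strand and applies independent per-base
substitutions (uniformly chosen different base) at the configured rate, with
constant Q37 qualities. Defaults follow the benchmark design: 150-bp reads
mixed 50/50 host/microbe, error-free unless stated. Paired mode emits
inward-facing mates from fixed-length fragments without size jitter.

Two failure mechanisms are constructed explicitly:

* `holdout_region()` removes an interval from the *filtering* copy of the
  host genome, so reads simulated from it leak past alignment against the
  incomplete reference and are caught only by a stage holding the complete
  genome — the missing-chromosome mechanism;
* `inject_shared_segment()` splices an identical (typically low-complexity)
  segment into a host and a microbe genome, so leaked host reads seed-match
  the microbe reference — the mismapping mechanism.

What passing these tests shows is that the *topologies* behave as designed
under controlled conditions. It does not certify performance on real data:
real genomes are repetitive and non-uniform, real reads have indels and
quality-dependent errors, and real aligners are mismatch-tolerant. The
substitution-only error model is sufficient here because every in-scope
computation consumes sequence content only.

## The re-identification model

For SNP site $i$ covered by $n_i$ reads of which $k_i$ support the
reference allele, and candidate genotype $g \in \{0,1,2\}$ (alternative
allele count), the per-site likelihood with per-base error $\varepsilon$ is

$$L(g, n_i, k_i) = \frac{1}{2^{n_i}}\,[(2-g)\varepsilon +
g(1-\varepsilon)]^{\,n_i-k_i}\,[g\varepsilon +
(2-g)(1-\varepsilon)]^{\,k_i},$$

so a heterozygote contributes exactly $2^{-n_i}$ regardless of $k_i$. The
likelihood score of genotype $j$ is $LS_j = \sum_i \ln L(g_{ij}, n_i,
k_i)$. Under Hardy–Weinberg genotype frequencies $(1-p_i)^2,\,
2p_i(1-p_i),\, p_i^2$, the population mean $E$ and variance $V$ of $LS$ are
the per-site moment sums, and $z = (LS - E)/\sqrt V$ is referred to the
standard normal. Defaults: $\varepsilon = 10^{-6}$; LD pruning at window
100, step 30, $r^2 > 0.1$; Bonferroni thresholds $\alpha/(M_{\text{meta}}
M_{\text{geno}})$ (pairwise) and $\alpha/M_{\text{meta}}$ (per-metagenome)
at $\alpha = 0.05$.

Choices fixed where the method leaves room:

* natural log throughout $LS$, $E$, $V$ (the standardization is
  base-invariant as long as one base is used consistently);
* the P-value is **upper one-sided**: only a higher-than-population
  likelihood score is evidence of donorship;
* LD pruning is greedy and deterministic: within each window, kept sites
  are scanned pairwise in index order and the *later* site of a violating
  pair is dropped; monomorphic dosage columns carry no correlation signal
  and are kept;
* sites with degenerate population frequency ($p \in \{0, 1\}$) are
  excluded from scoring (their likelihood carries no individual
  information and their variance is zero);
* pruning runs per metagenome on its covered-site list (sites with
  $n_i \ge 1$), matching how the covered-SNP list is assembled in practice;
* metagenomes with no usable covered site are reported as "insufficient"
  rather than scored;
* computation is in log space throughout; probabilities are exponentiated
  only on demand.

`synthesize_cohort()` emulates the model's study inputs: allele frequencies
uniform on [0.05, 0.95], HWE genotypes independent across sites, per-site
metagenome depth Poisson with small mean (`mean_depth = 0.1` gives the
sparse coverage typical of fecal data after host filtration), and reference
read counts binomial with the probability implied by the donor's genotype
under the error model. `attrition_experiment()` then models host filtration
as independent read thinning. On a 50-sample × 5,000-site cohort at
`mean_depth = 0.1` the true donor attains the top likelihood score for every
metagenome, non-donor standardized scores are approximately standard normal,
and thinning drives the count of Bonferroni-significant self-matches
monotonically to zero — the package's demonstration that thorough host
filtration destroys re-identifiability. Note that with few samples the
pruning threshold bites hard (chance $r^2$ between independent sites scales
as $1/(n_{\text{samples}}-1)$), so small panels retain few sites and weak
significance; this is a property of the method, not a defect of the
implementation.

## Statistical reporting

Method comparisons use the two-sided Wilcoxon signed-rank test on paired
per-dataset counts. Zero differences are dropped (the common convention;
left open by the method description), the statistic is the smaller signed
rank sum, and the P-value is exact for small samples — the closed-form
signed-rank distribution for ≤ 25 tie-free pairs, full $2^n$ sign
enumeration on midranks for tied samples up to $n = 15$ — with a
continuity- and tie-corrected normal approximation beyond. Ten pairs whose
differences all share one sign give $W = 0$ and exact two-sided
$p = 2/2^{10} = 0.00195...$, printing as 0.0020.

Coverage forensics use `coverage_depth_breadth()`: mean depth is total
covered bases over genome length, breadth the fraction of positions covered
at least once (interval union via `IRanges`). Depth concentrated on low
breadth is the signature of reads piling on one shared segment rather than
sampling a genome uniformly. `boxplot_stats()` emits the median/quartile/
1.5×IQR summary used in report tables; drawing is left to the caller.

## Problem sizes and seeds

The shipped experiments use sizes chosen to exercise every code path while
keeping the whole suite comfortably reproducible on a laptop: 20-kb
genomes, 1,000-read 50/50 mixtures, a 2-kb held-out region, ≥ 1,000
randomized oracle cases (reads up to 100 bp against references up to 500
bp), and the 50 × 5,000 re-identification cohort. All stochastic steps are
pure functions of explicit integer seeds.

## Known limitations

* Exact matching statistics are an upper bound on PML-style approximations;
  absolute score distributions (hence the average/custom defaults) do not
  transfer across index scales without recalibration (see the grid search).
* The alignment surrogate cannot reproduce mismatch-tolerant mapping, so
  benchmark numbers from real aligner pipelines are out of reach by design.
* No indel or quality-aware error modeling; no adapter/quality trimming.
* The re-identification model assumes independent sites after pruning and a
  biallelic panel; imputation, haplotype structure and phenotype inference
  are out of scope.
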