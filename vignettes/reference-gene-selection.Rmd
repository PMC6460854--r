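---
title: "Reference-gene selection and stability analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene selection and stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stableRef)
```

# The problem

RT-qPCR quantifies a target gene relative to one or more *reference genes*
assumed to be constant across the compared samples. When the assumed
references drift — as classical choices such as beta-actin or GAPDH often
do across developmental stages — every downstream fold-change is biased.
`stableRef` implements a two-arm workflow: a transcriptome-wide screen
that nominates stable candidates from RNA-Seq, and a qPCR-side validation
that scores a small panel's stability from measured Ct values.

# The screening model

The screen operates on a gene × condition matrix of TPM (transcripts per
million). TPM is used rather than RPKM/FPKM because each sample's values
sum to $10^6$, making values comparable between samples. Biological
replicates are averaged **on the linear TPM scale** before any log
transform; the log2 of an average is not the average of logs, and the
screen's statistics are defined on per-condition summary values. With
$L_c = \log_2(\mathrm{TPM}_c)$ over conditions $c = 1..n$, a candidate
must satisfy, in this order:

1. **Ubiquitous expression**: $\mathrm{TPM}_c > 0$ for every $c$. This is
   evaluated strictly, so criterion I also guarantees that $L$ is defined
   — no pseudocount is ever added.
2. **Low variance**: $\mathrm{sd}(L) < 1$ (strict), with the sample
   standard deviation ($n-1$ denominator). The choice of sample over
   population SD matters at the small condition counts typical of these
   designs (7–11); it is the package default and configurable only by
   screening criteria, not by a hidden switch.
3. **No exceptional expression**: $\max_c |L_c - \bar L| < 2$ (strict; a
   deviation of exactly two log2 units fails). The deviating condition is
   included in the mean it is compared against.
4. **Medium-to-high expression**: $\bar L > 5$ (strict), i.e. mean TPM
   above 32. Low-expression genes are hard to assay reliably by qPCR even
   when proportionally stable.

Stability of candidates is ranked by the coefficient of variation
$\mathrm{CV} = \mathrm{sd}(L)/\bar L$, computed on the log2 scale. The
log2 scale is forced by the structure of the criteria: criteria 2 and 4
give the analytic supremum

$$\mathrm{CV} < \frac{\text{sd bound}}{\text{mean bound}} = \frac{1}{5} = 0.2,$$

which `cv_bound_check()` returns and the test suite confirms on $10^4$
randomized genes. Ties in CV are broken by ascending gene id so ranking
is deterministic.

Criteria are applied sequentially and `screen_dataset()` records the
cascade counts (survivors after I, I–II, I–III, I–IV), which are weakly
decreasing by construction. Whether criterion I should be evaluated on
per-replicate or replicate-averaged TPM is genuinely open; we evaluate on
averaged conditions, consistent with all other criteria operating on the
condition-level matrix. A gene expressed in every condition-average but
dropping to zero in a single replicate would pass here; with complete
input matrices this distinction only affects borderline, noisy genes that
criterion II removes anyway.

`core_set()` intersects candidate sets from independent datasets, reports
the full Venn partition, and summarizes sharing as
$100\,|\cap|/|\cup|$ rounded to two decimals.

# Enrichment statistics

`enrich()` asks whether a candidate set is over-represented in annotation
terms. For a term with $m$ annotated genes in a universe of $N$, and a
query of $k$ genes overlapping the term in $x$, the p-value is the
upper-tail hypergeometric $P(X \ge x)$. Design choices: the universe is
the set of *annotated* genes supplied by the user (the GOstats
convention), not the genome size; only terms with overlap $\ge 1$ are
tested, and the number of tested terms is the Benjamini–Hochberg $m$;
only over-representation is tested. Significance defaults to FDR < 0.05.

# Stability statistics on Ct data

All three methods consume a gene × sample Ct matrix; technical
triplicates should be averaged to one Ct per biological sample first
(`stability_report(replicate_map = ...)` does this). Ct relates to
abundance through the per-gene amplification efficiency $E$: one cycle
multiplies template by $1 + E$. Efficiencies default to 1 (perfect
doubling) and can be estimated with `amplification_efficiency()` from a
two-fold dilution series (OLS of Ct on log2 input;
$E = 2^{-1/\text{slope}} - 1$).

**geNorm.** Quantities $Q_{gs} = (1+E_g)^{Ct_{\min}(g) - Ct_{gs}}$ rescale
each gene so its most abundant sample is 1. For genes $j, k$ the pairwise
variation $V_{jk}$ is the sample SD over samples of
$\log_2(Q_{js}/Q_{ks})$, and $M_j = \mathrm{mean}_{k \ne j} V_{jk}$.
`genorm_rank()` runs the stepwise procedure — recompute $M$, drop the
worst, repeat down to two genes, which are inherently unresolvable and
share rank 1.5 — and emits the pairwise-variation series $V(n/n+1)$, the
sample SD of $\log_2(NF_n/NF_{n+1})$ where $NF_n$ is the geometric mean
of the $n$ top-ranked genes' quantities. We emit the series but do not
hard-code the common $V < 0.15$ "enough genes" rule. When several genes
tie for worst $M$ the lexicographically last is removed, for determinism.

**NormFinder-style.** On the log2-quantity scale
$y_{is} = -Ct_{is}\log_2(1+E_i)$, ungrouped stability is the sample SD of
the column-centered values $y_{is} - \bar y_{\cdot s}$ — a gene's
wobble around the panel consensus. With sample groups, the measure is the
mean over groups of $|d_{ig}| + \sqrt{\sigma^2_{ig}/n_g}$, where
$d_{ig} = (\bar y_{ig} - \bar y_{i\cdot}) - (\bar y_{\cdot g} - \bar y_{\cdot\cdot})$
is the gene × group interaction and $\sigma^2_{ig}$ the within-group
variance of the centered values. This is a deliberate simplification of
Andersen et al.'s variance-decomposition model: it drops the shrinkage
(bias-correction) of interaction estimates, whose constants are not
reproducible from published summaries, while preserving the model's
ordering behavior on clean cases — verified in the tests by brute-force
oracle, not against the original binary. Groups of size 1 make
$\sigma^2_{ig}$ undefined; the function then instructs the user to run
ungrouped.

**Comparative delta-Ct.** Stability of gene $i$ is the mean over partners
$j$ of the sample SD of $Ct_{is} - Ct_{js}$, in cycles. At $E = 1$ for
all genes, $\log_2(Q_{is}/Q_{js}) = -(Ct_{is} - Ct_{js})$ up to a
per-pair constant, so delta-Ct stability coincides exactly with the
geNorm M value — an identity the test suite asserts to 1e-9.

**Comprehensive ranking.** Each method's scores are ranked ascending
(average ranks on ties) and combined per gene as the geometric mean of
the three ranks; the final order is ascending score with gene-id
tie-break. Because ranks, not raw scores, are combined, the result is
invariant under any monotone transform of an individual method's scores.
Two readings of "geometric mean of the ranking values" are possible —
ranks or scores; we combine **ranks**, which keeps the three methods'
different units (cycles, log2 units) commensurable. Likewise the geNorm
rank fed into the comprehensive score is the average-tied rank of the
full-panel M value, keeping the three inputs structurally parallel; the
stepwise-exclusion order remains available from `genorm_rank()` for
readers who want the canonical geNorm ordering.

# Ct ~ log2(TPM) calibration

`fit_ct_tpm()` pools all (gene, sample) pairs of a validated panel —
optionally excluding named unstable genes, an input rather than a
hard-coded list — and fits $Ct = a\,\log_2(\mathrm{TPM}) + b$ by OLS,
reporting Pearson's $r$ (two-sided t-test p-value) and $R^2 = r^2$. A
global line across genes is a coarse model (per-gene efficiencies and
priming differences shift intercepts), but it is the useful one for its
purpose: predicting roughly what Ct to expect from RNA-Seq abundance
before designing an assay. Deming/orthogonal regression is out of scope.

# The synthetic world

The generators state a fixed world; their defaults are not tuned to make
tests pass.

* `gen_expression()`: condition-level log2 expression is
  Normal(mean, sd) per gene — i.e. log-normal TPM, matching the screen's
  log2-scale statistics. Planted archetypes: **stable** genes
  (mean 8, sd 0.2 — comfortably inside all four criteria), **variable**
  genes (sd 2.0; mean 6, a value we chose as a realistic medium
  expression since only the sd is prescribed), **stage-specific** genes
  (expressed in exactly one condition), and **silent** genes (zero TPM
  everywhere; any zero condition already fails criterion I). Replicate
  measurements add Normal(0, 0.1) log2 noise. Presets mirror three
  realistic designs: 7 developmental stages, 11 tissues, or 8 gonadal
  conditions, each with 3 replicates.
* `gen_ct()`: $Ct = -0.94\,L + 29.67 + \mathcal N(0, \sigma)$, the
  empirically observed coupling scale for abundances spanning $L$ 4–14
  (Ct roughly 14–29). Default $\sigma = 0.25$ cycles — our choice for
  typical qPCR repeatability after triplicate averaging; per-gene
  $\sigma$ overrides allow spiking an unstable gene. Ct outside (0, 45]
  is clipped with a warning.
* `gen_fastq()`: truth-labelled reads in four categories (clean; exactly
  10 sub-Q20 bases — kept under the default rule; exactly 11 — dropped;
  one 'N' — dropped), so filter counts can be checked exactly at the
  boundary.

What a green synthetic test establishes: the algorithms implement their
definitions and separate a 10-fold stability difference essentially
always. What it does not establish: performance on real data, where
expression is not log-normal, replicates are correlated, library
composition varies, and annotation is incomplete. The headline counts of
any particular real study (thousands of candidates, a several-hundred-gene
core set) depend on the actual libraries and are not reproducible from
simulation; our acceptance checks are therefore property-based plus
self-contained arithmetic.

# Numerical conventions and degenerate inputs

* Sample SD ($n-1$) everywhere, for screen statistics and all three
  stability methods.
* Strict inequalities exactly as the criteria state them: a gene at
  mean $L = 5.0$, a deviation of exactly 2.0, or a read with exactly 10
  low-quality bases each sit on the *passing or failing* side dictated by
  the strict rule (fail IV, fail III, kept, respectively).
* Expression input must be complete: missing values are rejected at
  ingest, because criterion I is meaningless on genes with unobserved
  conditions. Drop such genes upstream.
* All-zero samples make TPM undefined and are an error, not a silent NaN.
* CV is reported for every gene passing criterion I, including
  non-candidates; genes failing I carry NA statistics and are never
  NaN-propagated.
* Quality encoding is Phred+33 by default with an explicit +64 flag.
* Seeds are mandatory for every generator; given a seed, output is
  bit-reproducible.

# Known limitations

* NormFinder here is the simplified estimator described above, not a
  drop-in numerical replica of the original tool.
* The geNorm V series is emitted without a recommendation threshold.
* The enrichment module does no GO-graph propagation or term slimming;
  it consumes flat gene-to-term maps.
* The Ct calibration is a single pooled line; per-gene calibration is
  intentionally out of scope.
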