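---
title: "Permutation-null differential expression: models and design choices"
author: "permdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-null differential expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permdeg)
```

# The analysis problem

permdeg implements a differential-expression pipeline for the smallest
common bulk RNA-seq design: two conditions (for example patient-derived
mutant fibroblasts against normal fibroblasts), three biological replicates
each, and a genes-by-samples matrix of read counts. With so few replicates a
parametric t reference is fragile, so the pipeline calibrates gene-wise
t-statistics against an *empirical* null obtained by exhaustively relabelling
the samples, pools those null statistics across genes, converts the empirical
p-values to Storey q-values, and calls differentially expressed genes (DEGs)
jointly on FDR and fold change. Downstream stages test DEG lists for gene-set
over-representation, export signed network node/edge tables, and quantify
qPCR validation measurements with the delta-delta-Ct method.

# The statistical procedure

## Normalization

Library sizes are normalized with the trimmed mean of M-values (TMM). For
sample $k$ against a reference sample $r$ (chosen as the sample whose
75th-percentile count fraction is closest to the mean of those fractions —
the method's published heuristic, overridable), gene-wise log ratios and
abundances are computed on library-size-scaled proportions
$p_{gk} = y_{gk}/N_k$:

$$M_g = \log_2 \frac{p_{gk}}{p_{gr}}, \qquad
  A_g = \tfrac12 \log_2 (p_{gk}\, p_{gr}),$$

over genes positive in both samples. The most extreme 30% of $M$ and 5% of
$A$ are trimmed from each tail (the published defaults; both configurable),
and the factor is $2$ raised to the mean of the surviving $M_g$, weighted by
the inverse asymptotic binomial variance
$(N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})$. Factors are
rescaled to geometric mean 1. Counts are then rescaled to the mean
TMM-effective depth, a pseudocount of 1 is added, and values are
log2-transformed, so a zero count maps to exactly 0.

Two ordering choices deserve a note. First, the pseudocount is added *after*
rescaling to a common effective depth, so the transform acts on normalized
counts that are still on a count-like scale; applying it to raw counts
instead is available via `rescale = FALSE`. Second, because the precision
weights use absolute counts, TMM factors are exactly invariant to a uniform
rescaling of a sample's proportions but only approximately (at the
sub-percent level for realistic depths) invariant to rescaling a single
sample's raw counts; the M values and the trim set are unaffected, only the
weights shift.

## Testing

For each gene the pooled-variance two-sample Student t is computed on the
log2 values (test minus control). The null distribution is built by
enumerating **all** $\binom{n_1+n_2}{n_1}$ assignments of the samples to two
groups of the observed sizes — 20 for a 3 vs 3 design — and computing every
gene's t under each. Because 20 assignments cannot resolve p-values below
1/20 for a single gene, the null statistics are pooled across genes
(`per_gene_null = TRUE` restores the per-gene variant).

The observed labelling, and for balanced designs its label swap, are
**excluded** from the pooled null by default. This is deliberate: those two
assignments realize the alternative hypothesis, and each gene would
contribute its own $|t|$ to the pool twice, so the gene with the $j$-th
smallest p could never have $p < 2j/(GC)$ and *every* q-value would be
bounded below by $2\hat\pi_0/C \approx 0.09$ at $C = 20$. An FDR threshold
of 0.05 would then be unattainable for any gene, however large its effect —
incompatible with the thresholds this pipeline exists to apply. With the
exclusion, the remaining 18 assignments per gene form a genuinely null
reference. `exclude_observed = FALSE` restores the fully inclusive pool.

Empirical two-tailed p-values use add-one smoothing,
$p = (1 + \#\{|t_\mathrm{null}| \ge |t_\mathrm{obs}|\}) / (1 + GC')$, and
therefore lie in $(0, 1]$. Degenerate genes are resolved deterministically:
zero pooled variance with equal means gives $t = 0$; with unequal means,
$t = \pm\infty$, which ranks more extreme than any finite statistic in both
the observed and the null computations. Genes with zero counts in every
sample are dropped before testing and recorded in the run log.

## FDR and calling

Storey's estimator $\hat\pi_0 = \#\{p > \lambda\}/(m(1-\lambda))$ with
$\lambda = 0.5$ (deterministic; a spline-smoothed $\lambda$-grid variant is
available) feeds the step-up q-values
$q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$, capped at 1. A gene
is a DEG when $q < 0.05$ and its fold change exceeds 1.5 *in either
direction* — the two-sided reading is forced by the existence of both up-
and downregulated DEG sets in the kind of study this pipeline reproduces.
Direction follows the sign of the log2 fold change, computed as the
difference of group means of the log2 values.

## Over-representation

Up- and downregulated DEG lists are tested separately (a combined mode
exists) against each gene set with the hypergeometric upper tail — the
one-sided Fisher exact test — or, by default, with DAVID's EASE score, which
removes one gene from the overlap before computing the tail and is therefore
uniformly more conservative. The universe defaults to the genes actually
tested in the DEG stage, not the whole genome, to guard against detection
bias; it is configurable. Selection is on the raw p-value at 0.1 with no
multiple-testing correction, mirroring the selection rule of the protocol
this package follows; the threshold is configurable.

## qPCR quantification

For a target gene, $\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{reference}$
within each sample, $\Delta\Delta Ct$ references every replicate to the
*mean* control $\Delta Ct$ (replicates are unpaired across conditions), and
the relative level is $2^{-\Delta\Delta Ct}$. Relative levels are finally
divided by the mean control-replicate level so the control condition
averages exactly 1 — without this step only the geometric mean of the
control levels is 1. Dispersion is reported as the SEM of the per-replicate
levels. Amplification-efficiency correction (Pfaffl) is out of scope.

# The synthetic-data generator

`simulate_counts()` draws counts from a negative binomial with mean

$$\mu_{gj} = L_j\, q_g\, 2^{\delta_g [j \in \mathrm{test}]}\, b_{gj},$$

in the mean/dispersion parameterization
($\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$ degenerates to Poisson).
Defaults describe the emulated design and were fixed once:

* `n_genes = 15000`, `n_per_group = 3`: the order of expressed genes and the
  replicate count of a typical two-condition fibroblast comparison.
* `pi_de = 0.1`, `log2fc_range = c(1, 2)`, `prop_down = 0.5`: a minority of
  genes truly DE, in both directions; `prop_down` can be raised to emulate a
  down-dominated response.
* `dispersion = 0.1`: a biological-replicate-level biological coefficient of
  variation of about 0.32.
* `lib_size_range = c(1e7, 2e7)` expected fragments per sample;
  `abundance_sdlog = 2` for a log-normal baseline that spans the dynamic
  range of bulk expression (median simulated count in the hundreds, a long
  low-count tail).
* Composition bias is planted by multiplying the expected counts of a random
  5% gene subset (`bias_gene_fraction`) in the designated sample by the
  requested factor. A factor applied to *all* genes of a sample would be
  absorbed into the realized library size and cancel out of the
  proportion-based TMM statistics, so a gene-subset construction is the only
  way to plant a recoverable composition effect.

Each generator (`simulate_counts`, `simulate_gene_sets`,
`simulate_ct_table`) seeds its own stream from its `seed` argument, so
stages are individually reproducible; the pipeline derives per-stage seeds
from one global seed.

What the generator does *not* emulate: batch effects beyond library size and
composition, gene–gene correlation, length/GC biases, and the
mean-dispersion trend of real data (dispersion is constant across genes).
Passing calibration tests on these simulations therefore demonstrates the
correctness and internal calibration of the procedure, not its power on any
particular real data set.

# Numerical and tie-breaking choices

* TMM trim ranks come from a stable sort (ties broken by gene order), and
  only ranks strictly inside the trimmed band survive, so factors are a
  deterministic function of the input. A sample whose proportion profile
  matches the reference to within $|M| < 10^{-6}$ gets factor exactly 1.
* The empirical p computation sorts the pooled null once and counts tails
  with `findInterval`; $\pm\infty$ sentinels sort to the ends and are
  handled without special cases.
* $\hat\pi_0$ is clipped into $(0, 1]$; an estimate of zero (every p below
  $\lambda$) is replaced by the smallest value the estimator can resolve,
  $1/(m(1-\lambda))$.
* Table outputs print reals at 15 significant digits, so a write/read round
  trip is exact to at least 12.

# Test problem sizes

The packaged tests calibrate the pipeline at sizes chosen to make the checks
statistically meaningful while keeping the whole suite fast: null
calibration on 5,000 genes (Kolmogorov distance to uniform below 0.02;
tail fraction at 0.05 within [0.04, 0.06]); FDR and recovery on twenty
10,000-gene simulations with $\pi_0 = 0.9$; the enrichment scores checked
against exhaustive tail summation for every table with a universe of up to
60 genes; TMM bias recovery averaged over five simulations.

# Known limitations

* **Power at 3 vs 3 with biological dispersion.** The pooled t has 4 degrees
  of freedom; its null tails are heavy, and with $\phi = 0.1$ a planted
  twofold change has noncentrality of only about 2.7–5.4. The realized
  false-discovery proportion stays controlled (the suite measures about
  0.03 at nominal 0.05), and called directions match the planted ones, but
  recall of planted effects at FDR < 0.05 is a few per mille — an intrinsic
  property of this design point, not an implementation artifact. Large DEG
  yields at these thresholds are only reachable with the much smaller
  dispersions of technical or cell-line replicates, or with more samples.
  The packaged acceptance suite states this expectation as written and the
  recall check fails by design at this design point; the measured values
  are in `scripts/acceptance.R` output.
* The moderated/shrinkage variance estimators that rescue power at small
  $n$ (as in limma or DESeq2) are deliberately out of scope: the package
  reproduces the plain-t permutation protocol.
* The hypergeometric selection rate under null gene sets sits at or just
  below the nominal threshold because the test is discrete; the suite
  checks a [0.05, 0.12] band around 0.1.
* Paired designs, covariates, and amplification-efficiency correction are
  not supported.
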