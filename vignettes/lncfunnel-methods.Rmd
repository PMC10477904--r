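---
title: "Methods: variant prioritization in lncRNAs and the quantification arithmetic behind it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization in lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfunnel)
```

## The problem

Most trait-associated SNPs land in non-coding sequence. When such a
variant falls in the exon of a long non-coding RNA, one concrete
mechanism is available to it that protein-coding logic does not cover:
a single substitution can reshape the RNA's base-pairing ensemble and
thereby its interactions. `lncfunnel` implements the corresponding
prioritization funnel — variants intersected with transcript models,
exonic hits mapped onto the mature transcript, and each allele pair
scored for structural disruption — together with the quantification
arithmetic used to follow up a candidate at the bench (qPCR relative
expression, subcellular fractionation ratios, RNA-seq count
normalization, gene-set overrepresentation, RIP percent-of-input).

## Coordinates and intersection

Internally all genomic intervals are 1-based and closed, the IRanges
convention; BED12's 0-based half-open records are converted on read and
restored bit-exactly on write, and GTF exons (1-based closed) are taken
as-is. Spliced (mature-transcript) positions are likewise 1-based. This
is a deliberate departure from the 0-based half-open convention common
in Python tooling: in R, every container this package builds on indexes
from 1, and a mixed convention is a standing source of off-by-one
errors. The tests therefore assert coordinate behaviour through an
independent oracle — explicit construction of the mature sequence and
`match()` of the genomic position — rather than through constants tied
to either convention.

Overlap testing ignores strand and uses the transcript's genomic span
(first exon start to last exon end): a variant inside the span is
exonic or intronic; a variant outside every span yields no row. Strand
is honoured where it matters physically: the mature sequence of a
minus-strand transcript runs from the highest genomic coordinate
downward, and plus-strand alleles are complemented before they are
applied to it (`orient_alleles()`). Variants lacking alleles are
intersected and counted but flagged unscoreable for the structure
stage, which needs both alleles.

Chromosome names are normalized (leading "chr" stripped, X/Y/MT
upper-cased) because variant tables and annotation sources routinely
disagree. Genome build reconciliation is the caller's responsibility;
no liftover is attempted.

## The folding model

Structure scoring needs equilibrium base-pair probabilities for two
alleles of the same window. The package uses a deliberately minimal
Boltzmann ensemble: a structure is any non-crossing set of canonical
pairs (Watson–Crick plus the G·U wobble) in which every pair encloses
at least `min_hairpin` unpaired bases, and its weight is the product of
one Boltzmann factor per pair,

$$ w(S) = \prod_{(i,j) \in S} e^{-e(b_i, b_j)/RT}. $$

Defaults are $e_{GC} = -3$, $e_{AU} = -2$, $e_{GU} = -1$ kcal/mol,
$T = 310.15$ K ($RT = 0.0019872\,T$ kcal/mol), and `min_hairpin = 3`,
the standard steric constraint. These energies keep the familiar
stability ordering GC > AU > GU at physiological temperature but make
no claim to nearest-neighbour (Turner-rule) realism — stacking, loop
penalties, dangles, and pseudoknots are out of scope. What the
simplification buys is exactness: the ensemble is small enough to
enumerate for short sequences, so every probability the dynamic program
reports can be checked against an independent exhaustive enumeration
(`enumerate_oracle()`, capped at 16 nt), and the test suite does so to
an absolute tolerance of 1e-9.

The inside recursion computes the partition function
$Z(i,j) = Z(i{+}1,j) + \sum_k w(i,k)\,Z(i{+}1,k{-}1)\,Z(k{+}1,j)$ with
$Z(\text{empty}) = 1$; pair probabilities follow by conditioning on the
closest enclosing pair, filled in order of decreasing span. All terms
are positive, so there is no cancellation; magnitudes stay within
double range for windows up to a few hundred bases (a 200-nt window can
hold at most ~98 pairs, far below overflow). The recursions run in
C++ (Rcpp); the enumeration oracle is plain R, a genuinely independent
route.

## Disruption scoring and the empirical null

Given wild-type and mutant probability matrices, `disruption_score()`
reports three measures on the upper triangle: the Euclidean distance
`d_global`; `d_local`, the maximum over contiguous intervals of length
at least `l_min = 10` of the interval's length-normalized distance
$\sqrt{\sum_{a \le i < j \le b} \Delta P_{ij}^2 / (b-a+1)}$ (ties broken
toward the smallest start, then end, for determinism); and `1 - r`, the
Pearson dissimilarity of the two upper-triangle vectors (with the
zero-variance convention r = 1 if the vectors are equal, else 0).
`d_local` is the default metric: it rewards perturbations concentrated
in one region, the signature of a genuine structural switch, rather
than diffuse numerical noise.

Significance comes from resampling: `empirical_pvalue()` scores B
(default 200) random substitutions of the same window — position and
alternative base uniform, the observed substitution excluded — by the
identical procedure and reports the add-one estimate
$p = (1 + \#\{\text{background} \ge \text{observed}\})/(B+1)$, which is
never below $1/(B+1)$ and is uniform under the null; the uniformity is
itself tested (Kolmogorov–Smirnov) in the suite. A variant is called
disruptive when $p \le \alpha$ with $\alpha = 0.1$ by default.
`score_variant()` folds both alleles over a window of at most `W = 200`
bases centred on the variant (clipped at the ends), since a single
substitution acts locally and full-length folding of multi-kilobase
lncRNAs would be both slow and physically dubious under this model.

One property of this null deserves emphasis, because it bounds what a
"disruptive" call can mean. The background is *other mutations of the
same window*, so the empirical p measures how exceptional the observed
substitution is among mutations of that sequence — not how different
the two ensembles are in absolute terms. On a short, perfect hairpin
almost every stem substitution breaks a pair, so a planted stem-break
scores high in absolute terms (its `d_local` exceeds a loop variant's
by two orders of magnitude) yet sits in the middle of the background
distribution, and the call rate at $\alpha = 0.1$ stays far below the
score separation. The two outputs are deliberately kept distinct: the
score quantifies the perturbation, the p-value quantifies its
exceptionality within the window. `scripts/acceptance.R` computes both
(call rate and median stem/loop scores) on seeded hairpins.

## qPCR, fractionation, and testing conventions

Relative expression uses the standard 2^−ΔΔCt form with technical
duplicates averaged before any ΔCt arithmetic. `induction_screen()`
flags a gene as induced at a timepoint when the mean fold versus the
baseline exceeds 1 *and* a two-tailed pooled-variance Student's t-test
on the replicate values is significant (`alpha = 0.05`); both
conditions are required so that a noisy but unshifted gene is not
starred. The t-test is the classic pooled form because that is what the
name "Student's t-test" denotes; a Welch flag is available. Multi-group
comparisons use a one-way ANOVA omnibus F followed by pairwise t
statistics on the pooled within-group variance, Bonferroni-adjusted by
the number of requested comparisons and capped at 1. Fractionation
ratios are reported as log base 10 of nuclear over whole-cell relative
amounts (base configurable). Per-replicate max-normalization divides by
the replicate's maximum, so each replicate's largest value is exactly 1
and the output is invariant to rescaling a replicate.

## RNA-seq arithmetic

Low-count filtering keeps a gene when strictly more than 10 counts are
seen in at least 3 samples (the strict inequality matters: a gene at
exactly 10 everywhere is dropped) and is idempotent. Upper-quartile
normalization takes, per sample, the 75th percentile (linear
interpolation between order statistics) of genes expressed in at least
one sample, and centres the factors by their geometric mean so the
overall count scale is preserved while upper quartiles equalize
exactly. "Significantly upregulated" means Benjamini–Hochberg FDR below
0.05 with positive log2 fold change — the threshold is configurable,
since upstream pipelines differ. Overrepresentation of a gene set among
the selected genes uses the upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated via
the distribution function in log space so it remains accurate at
$N \sim 10^4$; detected and selected fractions are reported as
percentages rounded to one decimal, matching how such tables are
printed. The differential-expression model fit itself (GLM, unwanted
variation) is consumed, not reproduced.

## RIP percent-of-input

The literal formula is $100 \cdot 2^{\,Ct_{input} - Ct_{IP}}$. Many
protocols save only a fraction of the lysate (commonly 10%) as input;
whether published values correct for that dilution is often unstated,
so the correction (multiplication by the input fraction) is an explicit
opt-in flag rather than a silent default — fidelity to the printed
formula first. Specific-over-IgG enrichment is a plain ratio of
percent-of-input values.

## What the generators emulate — and what they do not

Every input has a seeded generator that ships ground-truth labels, so
pipeline outputs are compared against planted truth, never against
other pipeline outputs.

* `simulate_locus_set()` places non-overlapping 1–4-exon transcripts on
  synthetic chromosomes and plants exonic/intronic/intergenic variants
  in stated proportions, with FASTA alleles consistent with the
  annotation (strand-aware). Real annotations contain overlapping and
  multi-isoform loci; the intersection code handles them (a variant can
  hit several transcripts), but the generator does not produce them, so
  that the truth table stays trivially exact.
* `make_hairpin_with_variant()` builds a perfect stem (random arm +
  all-A loop + exact reverse complement) and plants either a
  stem-breaking substitution at the arm base adjacent to the loop
  (disruptive truth) or a loop A→C (non-disruptive truth). Real
  riboSNitches sit in imperfect, nested structures; this contrast is
  the cleanest testable caricature.
* `simulate_ct_experiment()` draws reference Cts around 20 and target
  Cts around 24 with Gaussian noise (default sd 0.2 cycles, a typical
  bench value), shifting the treated target by −log2(fold). It models
  no amplification-efficiency error or plate effects.
* `simulate_counts()` uses log-normal gene means (log-mean 4, log-sd
  1.5), log-uniform library factors in [0.5, 2], and gamma-Poisson
  counts (dispersion 0.1), the overdispersion family RNA-seq tooling
  assumes.
* `simulate_de_results()` assigns selection by weighted sampling
  without replacement with odds ρ for set members; ρ = 1 is the exact
  hypergeometric null used for calibration.

Because the generators are caricatures, a green suite demonstrates the
*arithmetic* is right under its stated model — not that the pipeline's
biological sensitivity on real data matches any particular study.

## Numerical and design choices

* Partition-function sums are positive throughout; DP/oracle agreement
  is asserted at 1e-9 absolute, three orders looser than observed.
* `d_local` interval ties break lexicographically; background draws,
  generator draws and per-variant seeds make every disruption call
  reproducible from one integer seed (the pipeline derives per-variant
  seeds as master seed + row index).
* Null-calibration simulations were sized for the discreteness of their
  statistics: the hypergeometric check uses N = 20,000, K = 8,000,
  n = 600 so the p-value's support is dense enough (maximum pmf step
  ≈ 0.03) for a meaningful KS uniformity test, and the empirical-p
  calibration draws a fresh random 25-nt sequence per replicate to
  avoid tie-induced atoms from any single fixed window.
* Degenerate inputs fail loudly: empty variant tables, all-zero
  samples, zero upper quartiles, non-positive fractionation inputs,
  reference-allele mismatches, and annotation/FASTA id disagreements
  are errors, not warnings.
* Runs write a JSON manifest of all parameters; every output file
  carries the manifest's MD5 hash in a header comment, and re-running
  the same configuration reproduces outputs byte-identically. Problem
  sizes in the test suite (50-seed hairpin panels, 100 locus fixtures,
  500-replicate calibrations, 200-sequence oracle sweeps) were chosen
  as the smallest panels at which the asserted contrasts are stable.

## Known limitations

* The energy model is per-pair only. Absolute probabilities are not
  thermodynamically accurate and should be compared within the model,
  not against nearest-neighbour predictors.
* The empirical null measures within-window exceptionality (see above);
  sequences whose windows are saturated with structurally consequential
  positions will rarely yield small p-values for any one of them.
* Only single-nucleotide substitutions are modelled — no indels, no
  multi-allelic records.
* The overrepresentation test conditions on the selected-gene count and
  ignores inter-gene correlation, as the hypergeometric formulation
  always does.
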