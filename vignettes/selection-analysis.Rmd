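---
title: "Detecting selection and conservation at young lncRNA loci"
author: "lncsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection and conservation at young lncRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsel)
```

## The problem

Many primate lncRNAs are evolutionarily young. ESRG, a marker of human
pluripotent stem cells, is the canonical example: its promoter and first
exon derive from a HERV-H retroviral insertion (an LTR7/HERV-H-int element)
that post-dates the orangutan split, so classical phylogenetic conservation
scores are necessarily low across the locus. Low conservation does not by
itself rule out function, though — a transcript that matters to present-day
humans should instead show *population-genetic* signatures of purifying
selection: deleterious alleles held at low frequency (an excess of
singletons in the site-frequency spectrum) and a deficit of fixed
differences relative to polymorphism (a reduced fixation rate).

`lncsel` implements that battery of tests as a reusable pipeline: site
filtering for gnomAD-style population VCFs, exon/intron/LTR stratification,
phastCons conserved-fraction summaries, downsampled site-frequency spectra
with a singleton chi-squared contrast against a synonymous-site reference,
McDonald–Kreitman-style Fisher contrasts of human-lineage substitutions
(inferred by parsimony against the chimpanzee–bonobo ancestor) versus
polymorphism, and a cross-species expression screen built on the DESeq2
negative-binomial interaction model. A Poisson-random-field simulator with
known selection coefficients generates complete synthetic inputs so every
stage is testable without downloads.

## Site filtering

Population SNVs enter as VCF. Only single-nucleotide, bi-allelic records
with `FILTER = PASS` are used; positions carrying several alternate alleles
(in one record or split across records) are dropped entirely rather than
decomposed — the conservative, reproducible reading of a "bi-allelic SNVs"
rule, since no decomposition protocol is implied. Sites must further have
adequate sequencing depth across the cohort: at least 15x coverage in at
least 95% of individuals (`applyCoverageFilter()`, thresholds
configurable). Sites with no coverage row are dropped and counted; when
most sites lack one, the coverage table likely comes from a different
genome build, and the filter warns (escalatable to an error). Both filters
are idempotent.

## Stratification

Region labels partition the genome relative to one explicitly chosen
analysis transcript: `exon`, `intron` (within the transcript span),
`intergenic`. LTR-derived status is deliberately *orthogonal* — a flag, not
a fourth region — because the interesting stratum at a HERV-H-derived locus
is precisely the LTR-derived part of exon 1. Exonic statistics therefore
include LTR bases by default, with the LTR subset additionally reported so
either convention can be read off. Coding effects (for the neighboring
protein-coding comparator gene) substitute the alternate base into the
reference codon under the standard nuclear genetic code,
reverse-complementing on the minus strand; a stop gain counts as
nonsynonymous. Splice-site and UTR subcategories are not modeled.

## Conservation summaries

`conservedFraction()` reports, over the union of a gene's exons (merged
across transcripts so shared bases count once), the fraction of scored
positions with phastCons score strictly above 0.9. Positions without a
defined score are excluded from the denominator and reported. A lncRNA is
called `conserved` when strictly more than 5% of its scored exonic sites
clear the threshold — a cutoff that separates HOTAIR-like lncRNAs (about 8%
of sites conserved) from repeat-derived ones like ESRG (under 1%). Exons
are the primary scoring domain; the transcript-wide fraction is reported
alongside.

## The downsampled site-frequency spectrum

Different sites are called in different numbers of chromosomes. To compare
allele-frequency distributions on a common footing, each site observed with
`ac` alternate alleles among `an` called chromosomes contributes its
*hypergeometric expectation* to a spectrum over a fixed `m` (default
30,000) chromosomes:

$$ p_j \;=\; \frac{\binom{ac}{j}\binom{an-ac}{m-j}}{\binom{an}{m}},
   \qquad j = 0, \dots, m. $$

The vector sums to one and preserves the allele frequency
($\sum_j j\,p_j = m\,ac/an$). Mass landing on $j = 0$ or $j = m$ — sites
that would look monomorphic in the smaller sample — is set aside as
"dropped monomorphic mass", so total mass is conserved per site. Sites with
`an < m` cannot be projected upward and are excluded, with the exclusion
count kept on the object so the choice is auditable. The expectation mode
is deterministic and has strictly lower variance than drawing one random
subsample per site; a seeded sampling mode (`method = "sampled"`) exists
and is used as the independent cross-check in the tests.

Singletons are defined on the *projected* spectrum (bin $j = 1$ of the
`m`-sample), not on raw `ac = 1`. Under neutrality the expected singleton
fraction is $1/H(m-1)$ with $H$ the harmonic number — about 0.092 at
$m = 30{,}000$; purifying selection pushes it up. The contrast against the
synonymous-site reference is a Pearson chi-squared on the 2x2
singleton/non-singleton by target/reference table, one degree of freedom,
no continuity correction (the plain "chi-squared test"), on
integer-rounded projected masses. Expected cells below one flag the result
without suppressing it. The genome-style screen applies this per gene to
every lncRNA with at least 50 usable SNVs, flags significance at an
unadjusted two-sided 5% (the per-gene convention of such screens), and
emits a Benjamini–Hochberg column alongside.

The spectrum is unfolded by alternate allele, as in gnomAD-style input;
ancestral polarization is not applied. This is a documented limitation:
reference/alternate is not ancestral/derived at every site, but the
singleton contrast compares strata under the same convention, so the
comparison is internally consistent.

## Divergence contrasts

Human-lineage substitutions are inferred from a human–chimpanzee–bonobo
alignment by parsimony: when the two outgroups agree on a base, that base
is the ancestor, and a differing human base is a substitution. Columns with
outgroup disagreement, gaps or ambiguity codes are excluded from numerator
*and* denominator, and the exclusion count is reported. A position
polymorphic in humans is counted as polymorphism only, never also as a
substitution. The per-stratum denominator is the count of alignable,
outgroup-concordant positions, making $d_s$ a per-alignable-site rate;
since published per-site normalizations vary, the raw counts are always
emitted so any denominator can be reconstructed.

Two Fisher contrasts follow, both two-sided by the point-probability
convention (the sum over tables with fixed margins whose probability does
not exceed the observed table's — conventions differ, so this is stated):

* **Divergence ratio** — $d_\mathrm{exon}/d_\mathrm{intron}$ on
  `[[sns_e, sites_e - sns_e], [sns_i, sites_i - sns_i]]`;
* **Fixation-rate contrast** — the McDonald–Kreitman-style
  $(\mathrm{SNS_e/SNV_e})/(\mathrm{SNS_i/SNV_i})$ on
  `[[sns_e, snv_e], [sns_i, snv_i]]`.

Purifying selection on exons drives both ratios below one. Zero
denominators leave the ratio undefined (flagged) while the p-value is still
computed. CpG filtering is available as a preprocessing choice but not
applied by default.

## Cross-species expression screen

Genes are kept when detected (count > 0) in at least 40% of samples *and*
averaging at least 5 counts, both inclusive, computed after subsetting to
the iPSC and cardiomyocyte samples. "Detected" as count > 0 is a
configurable definition. Inference is the DESeq2 negative-binomial GLM
(median-of-ratios size factors, trended dispersion shrinkage, Wald test, no
fold-change shrinkage) with species and cell-type factors plus their
interaction; the interaction coefficient is the human-versus-chimpanzee
log2 fold change specific to the iPSC state. Reports use
log2(normalized count + 1) rather than a variance-stabilizing transform —
the transform affects only plotting, not the Wald inference. Expression
percentiles rank size-factor-normalized group means descending with
averaged ties: percentile $= 100\,(r - 0.5)/n$, so the top gene of 100
sits at 0.5 and the median of 101 at exactly 50. One-to-one orthology is
assumed resolved in the input matrix.

## The synthetic-data generator

`simulateDataset()` emulates the full input set on one contig: a two-exon
lncRNA (2,500 exonic, 5,900 intronic bases; the first 60% of exon 1
LTR-derived, mirroring ESRG's HERV-H geometry), a neutral reference region
standing in for synonymous sites, optional extra single-exon lncRNAs for
the screen, a per-base conservation track, a trio alignment, a coverage
table and a two-species count matrix. Defaults are the study conditions of
a gnomAD-scale analysis: n = 31,416 chromosomes projected to m = 30,000,
per-site Watterson theta 0.004 (matching the segregating-site density of
deep human panels — note a constant-size model then overstates pairwise
diversity, see limitations), and human-lineage divergence T = 0.008 per
site.

Polymorphism follows the Poisson random field: per stratum the number of
segregating sites is Poisson with the neutral expectation
$\theta L H(n-1)$; each site's population frequency is drawn from the
Wright stationary density — $\propto 1/q$ when neutral,
$\propto (1-e^{-\gamma(1-q)})/((1-e^{-\gamma})\,q(1-q))$ under scaled
selection coefficient $\gamma$ (the neutral case is the analytic limit,
never an evaluation at $\gamma = 0$) — and the sample count from a
Binomial over the site's called chromosomes, conditioned on being
polymorphic in the sample. Substitutions are placed independently per site
with probability $T$ scaled by the relative fixation rate
$u(\gamma) = \gamma/(1-e^{-\gamma})$; $u(-5) \approx 0.034$. Outgroup
discordance and gap columns are injected at configurable rates so the
parsimony exclusion path is exercised; coverage rows are all-passing by
default with a configurable failing fraction.

**Numerical choices.** The stationary density is non-integrable at
$q = 0$ (it behaves as $1/q$ for any $\gamma$), so sampling uses inverse-CDF
on a truncated, normalized grid over $[1/(100n),\, 1 - 1/(2n)]$ with
10,000 points by default. The grid is *log-spaced*: singletons in a sample
of 30,000 chromosomes arise from population frequencies around $10^{-5}$,
far below the resolution of any practical uniform grid. The truncation
discards alleles essentially never observed even once (relative
singleton-bin loss $\approx n \cdot q_\mathrm{min}$ = 1%); the tests bound
the discretization error by independent quadrature of the density over the
truncated support. Rejection sampling implements the
conditioned-on-segregating draw exactly. For very strong selection
($\gamma < -500$) the density switches to its asymptotic form
$e^{\gamma q}/(q(1-q))$ to avoid overflow. Conservation scores are rounded
to four digits for compact files, with above-threshold draws clamped
strictly above 0.9 so the two mixture components never straddle the
threshold by rounding.

**What the generator does not emulate.** Sites are independent (free
recombination — no linkage disequilibrium, no background-selection
interference); the population has constant size (real human panels carry a
growth-driven excess of rare alleles, which is why theta is calibrated to
segregating-site density rather than pairwise diversity); mutation is
uniform across bases (no CpG hypermutability, no context effects); the
alignment has no indel realism beyond injected outgroup gap columns.
Passing tests therefore demonstrate correctness of the *inference
machinery* under the stated model, not robustness to demography or
mutation-spectrum confounders in real data — demography-aware null models
are an explicit non-goal.

## Pipeline and determinism

`runSelectionAnalysis()` and `runExpressionScreen()` orchestrate the stages
from a single declarative YAML configuration (no positional-argument mode,
so provenance lives in one artifact); `inst/scripts/lncsel-cli.R` wraps
them for shell use with `simulate`/`select`/`expr` subcommands. All
thresholds default to the analysis conditions above. Reports are JSON whose
numbers are the module return values — no recomputation drift — and reruns
with the same configuration and seed are byte-identical, as are generator
outputs under identical parameters.

## Problem sizes in the test suite

Monte-Carlo-heavy properties run at reduced scale chosen to keep each
statistical bound decisive: projections are checked exhaustively up to
`an = 12` and at `m` of 100–1,000 against subsampling oracles; the
chi-squared calibration uses 2,000 replicates at a near-identity projection
(n = 110-ish to m = 100 keeps multinomial variance, which is what makes
the test exactly calibrated — heavy smoothing would make it conservative);
the Fisher calibrations use 200 replicates at count scale; the full
m = 30,000 projection is exercised once per run. Acceptance bounds on
rejection rates are set from binomial sampling theory at those replicate
counts, not from observed runs.

## Known limitations

* Unfolded spectra without ancestral polarization (above).
* Parsimony ancestral inference ignores back-mutation and rate variation;
  columns lost to outgroup discordance are missing not-at-random under
  hypermutability.
* The divergence denominator choice (alignable concordant sites) differs
  from alignment-length or stratum-length conventions; raw counts are
  emitted for re-normalization.
* No multiple-transcript handling beyond explicit transcript choice; no
  splice/UTR strata; no demography-aware neutrality tests or DFE
  inference.
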