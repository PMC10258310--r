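---
title: "Methods: paired-tissue immune repertoire analysis with repsig"
author: "repsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-tissue immune repertoire analysis with repsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsig)
```

## Scope and data model

`repsig` analyses adaptive immune repertoires — T-cell receptor chains
(TRA, TRB, TRG, TRD) and B-cell receptor heavy chains (IGH, isotypes
IgA/IgG/IgM) — sampled as clonotype tables from paired tumor and
adjacent non-tumor tissue of the same patient. The unit of observation
is the clonotype: a rearrangement identity (CDR3 sequence and V/D/J
gene calls) carrying a read/duplicate count. Counts are read weights,
not cell counts, and all abundance-weighted metrics use them as-is; no
depth normalization (rarefaction or subsampling) is applied, because
the comparisons the package targets are within-cohort and depth effects
are probed through simulation instead.

Upstream read processing, alignment and clonotype assembly are out of
scope: the package consumes AIRR Rearrangement TSVs or MiXCR-style
exports. Where an aligner reports several candidate gene calls (comma
separated, optionally with scores) the first, top-scoring call is kept,
and allele suffixes after `*` are dropped, so all analyses run at gene
level.

## Productive filter

A clonotype is productive iff (i) its CDR3 amino-acid length is at
least 4, (ii) its CDR3 nucleotide length is a multiple of 3, and (iii)
it contains no stop codon. Stop detection uses the amino-acid sequence
when present (`*` stop, `_` frameshift marker); otherwise the
nucleotide sequence is translated in frame 0 and scanned for
TAA/TAG/TGA. The filter acts on clonotype records — each record keeps
its count — and is idempotent. Records are filtered rather than reads
because the rules are properties of the rearrangement, not of
individual reads.

## Feature levels

Every repertoire feature is computed at two levels: **CDR3aa** (unique
CDR3 amino-acid sequences) and **VDJ**, defined here as the joint
(V, D, J) gene-segment combination with alleles stripped and an empty D
allowed for chains lacking a D segment. A nucleotide-level
rearrangement definition of "VDJ" would also be defensible; the
gene-combination reading was chosen because gene-usage clustering
operates on exactly those combinations, and both levels are always
emitted so the choice is transparent downstream.

## Diversity and similarity

For clone frequencies $p_1 \dots p_S$, richness is $S$, Shannon
entropy is $H = -\sum_i p_i \ln p_i$ in nats, and evenness is the
normalized Shannon diversity entropy $\mathrm{NSDE} = H / \ln S$
(Pielou's evenness). Natural logarithms are used throughout; the
normalization makes the base irrelevant for NSDE. A single-clone
repertoire has $\ln S = 0$; its NSDE is defined as 0 (maximal
clonality) rather than 0/0, consistent with evenness semantics.

The Morisita–Horn similarity of two profiles with counts $x_i, y_i$,
totals $X, Y$ and Simpson concentrations $d_x = \sum x_i^2/X^2$,
$d_y = \sum y_i^2/Y^2$ is

$$\mathrm{MHSI} = \frac{2 \sum_i x_i y_i}{(d_x + d_y)\, X Y}.$$

It is computed on counts (the index is defined on abundances, and a
presence/absence variant would discard the clonal-expansion signal),
is symmetric, scale-invariant in either profile, bounded in $[0,1]$,
and 0 exactly when the label sets are disjoint.

## Gene-usage ordination

Per-sample segment usage (V, J, or the joint VDJ combination) is the
count-weighted relative frequency over the union of labels across
samples. Ordination is PCA on column-centered — not variance-scaled —
frequencies (rows are compositional and already on a common scale), or
classical metric MDS on Euclidean row distances; on the same centered
matrix the two agree up to per-axis sign, which is fixed by making the
largest-magnitude loading (PCA) or coordinate (MDS) on each axis
positive, so results are fully deterministic.

A note on convergence: the count-weighted usage frequency concentrates
around the generating segment probabilities only when clone abundances
are close to uniform. Under a skewed clone-size law a handful of
expanded clones dominates the weights and the effective number of
independent segment draws is small — an intended property of the
estimator, not a defect, and the reason the package's convergence test
runs at low abundance skew.

## SHM classification and mutated-clone networks

An IGH clone with $\geq 1$ nucleotide mismatch of its V-region
alignment to germline is *mutated*; 0 mismatches is *original*; a
missing mismatch count is *unknown* and excluded from SHM percentages
and networks only (not from diversity), to avoid silently mislabeling
unmutated clones. Percentages are clone-based (unweighted); a
count-weighted variant is available by argument.

The mutated clones of one sample (or of one isotype view) are network
nodes. The edge rule is the standard clonal-lineage relatedness
convention: identical V gene, identical J gene, equal CDR3aa length,
and CDR3aa Hamming distance at most 1 (threshold configurable).
Average degree is $2E/N$ — the number of connections per node divided
by the total number of nodes — and the EXd1 variant removes all nodes
of degree exactly 1 in a single simultaneous pass (degree-0 nodes are
retained, pruning is not iterated) before recomputing it. For a star
lineage with $k$ leaves the closed forms are $2k/(k+1)$ and 0, which
the test suite asserts exactly. Per-isotype and combined-IgH networks
are both computed, since the two views answer different questions
about class-switched lineages.

## Cohort statistics

Group comparisons follow the two-sided, $\alpha = 0.05$ convention.
The Wilcoxon signed-rank test drops zero differences, midranks tied
absolute differences, and for $n \le 12$ computes the exact two-sided
p-value by enumerating all $2^n$ sign assignments; because the null
distribution is symmetric about $n(n+1)/4$ even under ties, the
two-sided p is the probability of a statistic at least as far from
that center as observed. Larger samples use the normal approximation
with tie correction and a 0.5 continuity correction. The Mann–Whitney
U test mirrors this with enumeration over all
$\binom{n_a+n_b}{n_a}$ group assignments for pooled sizes
$\le 12$. These exact branches are authored rather than delegated
because the standard implementations fall back to approximations in
the presence of ties precisely where small repertoire cohorts need
exactness; the tie-free cases are cross-checked against
`stats::wilcox.test` in the test suite.

Spearman's correlation is the Pearson correlation of midranks with a
t-approximate p-value. Categorical tables route to Fisher's exact test
(two-sided by the point-probability rule, as in `stats::fisher.test`)
when any expected cell count is 5 or less, and to Pearson's chi-square
without continuity correction otherwise; the boundary is inclusive so
that canonical 2×2 examples with expected counts exactly 5 are handled
exactly. No multiplicity correction is applied by default;
Benjamini–Hochberg is available by flag.

Survival stratification dichotomizes a numeric repertoire feature at
the cohort median — ties go to the "low" group, making the split
deterministic; the cutpoint is configurable — then fits Kaplan–Meier
product-limit curves per group and compares them with the two-group
log-rank test (`survival::survfit` / `survdiff`). With zero events the
curves are still returned and the p-value is `NA`. Missing values are
deleted pairwise per test and the effective $n$ is reported in every
result.

## The synthetic cohort generator

The generator exists so that every stage has inputs with known ground
truth. Its defaults describe a resected hepatocellular-carcinoma-like
cohort: clinical category frequencies follow the printed composition
of a 64-patient cohort (55 male; age bands 11/39/14 for <40, 40–60,
>60 years; 33 advanced-stage; 35 with recurrence and 5 unknown);
survival is exponential with median overall survival 60 months and
independent exponential censoring with median 96 months — values
chosen once as clinically realistic, since the source tables print
frequencies but not rates. The stratifying repertoire feature
multiplies the hazard of above-median patients by
`feature_hazard_ratio` (default 0.4) for every endpoint.

Repertoire samples draw clone identities by V(D)J recombination from
per-chain segment pools, with CDR3aa sequences starting at the
canonical cysteine and lengths from a discretized normal peaked at 14
residues. Abundances follow a Zipf rank-size law,
$p_i \propto i^{-\alpha}$ (default $\alpha$ 1.2 in tumor, 1.0 in
non-tumor, reflecting stronger intratumoral clonal expansion), with
deterministic masses $\max(1, \mathrm{round}(N p_i))$ by default:
this makes parameter-recovery relationships (NSDE strictly decreasing
in $\alpha$; MHSI strictly increasing in the shared fraction, exactly
0 at no sharing and exactly 1 at full sharing with equal skew) hold
deterministically rather than in expectation. Multinomial resampling
noise is available by configuration. Sharing is implemented at the
label level with rank alignment — a nested random subset of clone
ranks copies the paired sample's clone identity at the same rank — so
the index responds to both support overlap and abundance correlation,
and non-shared clones are rejection-sampled against the partner's
label space so that zero sharing yields exactly disjoint supports.

SHM structure is overlaid on IGH samples: each clone is mutated with
probability `mutation_prob`; mutated founders get $1+$Poisson V
mismatches and spawn a star lineage of geometric size whose members
differ from the founder at exactly one CDR3aa position each, at
pairwise-distinct positions — so descendants sit at Hamming distance 2
from each other and the resulting network component is exactly a star,
with closed-form degree statistics. Lineages descend from productive
founders only, keeping the generator's nonproductive manifest exactly
equal to the productive filter's removal set. Star topologies (rather
than trees) are the default because they admit exact expectations;
note that with descendants appended, the mutated fraction of all
clones is $pm/(1-p+pm)$ for mean lineage size $m$, so recovery checks
of the per-clone mutation probability itself are run at lineage size 1.

All randomness flows from one master integer seed through string-keyed
substreams (patient, tissue, chain, stage), so identical configurations
are byte-identical on disk and adding patients or chains never perturbs
existing samples.

What the generator does **not** emulate: sequencing error and PCR
amplification bias, isotype class-switch dynamics, germline allele
variation, convergent (public) clonotypes beyond the configured
sharing, and any real dependence structure between repertoire features
and clinical covariates beyond the injected survival effect and the
covariate correlation. Passing recovery tests therefore demonstrates
the correctness of the estimators under the stated generative model,
not the biological conclusions one would draw from patient data.

## Problem sizes and numerical choices

The test and validation suites run at sizes chosen to make sampling
bounds sharp while keeping the suite fast: 500–2000 clones per sample
for recovery checks (binomial ±3-point bounds at $n = 2000$), 1000
random profiles for metric invariants, 200 random small-sample cases
against enumeration oracles, and 100 replicate cohorts of 200 patients
for log-rank power (injected hazard ratio 0.4) and size (ratio 1.0).
Exact-test enumeration is capped at $n \le 12$ (4096 sign patterns /
924 splits), beyond which corrected normal approximations take over.
Floating-point oracle comparisons use $10^{-12}$ tolerances; the
enumeration two-sided rules include a $10^{-12}$ slack on the "at
least as extreme" comparison to absorb midrank rounding.

## Pipeline and interfaces

`run_pipeline()` executes simulate/read → filter → diversity →
similarity → SHM → cohort comparisons → survival, writes tidy TSVs and
a JSON run manifest (seed, per-stage row counts, output checksums),
and aborts on the first failing stage naming it. The R functions are
the primary interface; `inst/scripts/repsig.R` wraps the simulator and
pipeline for shell use. Stage outputs are pure functions of
(inputs, config, seed); the test suite asserts checksum-identical
reruns.

## Known limitations

- Diversity metrics are depth-sensitive; with no rarefaction, strongly
  unequal sequencing depths between paired samples can bias NSDE and
  MHSI comparisons. The simulator can probe this, but the package does
  not correct for it.
- The clonal-lineage edge rule (distance ≤ 1) is a convention; real
  lineages with larger divergence fragment into several components,
  deflating average degree.
- Exact tests are exact only within the enumeration range; midrank
  normal approximations are known to be slightly conservative at
  moderate $n$ with heavy ties.
- The median split is a declared analysis choice, not an inferred
  optimal cutpoint; optimal-cutpoint selection would require
  multiplicity control the package deliberately avoids.
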