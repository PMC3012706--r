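---
title: "Expression profiling for de novo transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression profiling for de novo transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Locusts switch between a solitary and a gregarious phase from one genome;
the transcriptome differences behind that polyphenism were measured by
short-read RNA-seq against a de novo assembled transcript catalog — no
reference genome, no isoform annotation. That setting breaks the two
standard quantification conveniences: multi-mapping reads cannot be
resolved positionally, and redundant contigs (isoforms, alleles, recent
paralogs) fragment read counts. `locustra` reimplements the analysis
pipeline for that setting as tested, reusable components, and ships a
synthetic-data generator with known ground truth so every stage can be
validated end to end.

The experimental design emulated throughout is 2 phases x 6 developmental
stages (egg; 1st+2nd, 3rd, 4th, 5th instar; adult) = 12 libraries, with
the two 4th-instar libraries ("G4", "S4") sequenced about 20x deeper than
the rest.

# Pipeline stages and their models

## Sequence clustering (`build_clusters`)

A self-to-self similarity search yields pairwise matches; an edge is kept
when the overlap ratio and identity both strictly exceed their
thresholds, and clusters are single-linkage connected components
("overlap to *any* sequence"). Two presets: gene-set deduplication
(overlap > 0.60, identity > 0.96) and expression clustering
(overlap > 0.80, identity > 0.96). The identity floor separates
paralogy from alternative splicing; the overlap thresholds were
calibrated against isoform-pair overlap quantiles in a well-annotated
insect genome.

Two details the printed rules leave open, recorded here as configurable
decisions: the overlap-ratio denominator is the *shorter* sequence (a
contained isoform then scores near 1, which is what the quantile
calibration presumes; `denominator = "longer"` is available), and
linkage is single (components), the natural reading of "to any
sequences". The representative of a cluster is its longest member, ties
broken by smallest id, and its id doubles as the cluster id.

## Cluster-aware read counting (`assign_reads`)

Counting unit = cluster or singleton transcript. A read whose hits all
fall inside one unit contributes exactly one count to that unit; a read
whose hits span two or more units is discarded. The per-library total
mapped reads N counts assigned reads only, so no read is ever counted
twice. Whether the original analysis credited an intra-cluster multiread
to every member it hit or once per cluster is not stated anywhere;
unit-level counting was chosen because it keeps N a true read count.
Member transcripts inherit their cluster's count for reporting and are
normalized by their own length.

"Expressed"/"detected" means assigned count >= 1 throughout (marker
screens, lane-detection summaries, the PCA filter); no RPKM floor is
imposed anywhere because none is defined for the pipeline.

## Normalization (`tmm_factor`, `effective_size`, `rpkm_matrix`)

Relative-abundance scaling uses the trimmed mean of M-values (TMM):
units zero in either library are excluded, M = log2 ratio of relative
abundances, A = mean log2 abundance, double trimming (30% per tail on
M, 5% on A), and an inverse-asymptotic-variance weighted mean of the
surviving M values; the factor is 2^mean. The solitary egg library is
the reference. Factors are renormalized to log-mean zero across
libraries (the published convention; whether the original analysis did
so is unstated — the choice shifts all factors by one constant and is
recorded in the normalization table).

The effective library size is N_eff = N * sqrt(f). The square root is
unusual — the common convention multiplies by f directly — but it is
the stated rule of the pipeline being reimplemented, so it is applied
exactly. RPKM = count / ((length/1000) * (N_eff/1e6)).

## Differential expression (`audic_test`, `call_dets`)

The Audic–Claverie posterior gives, for a transcript sampled x times in
a library of N1 mapped reads, the probability of y counts in a library
of N2 reads under equal expression:

p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)),  r = N2/N1

— a negative binomial in y with size x+1 and success probability
1/(1+r). Two modifications adapt it to RNA-seq on a de novo catalog:

1. **Length normalization.** Expected counts scale with transcript
   length, so x and y enter as mapped reads *per kilobase*.
2. **Smallest-library rescaling.** In a series of pairwise comparisons,
   deeper pairs would otherwise carry more statistical weight at the
   same relative effect; N1, N2, x and y are all rescaled to the
   smallest library of the series (N_min), after which r = 1. For a
   single pairwise comparison N_min defaults to min(N1, N2).

The rescaled x, y are real-valued; tails use the continuous extension
of the negative-binomial CDF via the regularized incomplete beta
function, evaluated in log-stable form by `pbeta`. The two-sided
p-value doubles the smaller of the two direction-specific tails, each
tail inclusive of the observed value and computed in its own
conditioning direction:

p = min(1, 2 min(P(Y >= y | x), P(X >= x | y)))

This construction was chosen over the textbook "double the smaller tail
of one conditional" because the latter is *not* symmetric under
swapping the libraries (at x=0, y=1, r=1 it gives 1 vs 1/2 depending on
order); the two-direction form is exactly symmetric, reduces to p = 1
when the normalized counts are equal, and reproduces the closed-form
checks (e.g. p = 0.25 for 0 vs 3 counts at equal sizes).

Calls require both FDR (Benjamini–Hochberg) below the cutoff and fold
change (ratio of TMM-adjusted RPKM) above it: FDR < 0.01 and fold > 2
for single-lane pairs, FDR < 1e-5 for the deep pair, where the larger
sampling size makes tiny relative differences statistically significant.
Units with zero counts in both libraries are untestable and excluded;
when exactly one side is zero, a pseudo-RPKM (default 1e-3) is added to
both sides of the ratio so presence/absence units remain callable.

The test models Poisson sampling. Its validation simulations therefore
use Poisson counts (dispersion 0): the null/type-I simulation by
construction, and the 4-fold power simulation for consistency — with
biological overdispersion the statistic is anticonservative, which is a
property of the method being reimplemented, not a defect of the
implementation.

## Phase-marker screens (`specific_markers`, `stable_markers`)

*Phase-specific*: detected in >= 5 of 6 stages of one phase and
undetected in >= 4 of 6 stages of the other. *Stable-difference*, over
the 5 post-egg stages (eggs excluded as printed): coefficient of
variability (sd/mean) < 0.3 within a phase group, phase mean ratio
> 1.5, Welch two-sample t-test p < 0.05. "t test" is implemented as
Welch's (unequal variances), the safe default at n = 5 per group.

The printed CV clause joins the two phases with an ambiguous "or". Both
readings are implemented (`cv_mode = "both"` / `"either"`); the package
default is "both" (a marker wildly varying in one phase contradicts the
screen's purpose). The recovery simulations run the literal "either"
reading, for a quantitative reason: negative-binomial noise at
dispersion 0.05 puts a floor of sqrt(0.05) ≈ 0.22 on the count CV, so
the sample CV from 5 stages exceeds 0.3 in at least one phase roughly a
third of the time no matter how deeply one sequences — under the "both"
reading the screen's recall saturates near 0.65 at that noise level,
under the literal reading it clears 0.9. The ambiguity materially
changes the screen and deserves exactly this documentation.

## Enrichment (`enrich_test`, `enrich_scan`)

For each term, a 2x2 table contrasts the gene list against the
background *minus* the list (the GOstat construction — the list must
not contaminate its own reference): list-in-term, list-not-in-term,
rest-in-term, rest-not-in-term. Pearson chi-square (1 df, no continuity
correction) approximates the p-value; when any expected cell is below 5
the two-sided Fisher exact test (point-mass rule) is used instead.
Raw p-values are reported at p < 0.01 with no cross-term correction,
matching the reporting convention reimplemented here; BH adjustment is
available behind an explicit flag. Two-sided testing with a direction
flag is used since sidedness was never stated.

## Library PCA (`pca_libraries`)

Transcripts expressed in fewer than six libraries are filtered; each
surviving transcript is standardized to zero mean, unit variance across
libraries; the eigen-decomposition is taken on the 12x12 library
covariance of the standardized matrix — mathematically equivalent to
the transcript-space formulation (standardization makes covariance
equal correlation) and far cheaper when transcripts vastly outnumber
libraries. Libraries get scores, transcripts loadings. Components are
sign-fixed (largest-magnitude loading positive) for determinism.
Zero-variance transcripts are dropped (standardization undefined);
"expressed" means count >= 1, which under this RPKM definition is
identical to RPKM > 0.

## Assembly QC (`length_stats`, `coverage_eval`, `chimera_flags`)

N50 = length at which the descending cumulative length first reaches
half the total. Length bins are the mutually exclusive report rows
[100,500), [500,1000), [1000,2000), [2000,∞); the assembler's minimum
reported length is 100 bp and any shorter input counts in the first bin
so bins always sum to the total. Coverage evaluation reports, per
reference, the fraction of bases at depth >= d (default 2) with a
strict qualifying threshold (default > 0.9), and a pooled mismatch rate
= mismatches / covered bases, where "covered" means depth >= 1 — the
depth threshold applies to the qualifying fraction only (the printed
procedure is ambiguous on this point; both readings differ only in the
denominator and the choice is documented here). Chimera candidates are
sequences with >= 2 distinct subject proteins each passing identity
> 0.3, e-value < 1e-10, score > 200; no positional condition is
imposed because none was stated. Intervals are 1-based inclusive.

# The synthetic-data generator

`simulate_inputs()` produces a complete input bundle with known truth.
What it emulates, and the defaults chosen as the package's study
conditions:

* **Catalog**: 1,600 singletons + 100 clusters (sizes 2–4, members
  chained by matches that pass the expression preset), lengths
  log-normal around ~800 bp, floored at 100 bp.
* **Depth**: shallow libraries 80,000 mapped reads, the deep 4th-instar
  pair 20x more. The shallow figure was calibrated to the real study's
  reads-per-transcript (~3M single-lane reads over ~73k transcripts
  ≈ 40 reads per transcript; 80,000 over ~2,000 units preserves that
  ratio at desk scale).
* **Counts**: negative binomial with variance mu + phi mu^2
  (phi = 0.05 by default; phi = 0 is Poisson; `noiseless = TRUE` gives
  rounded means for exact-recovery checks).
* **Phase DE**: 10% of units at fold 4, direction split between
  phases; under the default "increasing" profile the fold grows
  geometrically from 1 at egg to the full value at adult, emulating
  the finding that phase divergence grows with development.
* **Stage effects**: 30% of units carry per-stage log-normal
  multipliers (sd 1) shared by both phases — the developmental signal
  that dominates the library PCA, as in the real data.
* **Markers**: planted phase-specific (zero mean in the other phase)
  and stable-difference units (constant ratio 3). Marker units draw
  abundance floored at the distribution median — a marker below the
  detection limit is undefined — and carry no stage effect, since the
  screens define markers as development-stable.
* **Composition bias**: 10 units at 50x abundance in one phase, the
  canonical TMM stressor.
* **Multi-mapping**: 30% of reads from multi-member clusters gain a
  second in-cluster hit; 2% of reads gain a spurious cross-unit hit.
* **Annotation**: 50 uniform terms plus one planted term whose member
  sampling up-weights DE units 4-fold.

What it does **not** emulate: base-level read sequences and quality
scores, positional coverage bias, GC/length-dependent efficiency,
correlated biological replicates, or hierarchical term structure.
Passing tests therefore demonstrate the pipeline's statistics operate
correctly under their own model assumptions — not that those
assumptions hold for any particular real dataset.

# Numerical choices

* All count-test tails are computed through `pbeta` (regularized
  incomplete beta), accurate deep into the tails; the suite checks
  closed form against direct summation to 1e-9.
* TMM shortcut: if every usable M value is identical (proportional
  libraries) the factor is returned exactly, avoiding trimming noise.
* Ties in cluster representatives resolve to the lexicographically
  smallest id; PCA component signs are fixed by the largest loading;
  both make outputs order-independent and reproducible.
* Degenerate inputs error early and loudly: empty catalogs, all-zero
  tables, missing lengths, out-of-bounds intervals, N_min larger than
  the smaller library.
* Every generator stage takes a single integer seed; a fixed seed gives
  byte-identical TSV bundles across runs.

# Problem sizes in the validation suite

The suite's simulations are sized to be decisive yet quick: 5,000-unit
null and power pairs over 10 seeds for the DE operating
characteristics, 2,000-unit catalogs over 10 seeds for marker recovery,
100 replicates for enrichment power, 200-node graphs against the
union-find oracle, 1,000 random length sets for the assembly oracles,
and two full 12-library end-to-end runs compared byte for byte.

# Known limitations

* The Audic–Claverie statistic assumes Poisson sampling; with
  overdispersed biological replication it is anticonservative. This is
  faithful to the reimplemented pipeline; a dispersion-estimating GLM
  is deliberately out of scope.
* Unit-level counting cannot apportion reads among cluster members;
  member RPKM values within a cluster share one count.
* The enrichment scan treats terms as flat labels; no ontology-graph
  propagation.
* The stable-marker screen's CV rule is ambiguous in its source; both
  readings ship, and they differ materially under realistic noise (see
  the marker section).
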