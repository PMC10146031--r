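---
title: "Information scale correction for mixed-length amplicon meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information scale correction for mixed-length amplicon meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Meta-analyses of marker-gene surveys (here, the eukaryotic 18S rRNA v4
region) pool datasets produced with different primer pairs. Different
primers cut different windows of the same gene: published v4 amplicons
range from 344 bp to 720 bp depending on the primer positions. Because
denoised amplicon sequence variants (ASVs) are exact sequences, two
datasets that sequenced different windows share *no* ASVs even when they
sampled the same organisms, and community comparisons between them saturate
at maximal dissimilarity. This difference in *information scale* is a batch
effect. The remedy implemented here — information scale correction (ISC) —
trims every read to one common sub-region before ASV analysis, so that all
datasets carry the same information scale.

`iscr` implements the full loop: a nucleotide profile hidden Markov model
(HMM) locates the sub-region in reads without relying on primer sequences;
the detected window is excised; ASV tables are rebuilt; and a set of
ordination-based statistics decides whether the correction improved
cross-dataset comparability without over-correcting.

## The sub-region model

`build_profile()` turns a multiple alignment of the target sub-region into
a profile HMM over `{A,C,G,T}`:

* Columns with non-gap occupancy of at least `match_fraction` (default 0.5)
  become match states; residues in the remaining columns are insertions
  attached to the preceding match state.
* Match and insert emissions are Laplace-smoothed column frequencies,
  `(count + pseudocount) / (total + 4 * pseudocount)` with `pseudocount = 1`.
* Transitions are counted from each row's implied state path, with the same
  additive pseudocount over the full `{M,I,D} x {M,I,D}` set per node, so
  every outgoing distribution is proper.
* The background is uniform; all scoring is log2-odds against it, i.e. bit
  scores.

`viterbi_glocal()` aligns a read *glocally*: globally with respect to the
traversed stretch of the model, locally with respect to the read. Flanking
read sequence outside the hit is free (emitted at background, log-odds 0).
Entry and exit may be internal match states: a total probability mass
`skip_mass = 0.01` is spread uniformly over internal entry (and exit)
points. This matters because datasets whose amplicon is *shorter* than the
modeled region can only cover part of the model; a model-global aligner
would reject exactly the reads the correction most needs to keep. Ambiguous
bases (`N` and the other IUPAC codes) emit at background, so they neither
reward nor penalize a path.

`search_reads()` runs the aligner on both strands of every read (ties go to
`+`), reports at most one hit per read, and keeps hits with at least
`min_bits = 20` bits. The threshold is a package default, not an inference
from any published setting: at v4-like lengths it separates true amplicons
from shuffled sequence by a wide margin, and it is exposed as an argument
(and a CLI flag) for other regions. No E-value calibration is attempted;
thresholding is on bit scores only. `run_isc()` additionally requires a hit
to span at least `min_model_cov = 0.5` of the match states before excising,
so that accidental micro-hits are not promoted to "corrected reads".

The Viterbi kernel is exact: the test suite checks it against brute-force
enumeration of every legal path on hundreds of small random models, and
checks strand symmetry of best-of-both-strands scores to the last bit.

## ASV reconstruction

The denoiser follows the published UNOISE abundance-skew rule. After
dereplication (`dereplicate()`, size-sorted, ties broken lexicographically),
a greedy pass over the uniques joins a candidate of size `s` to a centroid
of accumulated size `c` at edit distance `d` iff `s/c <= 1 / 2^(alpha*d + 1)`
with `alpha = 2`; a candidate that joins nothing founds a centroid iff its
size reaches `minsize = 8`. The nearest eligible centroid wins; distance
ties go to the larger centroid. Pairs at distance greater than 10 are never
joined — the skew threshold at `d = 10` is below 1e-6, so such joins are
impossible at plausible sizes, and the cutoff lets the implementation use a
banded edit-distance kernel. No chimera filtering is performed; the
simulator produces no chimeras.

`map_reads()` assigns each read to the highest-identity ASV with identity
`1 - d / max(length)` of at least `min_identity = 0.97`, ties going to the
more abundant ASV; reads below the floor stay uncounted.

For evaluation, `paired_abundance_tables()` pools the pre- and
post-correction reads of all samples under comparison and denoises them
*once*, mirroring an abundance table whose columns are samples before and
after correction: both arms are counted in one common ASV space, which is
what makes their ordinations commensurable.

## Evaluation statistics

Given paired pre/post tables, `evaluate_correction()` computes:

* Bray–Curtis dissimilarities, `BC(x,y) = 1 - 2 * sum(min(x_i, y_i)) /
  (sum x + sum y)`;
* an NMDS embedding (Kruskal stress-1, monotone regression on ranks, best
  of 20 random starts, seeded);
* a symmetric Procrustes superimposition of the pre and post
  configurations: both are centered and scaled to unit sum of squares, the
  rotation comes from the SVD of `X'Y`, and the goodness-of-fit is
  `M2 = 1 - (sum of singular values)^2`, with a permutation p-value
  `(1 + #{permuted M2 <= observed}) / (1 + permutations)` (999 permutations
  by default, so the p floor is 1/1000);
* the pre-treatment medoid `m` (PAM with k = 1: the sample minimizing the
  summed Euclidean distance to all samples, lowest index on ties);
* per-sample correction effectiveness `delta_e = d(m, post) - d(m, pre)`,
  negative when the sample moved toward the medoid — i.e. similarity
  improved;
* a two-sided one-sample t-test of the `delta_e` vector against zero, and
  the convergence fraction (share of samples with `delta_e < 0`).

Group-level summaries use `E-bar(g1, g2) = mean(dE_g1) - mean(dE_g2)`
(rows of the pairwise matrix are `g1`), with a Welch two-sample t-test per
pair; a literal paired test is impossible between groups of unequal size.
Stars encode raw p-values (`*** < 0.001`, `** < 0.01`, `* < 0.05`,
`. < 0.1`); a Holm adjustment is available behind a flag but off by
default, matching how such matrices are usually displayed.
`length_effect_correlation()` correlates (Spearman) the absolute
window-length difference of each group pair with the pair's `E-bar`
oriented longer-minus-shorter, so that stronger correction of larger scale
differences appears as a negative correlation.

### Joint versus separate ordination

The two arms can be ordinated separately and merged by Procrustes, or
ordinated jointly (all pre and post columns in one NMDS) with the
Procrustes statistic computed between the two subconfigurations. The
*joint* mode is the default, for a structural reason. Pre-correction
tables of scale-discordant dataset pairs have fully disjoint ASV support,
so every between-dataset Bray–Curtis value is exactly 1. A rank-based NMDS
of such two-block data admits a degenerate zero-stress optimum in which
each block collapses to a point (the monotone fit absorbs all within-block
rank structure into a constant), and with many random starts the optimizer
reliably finds it. The collapsed configuration carries no internal
geometry, the Procrustes correlation vanishes, and `delta_e` cancels
antisymmetrically between the two datasets — the statistic dies. In the
joint ordination, the samples whose scale is unchanged anchor the two arms
in one space (their pre and post columns are nearly identical), so the
scale-discordant block's convergence after correction is measured against
a stable frame. The separate mode remains available
(`ordination = "separate"`) for data whose pre-tables genuinely share
support.

`delta_e` can also be measured directly on Bray–Curtis values rather than
embedded coordinates; the coordinate route is the default because the
medoid and distances then live in the same 2-D space that the standard
ordination overlay displays.

## What the simulator emulates — and what it does not

`make_family()` builds a sub-region family by mutating an ancestral region
independently per taxon (substitutions at per-site rate 0.10, single-base
indels at 0.01, both recorded so the true alignment is known) and attaches
conserved flanks (divergence/5, no indels). At divergence 0.10 the expected
pairwise region identity is `(1-d)^2 + d^2/3 = 0.813`, which the test suite
verifies by simulation. `simulate_sample()` draws taxon abundances
log-normal (`sigma = 1.5`, a realistic rank-abundance curve), read counts
multinomially, slices each template at a primer-window offset, and applies
independent per-base substitution errors (0.005). Indel sequencing error is
deliberately absent by default so that true region coordinates stay exact;
substitution-only error is also the regime in which coordinate-recovery
tests are meaningful.

`make_category_bundle()` realizes the four study conditions: every sample
index is one community realization observed through four windows — `Same`
(the region itself), `Near` (a matched-window replicate dataset), `Short`
(73 bp inside the region), and `Long` (160 bp into the conserved flanks).
Two design points deserve emphasis:

* **The `Near` group is a built-in true null.** With exact-sequence ASVs
  and shallow synthetic divergence, *any* literal window shift makes the
  pre-correction ASV sets of two datasets fully disjoint — which is itself
  a maximal information-scale batch effect, not a null. A dataset pair for
  which correction genuinely should change nothing must therefore share
  the window and differ only in its error realization. Real "near"
  datasets (window differences of a few bases at real community diversity)
  approximate this condition; the simulator constructs it exactly.
* **Bundle reads are orientation-consistent** (`rc_prob = 0`), as merged
  paired-end amplicon reads are in practice. If half the raw reads were
  stored reverse-complemented, dereplication would split every taxon into
  two orientation ASVs in the *pre* arm only (the corrected arm is
  canonically oriented by the model), forcing `BC(pre_i, post_i) = 0.5`
  even for identical windows — a spurious arm-level batch effect that real
  data does not have. Strand-flipped reads remain the default of
  `simulate_sample()` and exercise the strand-aware search in the unit
  tests.

The simulator does **not** emulate chimeras, PCR/primer bias, quality-score
structure, homopolymer indel error, or phylogenetically structured
divergence; and within a group, sample communities are independent
log-normal draws rather than an environmental gradient. Passing tests on
this generator therefore demonstrate that the machinery measures what it
claims under controlled scale differences — not that any particular real
dataset pair will show a particular effect size.

## Problem sizes and determinism

The packaged simulation study runs at 40 taxa, a 380 bp region with 200 bp
flanks, 20 samples per category, and 300 reads per sample — small enough
that the full pipeline (two bundle corrections, pooled denoising, pair and
four-group evaluations) completes in minutes on one core, while still
giving the group tests n = 20 per category and the correlation its six
pairs. `simulate_sample()` itself defaults to the study-scale depth of
10,000 reads.

Every stochastic step (resampling, simulation, NMDS starts, permutation
tests) flows from an explicit seed; the same seed reproduces the same
bundle byte for byte. The CLI logs the seed of every run to stderr.

## Known limitations

* The `Short` category can only ever be corrected to its own window (73 bp
  inside the region); after correction it still occupies a separate exact-
  sequence ASV space. The correction statistics reflect this honestly
  (near-zero `E-bar` against other categories), which matches the
  observation that amplicons much shorter than the target region are
  better treated as the baseline or excluded.
* Procrustes `M2` is scale-free by construction (both configurations are
  normalized), so a uniform contraction of the community cloud is
  invisible to it; directional claims rest on `delta_e`, not on `M2`
  alone.
* The one-sample t-test treats per-sample `delta_e` values as independent;
  in the joint ordination they share one embedding, so p-values should be
  read as descriptive strength-of-evidence, as is usual for
  ordination-derived statistics.
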