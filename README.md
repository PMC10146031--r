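# iscr — information scale correction for mixed-length amplicon meta-analysis

Marker-gene meta-analyses pool datasets that sequenced the *same* gene with
*different* primer pairs. For the eukaryotic 18S rRNA v4 region, published
amplicon windows range from 344 bp to 720 bp. Because denoised amplicon
sequence variants (ASVs) are exact sequences, two datasets that cut
different windows share no ASVs at all — their Bray–Curtis dissimilarities
saturate at 1 regardless of how similar the underlying communities are.
This *information scale* difference is a batch effect, and it grows with
the length difference between amplicons.

`iscr` removes it by **information scale correction (ISC)**: a nucleotide
profile hidden Markov model, trained on a multiple alignment of the target
sub-region, locates the sub-region in every read by glocal Viterbi
alignment (global in the model with internal entry/exit, local in the read
with free flanks, log2-odds scoring against a uniform background) and the
detected window is excised. All datasets then carry the same sub-region and
become comparable. Unlike in-silico PCR, no primer sequences are needed, so
reads with degraded or missing primer regions are still recovered.

The package also implements the downstream evaluation machinery used to
decide whether a correction helped:

* dereplication + UNOISE-style denoising (skew rule
  `beta(d) = 1 / 2^(alpha*d + 1)`, `alpha = 2`, `minsize = 8`) and
  abundance-table construction in a common pre/post ASV space;
* Bray–Curtis / NMDS ordination, symmetric Procrustes superimposition with
  `M2 = 1 - (sum of singular values)^2` and a permutation test;
* the pre-treatment medoid `m` (PAM, k = 1) and per-sample correction
  effectiveness `dE = d(m, post) - d(m, pre)` (negative = the sample
  converged toward the medoid), tested against 0;
* group-level mean effectiveness `Ebar(g1, g2) = mean(dE_g1) - mean(dE_g2)`
  with Welch tests and significance stars, and the Spearman correlation
  between window-length differences and `Ebar`;
* a fully seeded simulator (`make_category_bundle()`) producing shared
  communities observed through `Same` / `Near` / `Short` / `Long` primer
  windows, so the whole pipeline is testable offline.

See the vignette (`vignettes/information-scale-correction.Rmd`) for the
model details, defaults, and design rationale.

## Worked example

Train a model on a simulated sub-region family, observe one sample through
a "Long" window (60 bp extra flank on each side), and correct it:

```r
library(iscr)

fam   <- make_family(n_taxa = 25, region_len = 300, flank_len = 150, seed = 11)
model <- build_profile(fam$msa)
model
#> Profile HMM: 300 match states

raw <- simulate_sample(fam, window = c(60, 60), depth = 400,
                       error_rate = 0.005, seed = 12)
res <- run_isc(list(marine_a = raw$records), model)
res$report[, c("sample_id", "n_before", "n_after", "sensitivity",
               "len_median_before", "len_median_after")]
#>   sample_id n_before n_after sensitivity len_median_before len_median_after
#> 1  marine_a      400     400           1               419              299

asvs <- denoise(dereplicate(res$samples$marine_a))
nrow(asvs)
#> [1] 4
head(asvs$size, 5)
#> [1] 107  44  24  20
```

All 400 reads were detected (sensitivity 1) and the 419 bp amplicons were
trimmed to the 299–300 bp modeled sub-region — the information scale the
other windows can be corrected to as well. Denoising the corrected sample
recovers the community's abundant taxa as ASV centroids with their read
counts (the remaining taxa fall below the `minsize = 8` founding threshold
at this sequencing depth).

Paired pre/post evaluation on a full four-category bundle looks like:

```r
bundle  <- make_category_bundle(n_samples_per_group = 20, seed = 202)
model   <- build_profile(bundle$family$msa)
samples <- do.call(c, unname(bundle$groups))
isc     <- run_isc(samples, model)

ids  <- bundle$meta$sample_id[bundle$meta$group %in% c("Long", "Same")]
tabs <- paired_abundance_tables(samples[ids], isc$samples[ids])
evaluate_correction(tabs$pre, tabs$post, permutations = 199, seed = 71)
#> ISC evaluation over 40 samples
#>   Procrustes M2 = 0.927627 (permutation p = 0.04)
#>   mean delta_e = -0.4998 (t-test p = 2.366e-07)
#>   convergence: 72.5% of samples moved toward the medoid
```

The Long-window samples, maximally dissimilar from the Same-window samples
before correction, converge toward the pre-treatment medoid after ISC
(negative mean `delta_e`, 72.5% of samples closer). Running the same
evaluation on the matched-window null pair (`Near` vs `Same`) gives
`M2 = 9.4e-11` with a non-significant `delta_e` test — the correction
changes nothing where nothing should change.

A thin command-line front end over these functions ships in
`inst/scripts/isc` (subcommands `build-hmm`, `extract`, `asv`, `evaluate`,
`simulate`; all flags logged with the RNG seed to stderr).

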