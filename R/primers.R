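# The primer catalog: one row per dataset giving the primer pair, the
# 1-based inclusive coordinate window the pair amplifies on the reference
# gene, and the dataset's sample size. A catalog for eleven published 18S
# rRNA v4 primer sets ships with the package (see `primer_catalog()`).

catalog_cols <- c("group_id", "forward", "start", "reverse", "end",
                  "sample_size")

#' Read a primer catalog TSV
#'
#' Columns: `group_id`, `forward`, `start`, `reverse`, `end`, `sample_size`.
#' Coordinates are 1-based inclusive positions on the reference gene.
#'
#' @param path path to the TSV.
#' @return a data.frame catalog.
#' @export
read_primer_catalog <- function(path) {
  x <- read.delim(path, colClasses = c(group_id = "character",
                                       forward = "character",
                                       reverse = "character"))
  if (!all(catalog_cols %in% names(x)))
    stop("primer catalog must have columns: ",
         paste(catalog_cols, collapse = ", "))
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("start must be < end (row ", bad[1L], ")")
  if (any(!nzchar(x$forward)) || any(!nzchar(x$reverse)))
    stop("primer strings must be non-empty")
  x
}

#' The packaged 18S rRNA v4 primer catalog
#'
#' Eleven published metabarcoding primer sets for the 18S rRNA v4 region,
#' with amplicon windows ranging from 344 bp to 720 bp.
#'
#' @return a data.frame catalog.
#' @export
primer_catalog <- function() {
  read_primer_catalog(system.file("extdata", "primer_catalog_18s_v4.tsv",
                                  package = "iscr", mustWork = TRUE))
}

#' Amplicon length of a primer window
#'
#' The window is 1-based inclusive, so the length is `end - start + 1`.
#'
#' @param catalog a primer catalog data.frame (or any data.frame with
#'   `start` and `end` columns).
#' @return integer vector of amplicon lengths.
#' @export
amplicon_length <- function(catalog) {
  as.integer(catalog$end - catalog$start + 1L)
}

#' Classify primer windows against a baseline window
#'
#' `Same` means the window coincides with the baseline exactly. Otherwise
#' the amplicon-length difference decides: `Near` when the absolute length
#' difference is at most `threshold_bp`, `Short`/`Long` when the amplicon is
#' more than `threshold_bp` shorter/longer than the baseline.
#'
#' @param catalog a primer catalog data.frame.
#' @param baseline_start,baseline_end the baseline window (defaults: the
#'   most-used v4 window, 564-980).
#' @param threshold_bp length-difference threshold in bp.
#' @return factor with levels `Same`, `Near`, `Short`, `Long`.
#' @export
classify_primers <- function(catalog, baseline_start = 564L,
                             baseline_end = 980L, threshold_bp = 50L) {
  base_len <- baseline_end - baseline_start + 1L
  delta <- amplicon_length(catalog) - base_len
  lab <- ifelse(catalog$start == baseline_start & catalog$end == baseline_end,
                "Same",
                ifelse(abs(delta) <= threshold_bp, "Near",
                       ifelse(delta < 0, "Short", "Long")))
  factor(lab, levels = c("Same", "Near", "Short", "Long"))
}

#' Per-category dataset and sample counts
#'
#' @inheritParams classify_primers
#' @return data.frame with one row per category: `category`, `n_datasets`,
#'   `n_samples`.
#' @export
summarize_catalog <- function(catalog, baseline_start = 564L,
                              baseline_end = 980L, threshold_bp = 50L) {
  lev <- c("Same", "Near", "Short", "Long")
  if (nrow(catalog) == 0L)
    return(data.frame(category = factor(lev, levels = lev),
                      n_datasets = 0L, n_samples = 0L))
  cat_ <- classify_primers(catalog, baseline_start, baseline_end,
                           threshold_bp)
  data.frame(category = factor(lev, levels = lev),
             n_datasets = as.integer(table(cat_)[lev]),
             n_samples = as.integer(tapply(catalog$sample_size, cat_, sum,
                                           default = 0L)[lev]),
             row.names = NULL)
}

#' Depth-harmonize samples: drop shallow ones, downsample deep ones
#'
#' Samples with fewer than `min_reads` reads are removed; samples with more
#' than `cap` reads are downsampled uniformly without replacement to exactly
#' `cap`; samples in between are passed through unchanged. Boundaries are
#' kept: exactly `min_reads` reads survive, exactly `cap` reads are not
#' resampled.
#'
#' @param samples named list of sequence-record data.frames (see
#'   [read_fasta()]).
#' @param min_reads minimum read count to retain a sample.
#' @param cap read count to which deeper samples are downsampled.
#' @param seed integer RNG seed (`NULL` = use the current RNG stream).
#' @return named list of the same shape, filtered/downsampled.
#' @export
filter_and_resample <- function(samples, min_reads = 5000L, cap = 10000L,
                                seed = NULL) {
  with_seed(seed, {
    n <- vapply(samples, nrow, integer(1))
    kept <- samples[n >= min_reads]
    lapply(kept, function(s) {
      if (nrow(s) > cap) s[sort(sample.int(nrow(s), cap)), , drop = FALSE]
      else s
    })
  })
}
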