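# The information-scale-correction step proper: excise the detected
# sub-region from each read so that datasets amplified with different primer
# windows end up on a common information scale.

#' Excise the located sub-region from a read
#'
#' Returns the subsequence `read[read_start..read_end]`; for a `-` strand
#' hit the reverse complement of that window is returned, so all outputs are
#' in model orientation. The record id is preserved.
#'
#' @param record a one-row sequence-record data.frame.
#' @param hit a one-row hit table (see [search_reads()]).
#' @return a one-row sequence-record data.frame.
#' @export
excise <- function(record, hit) {
  stopifnot(nrow(record) == 1L, nrow(hit) == 1L,
            record$id == hit$read_id)
  if (hit$read_start < 1L || hit$read_end > nchar(record$seq) ||
      hit$read_start > hit$read_end)
    stop("hit coordinates out of range for read '", record$id, "'")
  sub <- substr(record$seq, hit$read_start, hit$read_end)
  if (hit$strand == "-") sub <- revcomp(sub)
  new_seq_records(record$id, sub)
}

# Vectorized core used by run_isc (records and hits matched by position).
excise_all <- function(records, hits) {
  sub <- substr(records$seq, hits$read_start, hits$read_end)
  neg <- hits$strand == "-"
  if (any(neg)) sub[neg] <- revcomp(sub[neg])
  new_seq_records(records$id, sub)
}

#' Run information scale correction on a set of samples
#'
#' For every sample, the modeled sub-region is located in each read
#' ([search_reads()]); reads without a hit, or whose hit covers less than
#' `min_model_cov` of the model's match states, are dropped; surviving reads
#' are replaced by their excised sub-region in model orientation.
#'
#' @param samples named list of sequence-record data.frames.
#' @param model an `isc_phmm`.
#' @param min_bits bit-score threshold for a hit.
#' @param min_model_cov minimum fraction of model match states a hit must
#'   span for the read to be kept (partial-coverage reads below this are
#'   dropped rather than excised).
#' @param both_strands search both strands?
#' @param skip_mass see [viterbi_glocal()].
#' @return list with `samples` (the corrected read sets) and `report`, a
#'   data.frame with per-sample read counts before/after, sensitivity, and
#'   min/median/max read length before/after.
#' @export
run_isc <- function(samples, model, min_bits = 20, min_model_cov = 0.5,
                    both_strands = TRUE, skip_mass = 0.01) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  corrected <- vector("list", length(samples))
  names(corrected) <- names(samples)
  rep_rows <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    recs <- samples[[s]]
    hits <- search_reads(model, recs, min_bits = min_bits,
                         both_strands = both_strands, skip_mass = skip_mass)
    cov <- (hits$model_end - hits$model_start + 1L) / model$K
    hits <- hits[cov >= min_model_cov, , drop = FALSE]
    keep <- recs[match(hits$read_id, recs$id), , drop = FALSE]
    out <- excise_all(keep, hits)
    corrected[[s]] <- out
    len_b <- nchar(recs$seq)
    len_a <- nchar(out$seq)
    q <- function(x, f) if (length(x)) f(x) else NA_real_
    rep_rows[[s]] <- data.frame(
      sample_id = names(samples)[s],
      n_before = nrow(recs), n_after = nrow(out),
      sensitivity = if (nrow(recs)) nrow(out) / nrow(recs) else NaN,
      len_min_before = q(len_b, min), len_median_before = q(len_b, median),
      len_max_before = q(len_b, max),
      len_min_after = q(len_a, min), len_median_after = q(len_a, median),
      len_max_after = q(len_a, max))
  }
  list(samples = corrected,
       report = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))))
}
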