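# Dereplication, UNOISE-style denoising and ASV abundance-table
# construction, applied identically to pre- and post-correction read sets.

#' Dereplicate reads into unique sequences
#'
#' @param records a sequence-record data.frame.
#' @return data.frame with columns `seq`, `size` (copy count) and
#'   `exemplar_id` (id of the first read bearing the sequence), sorted by
#'   decreasing size with size ties broken lexicographically by sequence.
#' @export
dereplicate <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(seq = character(0), size = integer(0),
                      exemplar_id = character(0)))
  first <- !duplicated(records$seq)
  size <- as.integer(table(factor(records$seq,
                                  levels = records$seq[first])))
  u <- data.frame(seq = records$seq[first], size = size,
                  exemplar_id = records$id[first])
  u <- u[order(-u$size, u$seq), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' UNOISE-style abundance-skew denoising
#'
#' A single greedy pass over the uniques in descending abundance. A unique
#' of size `s` at edit distance `d >= 1` from an existing centroid of
#' (accumulated) size `c` joins that centroid iff `s/c <= beta(d)` with
#' `beta(d) = 1 / 2^(alpha * d + 1)`; among eligible centroids the nearest
#' wins (distance ties go to the larger centroid). A unique that joins
#' nothing founds a new centroid if `s >= minsize`, otherwise it is
#' discarded from centroid founding. Centroid sizes accumulate joined sizes.
#' Pairs at edit distance greater than `max_dist` are never joined
#' (`beta(10)` is already below 1e-6, making such joins impossible at
#' plausible sizes).
#'
#' @param uniques output of [dereplicate()] (must be sorted by size desc).
#' @param alpha skew-curve steepness.
#' @param minsize minimum size to found a centroid.
#' @param max_dist edit-distance cutoff for join candidates.
#' @return data.frame of ASV centroids with columns `seq`, `size` (own +
#'   absorbed copies), `exemplar_id`, sorted by decreasing accumulated size.
#' @export
denoise <- function(uniques, alpha = 2.0, minsize = 8L, max_dist = 10L) {
  n <- nrow(uniques)
  cen_seq <- character(0)
  cen_size <- numeric(0)
  cen_ex <- character(0)
  for (i in seq_len(n)) {
    s <- uniques$size[i]
    sq <- uniques$seq[i]
    pick <- if (length(cen_seq))
      denoise_pick_cpp(sq, cen_seq, cen_size, s, alpha, max_dist) else 0L
    if (pick > 0L) {
      cen_size[pick] <- cen_size[pick] + s
    } else if (s >= minsize) {
      cen_seq <- c(cen_seq, sq)
      cen_size <- c(cen_size, s)
      cen_ex <- c(cen_ex, uniques$exemplar_id[i])
    }
  }
  out <- data.frame(seq = cen_seq, size = cen_size, exemplar_id = cen_ex)
  out <- out[order(-out$size, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map reads onto ASV centroids (one abundance-table column)
#'
#' Each read is assigned to the highest-identity ASV with identity at least
#' `min_identity` (identity = 1 - edit distance / longer length); identity
#' ties go to the first ASV in abundance order. Reads below the threshold
#' are left uncounted.
#'
#' @param records a sequence-record data.frame (one sample).
#' @param asvs centroids from [denoise()] (abundance order).
#' @param min_identity minimum identity for assignment.
#' @return named integer vector of per-ASV read counts (names `asv_1`, ...
#'   by abundance order).
#' @export
map_reads <- function(records, asvs, min_identity = 0.97) {
  if (nrow(asvs) == 0L) stop("no ASVs to map against")
  counts <- integer(nrow(asvs))
  names(counts) <- paste0("asv_", seq_len(nrow(asvs)))
  if (nrow(records) == 0L) return(counts)
  u <- dereplicate(records)
  for (i in seq_len(nrow(u))) {
    pick <- map_pick_cpp(u$seq[i], asvs$seq, min_identity)
    if (pick > 0L) counts[pick] <- counts[pick] + u$size[i]
  }
  counts
}

#' Build an ASV abundance table for a set of samples
#'
#' Reads of all samples are pooled, dereplicated and denoised into one ASV
#' space, then each sample is mapped against it.
#'
#' @param samples named list of sequence-record data.frames.
#' @param alpha,minsize,max_dist see [denoise()].
#' @param min_identity see [map_reads()].
#' @param asvs optional pre-computed centroids (skips pooling/denoising).
#' @return list with `table` (ASV x sample integer matrix) and `asvs`.
#' @export
abundance_table <- function(samples, alpha = 2.0, minsize = 8L,
                            max_dist = 10L, min_identity = 0.97,
                            asvs = NULL) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  if (is.null(asvs)) {
    pooled <- do.call(rbind, c(unname(lapply(names(samples), function(nm) {
      r <- samples[[nm]]
      r$id <- paste0(nm, ":", r$id)
      r
    })), list(make.row.names = FALSE)))
    asvs <- denoise(dereplicate(pooled), alpha = alpha, minsize = minsize,
                    max_dist = max_dist)
  }
  if (nrow(asvs) == 0L) stop("denoising produced no ASV centroids")
  cols <- vapply(samples, map_reads, integer(nrow(asvs)), asvs = asvs,
                 min_identity = min_identity)
  m <- matrix(as.integer(cols), nrow = nrow(asvs),
              dimnames = list(paste0("asv_", seq_len(nrow(asvs))),
                              names(samples)))
  list(table = m, asvs = asvs)
}

#' Paired pre/post abundance tables in one ASV space
#'
#' Reads of the pre- and post-correction arms of all samples are pooled and
#' denoised into a single ASV space (mirroring an abundance table whose
#' columns are samples before and after correction), then each arm is
#' mapped per sample. Samples with no mapped reads in either arm are
#' dropped from both tables with a warning.
#'
#' @param pre_samples,post_samples named lists of sequence-record
#'   data.frames with identical names.
#' @inheritParams abundance_table
#' @return list with `pre` and `post` (ASV x sample integer matrices over
#'   the same ASV rows and the same retained samples) and `asvs`.
#' @export
paired_abundance_tables <- function(pre_samples, post_samples, alpha = 2.0,
                                    minsize = 8L, max_dist = 10L,
                                    min_identity = 0.97) {
  stopifnot(identical(names(pre_samples), names(post_samples)))
  pooled_in <- c(setNames(pre_samples, paste0("pre:", names(pre_samples))),
                 setNames(post_samples, paste0("post:", names(post_samples))))
  pooled <- do.call(rbind, c(unname(lapply(names(pooled_in), function(nm) {
    r <- pooled_in[[nm]]
    r$id <- paste0(nm, ":", r$id)
    r
  })), list(make.row.names = FALSE)))
  asvs <- denoise(dereplicate(pooled), alpha = alpha, minsize = minsize,
                  max_dist = max_dist)
  pre <- abundance_table(pre_samples, min_identity = min_identity,
                         asvs = asvs)$table
  post <- abundance_table(post_samples, min_identity = min_identity,
                          asvs = asvs)$table
  empty <- colSums(pre) == 0L | colSums(post) == 0L
  if (any(empty)) {
    warning("dropping sample(s) with no mapped reads: ",
            paste(colnames(pre)[empty], collapse = ", "))
    pre <- pre[, !empty, drop = FALSE]
    post <- post[, !empty, drop = FALSE]
  }
  list(pre = pre, post = post, asvs = asvs)
}
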