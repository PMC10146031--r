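# Nucleotide profile HMM: model construction from a sub-region alignment and
# sub-region detection in reads by glocal Viterbi alignment (model-global
# with internal entry/exit into match states, read-local with free flanks).
# Scores are log2-odds against a uniform background.

BASES <- c("A", "C", "G", "T")

#' Build a nucleotide profile HMM from an alignment
#'
#' Alignment columns whose non-gap fraction is at least `match_fraction`
#' become match states; residues in the remaining columns are treated as
#' insertions attached to the preceding match state. Emission and transition
#' probabilities are Laplace-smoothed relative frequencies: each match
#' column's base counts get `pseudocount` added per base, and each per-node
#' transition count gets `pseudocount` added per target state. Residues
#' outside `{A,C,G,T}` contribute to neither numerator nor ACGT total. The
#' background is uniform (0.25 per base).
#'
#' @param msa an `isc_msa` alignment (see [read_msa()]).
#' @param match_fraction minimum non-gap column occupancy for a match state.
#' @param pseudocount additive (Laplace) pseudocount.
#' @return an object of class `isc_phmm` with elements `K`, `match_emission`
#'   (K x 4), `insert_emission` ((K+1) x 4, rows for insert states before
#'   match 1 through after match K), `transitions` ((K-1) x 9 with columns
#'   `mm,mi,md,im,ii,id,dm,dd,di`), `background`, and `consensus` (the
#'   majority base per match state).
#' @export
build_profile <- function(msa, match_fraction = 0.5, pseudocount = 1.0) {
  stopifnot(inherits(msa, "isc_msa"))
  chars <- do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
  occupancy <- colMeans(chars != "-")
  is_match <- occupancy >= match_fraction
  K <- sum(is_match)
  if (K < 1L) stop("no alignment column passes the match-fraction rule")
  match_cols <- which(is_match)

  count_bases <- function(x) {
    cnt <- table(factor(x, levels = BASES))
    as.numeric(cnt)
  }
  # match emissions
  me <- t(vapply(match_cols, function(j) {
    cnt <- count_bases(chars[, j])
    (cnt + pseudocount) / (sum(cnt) + 4 * pseudocount)
  }, numeric(4)))
  colnames(me) <- BASES

  # node index per column: 0 before the first match column
  node_of_col <- cumsum(is_match)

  # insert emissions: residues in non-match columns, grouped by node
  ie <- matrix(pseudocount, nrow = K + 1L, ncol = 4L,
               dimnames = list(NULL, BASES))
  ins_cols <- which(!is_match)
  for (j in ins_cols) {
    k <- node_of_col[j] + 1L             # row k = insert state after match k-1
    ie[k, ] <- ie[k, ] + count_bases(chars[, j])
  }
  ie <- ie / rowSums(ie)

  # transitions from per-row state paths (full {M,I,D} x {M,I,D} counting)
  tr_names <- c("mm", "mi", "md", "im", "ii", "id", "dm", "dd", "di")
  tc <- matrix(0, nrow = max(K - 1L, 1L), ncol = 9L,
               dimnames = list(NULL, tr_names))
  for (r in seq_len(nrow(chars))) {
    prev_state <- NA_character_
    prev_node <- 0L
    for (j in seq_len(ncol(chars))) {
      res <- chars[r, j] != "-"
      if (is_match[j]) {
        st <- if (res) "m" else "d"
        nd <- node_of_col[j]
      } else if (res) {
        st <- "i"
        nd <- node_of_col[j]
      } else next
      if (!is.na(prev_state)) {
        from_node <- if (prev_state == "i") prev_node else prev_node
        # transitions out of node `from_node` (insert self-loops included)
        if (from_node >= 1L && from_node <= K - 1L) {
          key <- paste0(prev_state, st)
          tc[from_node, key] <- tc[from_node, key] + 1
        }
      }
      prev_state <- st
      prev_node <- nd
    }
  }
  tc <- tc + pseudocount
  tr <- tc
  for (from in c("m", "i", "d")) {
    cols <- paste0(from, c("m", "i", "d"))
    tr[, cols] <- tc[, cols] / rowSums(tc[, cols, drop = FALSE])
  }
  if (K == 1L) tr <- tr[0L, , drop = FALSE]

  structure(list(K = K,
                 match_emission = me,
                 insert_emission = ie,
                 transitions = tr,
                 background = setNames(rep(0.25, 4), BASES),
                 consensus = paste(BASES[max.col(me, ties.method = "first")],
                                   collapse = "")),
            class = "isc_phmm")
}

#' @export
print.isc_phmm <- function(x, ...) {
  cat("Profile HMM:", x$K, "match states\n")
  cat("consensus:", substr(x$consensus, 1, 60),
      if (x$K > 60) "..." else "", "\n")
  invisible(x)
}

# Internal: log2-odds emission matrices and glocal entry/exit vectors.
# `skip_mass` is the total probability mass given to internal entry (and,
# symmetrically, internal exit) points, spread uniformly across them.
phmm_scores <- function(model, skip_mass = 0.01) {
  K <- model$K
  mlo <- log2(model$match_emission / 0.25)
  ilo <- log2(model$insert_emission / 0.25)[seq_len(K) + 1L, , drop = FALSE]
  ilo <- ilo[seq_len(max(K - 1L, 1L)), , drop = FALSE]
  if (K == 1L) {
    entry <- 0
    exitp <- 0
    trans <- matrix(0, 0, 9)
  } else {
    entry <- log2(c(1 - skip_mass, rep(skip_mass / (K - 1), K - 1)))
    exitp <- log2(c(rep(skip_mass / (K - 1), K - 1), 1 - skip_mass))
    trans <- log2(model$transitions)
  }
  list(mlo = mlo, ilo = ilo, trans = trans, entry = entry, exitp = exitp)
}

#' Glocal Viterbi alignment of one sequence to a profile HMM
#'
#' Finds the maximum log2-odds path that traverses the model from an entry
#' match state to an exit match state, with free (unscored) flanking read
#' sequence on both sides. Entry and exit may be internal match states: a
#' total probability mass of `skip_mass` is spread uniformly over internal
#' entry (and exit) points, so reads covering only part of the model still
#' align at a small penalty. Ambiguous bases emit at background (log-odds 0).
#'
#' @param model an `isc_phmm`.
#' @param seq a single nucleotide string.
#' @param skip_mass total probability mass for internal entry/exit.
#' @return list with `bit_score`, `read_start`, `read_end` (1-based, on the
#'   given sequence), `model_start`, `model_end` (match-state indices), and
#'   `path` (state tokens such as `"M3"`, `"I3"`, `"D4"`).
#' @export
viterbi_glocal <- function(model, seq, skip_mass = 0.01) {
  stopifnot(inherits(model, "isc_phmm"), is.character(seq),
            length(seq) == 1L, nchar(seq) >= 1L)
  s <- phmm_scores(model, skip_mass)
  viterbi_glocal_cpp(s$mlo, s$ilo, s$trans, s$entry, s$exitp, seq)
}

#' Locate the modeled sub-region in a set of reads
#'
#' Runs glocal Viterbi on the forward strand and (optionally) the reverse
#' complement of each read, keeps the better strand (ties go to `+`), and
#' emits at most one hit per read when the bit score reaches `min_bits`.
#' Hit coordinates are always reported on the forward strand of the read.
#'
#' @param model an `isc_phmm`.
#' @param records a sequence-record data.frame (columns `id`, `seq`).
#' @param min_bits bit-score threshold for reporting a hit.
#' @param both_strands search the reverse complement as well?
#' @param skip_mass see [viterbi_glocal()].
#' @return a hit-table data.frame (see [write_hit_table()]).
#' @export
search_reads <- function(model, records, min_bits = 20, both_strands = TRUE,
                         skip_mass = 0.01) {
  stopifnot(inherits(model, "isc_phmm"))
  if (nrow(records) == 0L) return(empty_hit_table())
  s <- phmm_scores(model, skip_mass)
  fwd <- viterbi_batch_cpp(s$mlo, s$ilo, s$trans, s$entry, s$exitp,
                           records$seq)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(records$seq)))
    rev <- viterbi_batch_cpp(s$mlo, s$ilo, s$trans, s$entry, s$exitp, rc)
    use_rev <- rev$bit_score > fwd$bit_score
  } else {
    use_rev <- rep(FALSE, nrow(records))
  }
  len <- nchar(records$seq)
  hit <- fwd
  hit$strand <- ifelse(use_rev, "-", "+")
  if (any(use_rev)) {
    i <- which(use_rev)
    hit$bit_score[i] <- rev$bit_score[i]
    hit$model_start[i] <- rev$model_start[i]
    hit$model_end[i] <- rev$model_end[i]
    # map reverse-complement coordinates back to the forward strand
    hit$read_start[i] <- len[i] - rev$read_end[i] + 1L
    hit$read_end[i] <- len[i] - rev$read_start[i] + 1L
  }
  keep <- hit$bit_score >= min_bits
  out <- data.frame(read_id = records$id,
                    read_start = hit$read_start, read_end = hit$read_end,
                    model_start = hit$model_start, model_end = hit$model_end,
                    strand = hit$strand, bit_score = hit$bit_score)[keep, ,
                                                                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of reads with a reported hit
#'
#' @param hits a hit table from [search_reads()].
#' @param records the searched reads.
#' @return fraction in `[0, 1]`.
#' @export
sensitivity <- function(hits, records) {
  if (nrow(records) == 0L) return(NaN)
  length(unique(hits$read_id)) / nrow(records)
}

#' Serialize / load a profile HMM (plain text)
#'
#' A small line-oriented format: a header with the match-state count and
#' alphabet, then the emission and transition blocks at full precision.
#'
#' @param model an `isc_phmm`.
#' @param path file path.
#' @return `path` (writer) or the `isc_phmm` (reader).
#' @export
write_profile <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(m) apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(sprintf("iscr-phmm\t1"),
               sprintf("K\t%d", model$K),
               sprintf("alphabet\t%s", paste(BASES, collapse = "")),
               "match_emission", fmt(model$match_emission),
               "insert_emission", fmt(model$insert_emission),
               "transitions",
               if (nrow(model$transitions)) fmt(model$transitions)), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "iscr-phmm")) stop("not an iscr profile: ", path)
  K <- as.integer(strsplit(lines[2L], "\t")[[1L]][2L])
  block <- function(name, nrows, ncol_, cn) {
    at <- which(lines == name)
    rows <- lines[at + seq_len(nrows)]
    m <- do.call(rbind, lapply(strsplit(rows, "\t"), as.numeric))
    if (nrows == 0L) m <- matrix(0, 0L, ncol_)
    dimnames(m) <- list(NULL, cn)
    m
  }
  me <- block("match_emission", K, 4L, BASES)
  ie <- block("insert_emission", K + 1L, 4L, BASES)
  tr <- block("transitions", max(K - 1L, 0L), 9L,
              c("mm", "mi", "md", "im", "ii", "id", "dm", "dd", "di"))
  structure(list(K = K, match_emission = me, insert_emission = ie,
                 transitions = tr,
                 background = setNames(rep(0.25, 4), BASES),
                 consensus = paste(BASES[max.col(me, ties.method = "first")],
                                   collapse = "")),
            class = "isc_phmm")
}
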