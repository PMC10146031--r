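# Seeded simulator producing data with the structure the evaluation
# machinery assumes: a reference sub-region family (with a true alignment),
# full-length templates with conserved flanks, shared per-sample
# communities, and per-category amplicon windows with sequencing error.

mutate_positions <- function(ch, idx) {
  for (h in idx) ch[h] <- sample(BASES[BASES != ch[h]], 1L)
  ch
}

#' Simulate a sub-region sequence family
#'
#' An ancestral region of `region_len` bases is mutated independently per
#' taxon: substitutions at per-site rate `divergence`, single-base
#' insertions/deletions at total per-site rate `indel_rate` (half each).
#' Conserved flanks of `flank_len` bases (substitutions at `divergence/5`,
#' no indels) are attached on both sides to form full-length templates.
#' Because indel events are recorded, the true multiple alignment of the
#' region is returned alongside the sequences.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param region_len,flank_len lengths in bp.
#' @param divergence per-site substitution probability in the region.
#' @param indel_rate per-site indel probability in the region.
#' @param seed integer RNG seed (`NULL` = current stream).
#' @return list of class `isc_family`: `msa` (true region alignment),
#'   `templates` (named full-length sequences), `truth` (data.frame with
#'   `taxon`, `region_start`, `region_end` in template coordinates),
#'   `region_len`, `flank_len`.
#' @export
make_family <- function(n_taxa, region_len = 380L, flank_len = 200L,
                        divergence = 0.10, indel_rate = 0.01, seed = NULL) {
  stopifnot(n_taxa >= 2L, region_len >= 1L, flank_len >= 0L,
            divergence >= 0, divergence < 0.5, indel_rate >= 0)
  with_seed(seed, {
    ids <- sprintf("taxon_%03d", seq_len(n_taxa))
    anc <- sample(BASES, region_len, replace = TRUE)
    anc_left <- sample(BASES, flank_len, replace = TRUE)
    anc_right <- sample(BASES, flank_len, replace = TRUE)

    res <- matrix(anc, n_taxa, region_len, byrow = TRUE)
    ins <- matrix("", n_taxa, region_len)       # insertion after position j
    for (t in seq_len(n_taxa)) {
      sub_idx <- which(runif(region_len) < divergence)
      res[t, ] <- mutate_positions(res[t, ], sub_idx)
      del_idx <- which(runif(region_len) < indel_rate / 2)
      res[t, del_idx] <- "-"
      ins_idx <- which(runif(region_len) < indel_rate / 2)
      ins[t, ins_idx] <- sample(BASES, length(ins_idx), replace = TRUE)
    }

    # true alignment: ancestral columns plus one inserted column wherever
    # any taxon carries an insertion after that position
    cols <- vector("list", region_len)
    for (j in seq_len(region_len)) {
      block <- res[, j, drop = FALSE]
      if (any(nzchar(ins[, j])))
        block <- cbind(block, ifelse(nzchar(ins[, j]), ins[, j], "-"))
      cols[[j]] <- block
    }
    ali <- do.call(cbind, cols)
    aligned <- apply(ali, 1L, paste, collapse = "")
    region_seq <- gsub("-", "", aligned, fixed = TRUE)

    flank_of <- function(anc_fl) {
      if (flank_len == 0L) return(rep("", n_taxa))
      vapply(seq_len(n_taxa), function(t) {
        idx <- which(runif(flank_len) < divergence / 5)
        paste(mutate_positions(anc_fl, idx), collapse = "")
      }, character(1))
    }
    left <- flank_of(anc_left)
    right <- flank_of(anc_right)
    templates <- setNames(paste0(left, region_seq, right), ids)
    truth <- data.frame(taxon = ids,
                        region_start = flank_len + 1L,
                        region_end = flank_len + nchar(region_seq))
    structure(list(msa = msa(ids, aligned), templates = templates,
                   truth = truth, region_len = region_len,
                   flank_len = flank_len),
              class = "isc_family")
  })
}

#' Simulate one amplicon sample from a family
#'
#' Taxon abundances are drawn log-normal (then fixed for the sample) and
#' read counts multinomial at the requested depth. Each read is the
#' template slice `[region_start - window[1], region_end + window[2]]`
#' (negative offsets move the cut inside the region) with independent
#' per-base substitution errors; each read is reverse-complemented with
#' probability one half.
#'
#' @param family an `isc_family`.
#' @param window length-2 integer vector of left/right extension offsets
#'   relative to the true region (0,0 = exactly the region).
#' @param depth number of reads.
#' @param error_rate per-base substitution error probability.
#' @param lognormal_sigma log-scale sd of the abundance distribution.
#' @param rc_prob probability that a read is stored reverse-complemented
#'   (0 emulates orientation-consistent merged reads).
#' @param abundances optional fixed abundance vector (overrides the draw).
#' @param seed integer RNG seed (`NULL` = current stream).
#' @return list with `records` (sequence-record data.frame), `truth`
#'   (data.frame: `read_id`, `taxon`, `strand`, `region_start`,
#'   `region_end` — the true coordinates of the modeled region on the
#'   stored read's forward strand), `abundances` and `counts`.
#' @export
simulate_sample <- function(family, window = c(0L, 0L), depth = 10000L,
                            error_rate = 0.005, lognormal_sigma = 1.5,
                            rc_prob = 0.5, abundances = NULL, seed = NULL) {
  stopifnot(inherits(family, "isc_family"), length(window) == 2L,
            depth >= 1L)
  with_seed(seed, {
    n_taxa <- nrow(family$truth)
    p <- if (is.null(abundances)) rlnorm(n_taxa, 0, lognormal_sigma) else
      abundances
    p <- p / sum(p)
    counts <- as.vector(rmultinom(1L, depth, p))

    astart <- family$truth$region_start - window[1L]
    aend <- family$truth$region_end + window[2L]
    tlen <- nchar(family$templates)
    if (any(astart < 1L) || any(aend > tlen) || any(astart > aend))
      stop("amplicon window falls outside the template")
    amplicon <- substr(family$templates, astart, aend)
    # true region coordinates on the amplicon (clipped overlap)
    ov_s <- pmax(astart, family$truth$region_start) - astart + 1L
    ov_e <- pmin(aend, family$truth$region_end) - astart + 1L

    tax_idx <- rep(seq_len(n_taxa), counts)
    seqs <- amplicon[tax_idx]
    if (error_rate > 0) {
      L <- nchar(seqs)
      nerr <- stats::rbinom(length(seqs), L, error_rate)
      for (r in which(nerr > 0L)) {
        ch <- strsplit(seqs[r], "", fixed = TRUE)[[1L]]
        ch <- mutate_positions(ch, sample.int(L[r], nerr[r]))
        seqs[r] <- paste(ch, collapse = "")
      }
    }
    flip <- runif(length(seqs)) < rc_prob
    rs <- ov_s[tax_idx]
    re <- ov_e[tax_idx]
    if (any(flip)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
      L <- nchar(seqs[flip])
      new_rs <- L - re[flip] + 1L
      re[flip] <- L - rs[flip] + 1L
      rs[flip] <- new_rs
      seqs[flip] <- rc
    }
    ids <- sprintf("r%05d", seq_along(seqs))
    list(records = new_seq_records(ids, seqs),
         truth = data.frame(read_id = ids,
                            taxon = family$truth$taxon[tax_idx],
                            strand = ifelse(flip, "-", "+"),
                            region_start = rs, region_end = re),
         abundances = p, counts = counts)
  })
}

#' Simulate the four-category amplicon bundle
#'
#' One family is simulated; then every sample index gets one community
#' realization (a log-normal abundance draw) that all four groups observe
#' through their own window: `Same` cuts exactly the region; `Near` is the
#' built-in true null, a matched-window dataset differing only in its error
#' realization (window-length difference 0, within the <= 50 bp category
#' rule); `Short` cuts 73 bp inside the region; `Long` extends 160 bp into
#' the conserved flanks. Pre-correction tables thus differ by construction
#' between scale categories while post-correction tables should converge.
#'
#' Reads are stored orientation-consistently (`rc_prob = 0`), as merged
#' paired-end amplicon reads are in practice; strand-flipped reads are the
#' business of [simulate_sample()]'s `rc_prob` default.
#'
#' @param n_samples_per_group samples per category.
#' @param n_taxa,region_len,flank_len,divergence,indel_rate
#'   see [make_family()].
#' @param depth,error_rate,lognormal_sigma,rc_prob see [simulate_sample()].
#' @param seed master RNG seed; all randomness flows from it.
#' @return list of class `isc_bundle`: `groups` (group id -> named list of
#'   sample read sets), `truth` (same shape, per-read truth), `family`,
#'   `windows`, and `meta` (data.frame of sample id, group, window length).
#' @export
make_category_bundle <- function(n_samples_per_group = 20L, n_taxa = 40L,
                                 depth = 300L, error_rate = 0.005,
                                 region_len = 380L, flank_len = 200L,
                                 divergence = 0.10, indel_rate = 0.01,
                                 lognormal_sigma = 1.5, rc_prob = 0,
                                 seed = NULL) {
  with_seed(seed, {
    fam <- make_family(n_taxa, region_len, flank_len, divergence,
                       indel_rate)
    windows <- list(Same = c(0L, 0L), Near = c(0L, 0L),
                    Short = c(-36L, -37L), Long = c(80L, 80L))
    groups <- truth <- lapply(windows, function(w) list())
    for (s in seq_len(n_samples_per_group)) {
      ab <- rlnorm(n_taxa, 0, lognormal_sigma)
      for (g in names(windows)) {
        sim <- simulate_sample(fam, windows[[g]], depth = depth,
                               error_rate = error_rate, rc_prob = rc_prob,
                               abundances = ab)
        nm <- sprintf("%s_s%02d", g, s)
        groups[[g]][[nm]] <- sim$records
        truth[[g]][[nm]] <- sim$truth
      }
    }
    meta <- data.frame(
      sample_id = unlist(lapply(groups, names), use.names = FALSE),
      group = rep(names(windows), each = n_samples_per_group),
      window_len = rep(region_len + vapply(windows, sum, integer(1)),
                       each = n_samples_per_group))
    structure(list(groups = groups, truth = truth, family = fam,
                   windows = windows, meta = meta),
              class = "isc_bundle")
  })
}
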