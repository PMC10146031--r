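# Readers/writers for the external representations the toolchain touches:
# FASTA, FASTQ (Phred+33), alignments (aligned FASTA / Stockholm), the TSV
# hit table and the TSV abundance table.
#
# Reads are carried as a plain data.frame with columns `id`, `seq` and `qual`
# (the Phred+33 quality string, NA when absent). Sequences are uppercased on
# input and RNA 'U' is mapped to 'T'; IUPAC ambiguity codes (including 'N')
# are retained — downstream HMM scoring treats them as background.

new_seq_records <- function(id, seq, qual = NA_character_) {
  stopifnot(length(id) == length(seq))
  data.frame(id = as.character(id), seq = as.character(seq),
             qual = rep_len(as.character(qual), length(id)))
}

normalize_seq <- function(x) chartr("Uu", "Tt", toupper(x))

check_unique_ids <- function(id, path) {
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(dup, collapse = ", "))
}

#' Read a FASTA file
#'
#' Sequences are uppercased and 'U' is mapped to 'T'. The record id is the
#' first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return a data.frame of sequence records with columns `id`, `seq`, `qual`
#'   (`qual` is `NA` for FASTA input).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  id <- sub("\\s.*$", "", names(set))
  check_unique_ids(id, path)
  new_seq_records(id, normalize_seq(as.character(set)))
}

#' Read a FASTQ file (Phred+33, strict 4-line records)
#'
#' @param path path to a FASTQ file.
#' @return a data.frame of sequence records; `qual` holds the Phred+33
#'   quality string.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("no FASTQ records in '", path, "'")
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
         " in '", path, "'")
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in '", path, "'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("sequence/quality length mismatch at record ", bad[1L],
         " in '", path, "'")
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  check_unique_ids(id, path)
  new_seq_records(id, normalize_seq(seq), qual)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer(0))
    as.integer(charToRaw(q)) - 33L
  })
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  writeLines(paste0(">", records$id, "\n", records$seq), path)
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Both `.` and `-` gap characters are normalized to `-`; residues are
#' uppercased with 'U' mapped to 'T'. Stockholm annotation lines (`#=GF`,
#' `#=GC`, ...) are ignored; multi-block Stockholm alignments are
#' concatenated per sequence name.
#'
#' @param path path to the alignment.
#' @param dialect `"afa"` (aligned FASTA) or `"stockholm"`.
#' @return an object of class `isc_msa`: a list with `ids`, `seqs` (aligned
#'   strings) and `n_columns`.
#' @export
read_msa <- function(path, dialect = c("afa", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "afa") {
    set <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(set) == 0L) stop("no alignment rows in '", path, "'")
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
    if (length(rows) == 0L) stop("no alignment rows in '", path, "'")
    parts <- regmatches(rows, regexpr("^\\S+", rows))
    seqpart <- trimws(sub("^\\S+\\s+", "", rows))
    seqs <- vapply(split(seqpart, factor(parts, levels = unique(parts))),
                   paste0, character(1), collapse = "")
    ids <- unique(parts)
  }
  check_unique_ids(ids, path)
  seqs <- chartr(".", "-", normalize_seq(unname(seqs)))
  msa(ids, seqs)
}

#' Construct an MSA object
#'
#' @param ids row identifiers.
#' @param seqs aligned strings over `{A,C,G,T,-}` (plus ambiguity codes).
#' @return an `isc_msa` object.
#' @export
msa <- function(ids, seqs) {
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(w), collapse = ", "))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 rows")
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 n_columns = w[1L]),
            class = "isc_msa")
}

#' @export
print.isc_msa <- function(x, ...) {
  cat("MSA:", length(x$ids), "rows x", x$n_columns, "columns\n")
  invisible(x)
}

#' Write a Stockholm alignment
#'
#' @param msa an `isc_msa` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(msa, path) {
  wid <- max(nchar(msa$ids))
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("%-*s %s", wid, msa$ids, msa$seqs),
               "//"), path)
  invisible(path)
}

hit_table_cols <- c("read_id", "read_start", "read_end",
                    "model_start", "model_end", "strand", "bit_score")

#' Construct an empty hit table
#' @return a zero-row hit-table data.frame.
#' @export
empty_hit_table <- function() {
  data.frame(read_id = character(0), read_start = integer(0),
             read_end = integer(0), model_start = integer(0),
             model_end = integer(0), strand = character(0),
             bit_score = numeric(0))
}

#' Write/read the TSV hit table
#'
#' The table records, per read, the located sub-region: read coordinates
#' (1-based, always on the forward strand of the read), model (match-state)
#' coordinates, strand, and the log2-odds bit score. Scores are written with
#' 17 significant digits so that `read_hit_table(write_hit_table(x))` is an
#' identity.
#'
#' @param hits a hit-table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_table_cols %in% names(hits)))
  out <- hits[hit_table_cols]
  out$bit_score <- sprintf("%.17g", out$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  x <- read.delim(path, colClasses = c(read_id = "character",
                                       strand = "character"))
  if (!identical(names(x), hit_table_cols))
    stop("not a hit table: '", path, "'")
  x
}

#' Write/read an ASV abundance table (TSV)
#'
#' Rows are ASV ids, columns are sample ids, cells are integer read counts.
#'
#' @param table integer matrix with ASV row names and sample column names.
#' @param path output path.
#' @return `path` (writer) or the integer matrix (reader).
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(asv_id = rownames(table), table, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(asv_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$asv_id
  storage.mode(m) <- "integer"
  m
}
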