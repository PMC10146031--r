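test_that("profile construction applies the occupancy rule and Laplace smoothing", {
  m <- build_profile(msa(sprintf("r%d", 1:4),
                         c("AA", "AA", "AA", "A-")))
  # column 1: 4 A's -> P(A) = (4+1)/(4+4)
  expect_equal(unname(m$match_emission[1, "A"]), 0.625)
  expect_equal(m$K, 2L)

  # a 25%-occupied column is not a match state at the default 50% rule
  m2 <- build_profile(msa(sprintf("r%d", 1:4),
                          c("CAC", "C-C", "C-C", "C-C")))
  expect_equal(m2$K, 2L)

  # ungapped alignment: every column is a match state
  m3 <- build_profile(msa(c("a", "b"), c("ACG", "ACG")))
  expect_equal(m3$K, 3L)

  expect_error(build_profile(msa(sprintf("r%d", 1:4),
                                 c("A---", "-C--", "--G-", "---T"))),
               "match-fraction")
})

test_that("profile probabilities are normalized on random alignments", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    w <- sample(3:12, 1)
    rows <- replicate(n, {
      ch <- sample(c("A", "C", "G", "T", "-"), w, replace = TRUE,
                   prob = c(rep(0.2, 4), 0.2))
      paste(ch, collapse = "")
    })
    m <- try(build_profile(msa(sprintf("r%d", 1:n), rows)), silent = TRUE)
    if (inherits(m, "try-error")) next
    expect_equal(rowSums(m$match_emission), rep(1, m$K), tolerance = 1e-9)
    expect_equal(rowSums(m$insert_emission), rep(1, m$K + 1),
                 tolerance = 1e-9)
    if (m$K > 1) {
      for (from in c("m", "i", "d")) {
        cols <- paste0(from, c("m", "i", "d"))
        expect_equal(unname(rowSums(m$transitions[, cols, drop = FALSE])),
                     rep(1, m$K - 1), tolerance = 1e-9)
      }
    }
  }
})

test_that("glocal Viterbi equals exhaustive path enumeration on small models", {
  set.seed(33)
  for (case in 1:60) {
    m <- random_small_model(n_rows = sample(3:6, 1), n_cols = sample(2:6, 1))
    s <- random_dna(sample(1:6, 1))
    expect_equal(viterbi_glocal(m, s)$bit_score,
                 enumerate_glocal_score(m, s), tolerance = 1e-12)
  }
})

test_that("consensus reads align full-span; an inserted base uses an insert state", {
  sf <- small_family_fixture()
  model <- sf$model
  v <- viterbi_glocal(model, model$consensus)
  expect_equal(v$model_start, 1L)
  expect_equal(v$model_end, model$K)
  expect_equal(v$read_start, 1L)
  expect_equal(v$read_end, nchar(model$consensus))

  ins <- paste0(substr(model$consensus, 1, 40), "A",
                substr(model$consensus, 41, model$K))
  vi <- viterbi_glocal(model, ins)
  expect_equal(sum(startsWith(vi$path, "I")), 1L)
  expect_lt(vi$bit_score, v$bit_score)
})

test_that("best-of-both-strands scores are strand-symmetric, exactly", {
  sf <- small_family_fixture()
  set.seed(8)
  seqs <- c(unname(sf$family$templates[1:3]),
            replicate(3, random_dna(100)))
  for (s in seqs) {
    pair <- new_seq_records(c("f", "r"), c(s, revcomp(s)))
    h <- search_reads(sf$model, pair, min_bits = -Inf)
    expect_identical(h$bit_score[1], h$bit_score[2])
  }
})

test_that("free flanks leave the best hit score unchanged", {
  sf <- small_family_fixture()
  set.seed(9)
  base <- viterbi_glocal(sf$model, sf$model$consensus)$bit_score
  for (i in 1:5) {
    flanked <- paste0(random_dna(30), sf$model$consensus, random_dna(30))
    expect_equal(viterbi_glocal(sf$model, flanked)$bit_score, base,
                 tolerance = 1e-9)
  }
})

test_that("search reports at most one hit per read with forward-strand coords", {
  sf <- small_family_fixture()
  reads <- new_seq_records(
    c("fwd", "rev", "junk"),
    c(paste0("TTTTT", sf$model$consensus, "AAAAA"),
      revcomp(paste0("TTTTT", sf$model$consensus, "AAAAA")),
      with_seed_dna(1234, 120)))
  hits <- search_reads(sf$model, reads)
  expect_equal(hits$read_id, c("fwd", "rev"))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$bit_score[1], hits$bit_score[2])
  expect_equal(hits$read_start, c(6L, 6L))
  expect_equal(hits$read_end, rep(5L + sf$model$K, 2))
  expect_equal(sensitivity(hits, reads), 2 / 3)
})

test_that("ambiguous bases score as background and never crash", {
  sf <- small_family_fixture()
  s <- sf$model$consensus
  s_n <- paste0(substr(s, 1, 10), "N", substr(s, 12, nchar(s)))
  v <- viterbi_glocal(sf$model, s_n)
  expect_true(is.finite(v$bit_score))
  expect_lt(v$bit_score, viterbi_glocal(sf$model, s)$bit_score)
})

test_that("profile serialization round-trips", {
  sf <- small_family_fixture()
  f <- withr::local_tempfile(fileext = ".ihmm")
  write_profile(sf$model, f)
  m2 <- read_profile(f)
  expect_equal(m2$K, sf$model$K)
  expect_equal(m2$match_emission, sf$model$match_emission)
  expect_equal(m2$insert_emission, sf$model$insert_emission)
  expect_equal(m2$transitions, sf$model$transitions)
  expect_identical(viterbi_glocal(m2, sf$model$consensus)$bit_score,
                   viterbi_glocal(sf$model, sf$model$consensus)$bit_score)
})
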