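test_that("dereplication counts copies and orders by size then sequence", {
  r <- new_seq_records(c("a", "b", "c"), c("ACGT", "ACGT", "AAAA"))
  u <- dereplicate(r)
  expect_equal(u$seq, c("ACGT", "AAAA"))
  expect_equal(u$size, c(2L, 1L))
  expect_equal(u$exemplar_id, c("a", "c"))

  expect_equal(nrow(dereplicate(new_seq_records(character(0),
                                                character(0)))), 0L)

  set.seed(2)
  distinct <- new_seq_records(sprintf("r%d", 1:100),
                              replicate(100, random_dna(30)))
  u2 <- dereplicate(distinct)
  expect_equal(nrow(u2), 100L)
  expect_true(all(u2$size == 1L))
  expect_equal(u2$seq, sort(u2$seq))          # size ties broken lexically
})

test_that("bounded edit distance agrees with utils::adist within the band", {
  set.seed(6)
  for (i in 1:50) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    d_true <- drop(utils::adist(a, b))
    d_band <- iscr:::bounded_edit_cpp(a, b, 10L)
    if (d_true <= 10L) expect_equal(d_band, d_true) else
      expect_equal(d_band, 11L)
  }
})

test_that("denoiser join rule follows the abundance-skew threshold", {
  # centroid of size 64; candidate at edit distance 2:
  # beta(2) = 1/2^(2*2+1) = 1/32
  cen <- strrep("ACGT", 10)
  cand <- paste0(substr(cen, 1, 38), "AA")           # two substitutions
  expect_equal(iscr:::bounded_edit_cpp(cand, cen, 10L), 2L)

  join <- denoise(data.frame(seq = c(cen, cand), size = c(64L, 1L),
                             exemplar_id = c("e1", "e2")))
  expect_equal(nrow(join), 1L)                       # 1/64 <= 1/32: joined
  expect_equal(join$size, 65)

  nojoin <- denoise(data.frame(seq = c(cen, cand), size = c(64L, 4L),
                               exemplar_id = c("e1", "e2")))
  expect_equal(nrow(nojoin), 1L)     # 4/64 > 1/32: not joined; 4 < minsize
  expect_equal(nojoin$size, 64)

  single <- denoise(data.frame(seq = cen, size = 10L, exemplar_id = "e"))
  expect_equal(nrow(single), 1L)
})

test_that("denoiser conserves read counts and is monotone in alpha", {
  set.seed(17)
  templates <- replicate(4, random_dna(60))
  reads <- list()
  for (t in seq_along(templates)) {
    n <- sample(20:60, 1)
    seqs <- rep(templates[t], n)
    err <- runif(n) < 0.4
    seqs[err] <- vapply(seqs[err], function(s) {
      p <- sample.int(60, 1)
      paste0(substr(s, 1, p - 1), sample(c("A", "C", "G", "T"), 1),
             substr(s, p + 1, 60))
    }, character(1))
    reads[[t]] <- seqs
  }
  all_reads <- new_seq_records(sprintf("r%d", seq_along(unlist(reads))),
                               unlist(reads))
  u <- dereplicate(all_reads)

  n_prev <- Inf
  for (a in c(1, 2, 4, 8)) {
    cents <- denoise(u, alpha = a, minsize = 4L)
    expect_lte(nrow(cents), n_prev)
    n_prev <- nrow(cents)
  }

  # conservation: with minsize 1 nothing is discarded, so centroid sizes
  # must sum exactly to the input read count
  cents1 <- denoise(u, alpha = 2, minsize = 1L)
  expect_equal(sum(cents1$size), nrow(all_reads))
  # at a higher minsize, discarded mass is the exact complement
  cents <- denoise(u, alpha = 2, minsize = 4L)
  expect_gte(sum(cents1$size) - sum(cents$size), 0)
})

test_that("read mapping assigns by identity with a floor", {
  asvs <- data.frame(seq = c(strrep("A", 100), strrep("C", 100)),
                     size = c(50, 40), exemplar_id = c("e1", "e2"))
  reads <- new_seq_records(
    c("exact", "close", "far"),
    c(strrep("A", 100),
      paste0(strrep("A", 98), "CC"),       # 98% identity to asv_1
      paste0(strrep("A", 80), strrep("G", 20))))  # 80% identity: uncounted
  col <- map_reads(reads, asvs)
  expect_equal(unname(col), c(2L, 0L))
})

test_that("clean template mixtures are reconstructed exactly end-to-end", {
  set.seed(23)
  templates <- c(strrep("ACGT", 25), strrep("GGCA", 25), strrep("TTAC", 25))
  sizes <- c(40L, 25L, 10L)
  reads <- new_seq_records(
    sprintf("r%d", seq_len(sum(sizes))),
    rep(templates, sizes))
  asvs <- denoise(dereplicate(reads))
  expect_equal(nrow(asvs), 3L)
  col <- map_reads(reads, asvs)
  expect_equal(unname(col), sort(sizes, decreasing = TRUE))

  tab <- abundance_table(list(s1 = reads))
  expect_equal(unname(colSums(tab$table)), sum(sizes))
})
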