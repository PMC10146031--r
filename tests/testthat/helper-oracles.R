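# Independent oracles and shared fixtures for the test suite.

# Exhaustive-path oracle for the glocal Viterbi score: enumerates every
# legal state path (entry into any match state after any free prefix,
# transitions through M/I/D, exit from any match state, free suffix) by
# direct recursion and returns the maximum log2-odds score. Only feasible
# for tiny models/sequences; it shares the model definition but not the
# dynamic-programming decomposition.
enumerate_glocal_score <- function(model, seq, skip_mass = 0.01) {
  K <- model$K
  mlo <- log2(model$match_emission / 0.25)
  ilo <- log2(model$insert_emission / 0.25)   # row k+1 = insert after match k
  tr <- if (K > 1) log2(model$transitions) else
    matrix(numeric(0), 0, 9,
           dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "id",
                                   "dm", "dd", "di")))
  entry <- if (K == 1) 0 else log2(c(1 - skip_mass,
                                     rep(skip_mass / (K - 1), K - 1)))
  exitp <- if (K == 1) 0 else log2(c(rep(skip_mass / (K - 1), K - 1),
                                     1 - skip_mass))
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  L <- length(x)
  em <- function(j, i) if (is.na(x[i])) 0 else mlo[j, x[i]]
  iem <- function(j, i) if (is.na(x[i])) 0 else ilo[j + 1, x[i]]

  best <- -Inf
  rec <- function(state, j, i, sc) {
    # state just produced at node j; i = next unconsumed read position
    if (state == "M") {
      best <<- max(best, sc + exitp[j])         # exit here, free suffix
      if (j < K) {
        if (i <= L) {
          rec("M", j + 1, i + 1, sc + tr[j, "mm"] + em(j + 1, i))
          rec("I", j, i + 1, sc + tr[j, "mi"] + iem(j, i))
        }
        rec("D", j + 1, i, sc + tr[j, "md"])
      }
    } else if (state == "I") {
      if (i <= L) {
        rec("M", j + 1, i + 1, sc + tr[j, "im"] + em(j + 1, i))
        rec("I", j, i + 1, sc + tr[j, "ii"] + iem(j, i))
      }
      rec("D", j + 1, i, sc + tr[j, "id"])
    } else {                                     # deletion at node j
      if (j < K) {
        if (i <= L) {
          rec("M", j + 1, i + 1, sc + tr[j, "dm"] + em(j + 1, i))
          rec("I", j, i + 1, sc + tr[j, "di"] + iem(j, i))
        }
        rec("D", j + 1, i, sc + tr[j, "dd"])
      }
    }
    invisible(NULL)
  }
  for (i0 in seq_len(L))
    for (j0 in seq_len(K))
      rec("M", j0, i0 + 1, entry[j0] + em(j0, i0))
  best
}

# Random small alignment -> profile HMM, for property-based Viterbi tests.
random_small_model <- function(n_rows = 4, n_cols = 4, gap_p = 0.2) {
  rows <- replicate(n_rows, {
    ch <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
    gap <- runif(n_cols) < gap_p
    ch[gap] <- "-"
    paste(ch, collapse = "")
  })
  # ensure at least one match column survives the occupancy rule
  m <- try(build_profile(msa(sprintf("r%d", seq_len(n_rows)), rows)),
           silent = TRUE)
  if (inherits(m, "try-error")) return(random_small_model(n_rows, n_cols,
                                                          gap_p))
  m
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

with_seed_dna <- function(seed, n) {
  set.seed(seed)
  random_dna(n)
}

# Brute-force medoid: literal argmin of summed Euclidean distances.
brute_medoid <- function(points) {
  n <- nrow(points)
  sums <- vapply(seq_len(n), function(i)
    sum(sqrt(rowSums((points - matrix(points[i, ], n, ncol(points),
                                      byrow = TRUE))^2))), numeric(1))
  which.min(sums)
}

# Expensive shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The two study-scale bundles (error-free and at the default error rate)
# with their trained model and ISC output.
clean_bundle_fixture <- function() fixture("clean_bundle", function() {
  bundle <- make_category_bundle(n_samples_per_group = 20, error_rate = 0,
                                 seed = 101)
  model <- build_profile(bundle$family$msa)
  samples <- do.call(c, unname(bundle$groups))
  isc <- run_isc(samples, model)
  list(bundle = bundle, model = model, samples = samples, isc = isc)
})

noisy_bundle_fixture <- function() fixture("noisy_bundle", function() {
  bundle <- make_category_bundle(n_samples_per_group = 20, seed = 202)
  model <- build_profile(bundle$family$msa)
  samples <- do.call(c, unname(bundle$groups))
  isc <- run_isc(samples, model)
  list(bundle = bundle, model = model, samples = samples, isc = isc)
})

# Small family for cheap unit tests.
small_family_fixture <- function() fixture("small_family", function() {
  fam <- make_family(n_taxa = 10, region_len = 80, flank_len = 40, seed = 7)
  list(family = fam, model = build_profile(fam$msa))
})
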