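# Independent oracles and shared fixtures for the test suite.

# Brute-force affine-gap DP (Gotoh), score only, full matrices, plain R.
# Glocal boundary conditions: free reference overhangs, read global.
# Kept deliberately independent of the production C++ implementation.
oracle_glocal_score <- function(read, ref, sc = default_scoring()) {
  n <- nchar(read); m <- nchar(ref)
  rb <- strsplit(read, "")[[1]]; fb <- strsplit(ref, "")[[1]]
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  H[1, ] <- 0
  go <- sc$gap_open + sc$gap_extend; ge <- sc$gap_extend
  for (i in 1:n) {
    I[i + 1, 1] <- -(sc$gap_open + i * ge)
    H[i + 1, 1] <- I[i + 1, 1]
    si <- ifelse(rb[i] == fb & rb[i] %in% c("A", "C", "G", "T"),
                 sc$match, -sc$mismatch)
    for (j in 1:m) {
      D[i + 1, j + 1] <- max(H[i + 1, j] - go, D[i + 1, j] - ge)
      I[i + 1, j + 1] <- max(H[i, j + 1] - go, I[i, j + 1] - ge)
      H[i + 1, j + 1] <- max(H[i, j] + si[j], D[i + 1, j + 1],
                             I[i + 1, j + 1])
    }
  }
  max(H[n + 1, ])
}

# Placement-enumeration microhomology oracle: the number of deletion
# placements (same size) that yield an identical edited sequence,
# minus one, for a left-aligned deletion.
oracle_mh_length <- function(s, e, seqn) {
  size <- e - s
  edited <- paste0(substr(seqn, 1, s), substr(seqn, e + 1, nchar(seqn)))
  count <- 0L
  for (s2 in 0:(nchar(seqn) - size)) {
    alt <- paste0(substr(seqn, 1, s2),
                  substr(seqn, s2 + size + 1, nchar(seqn)))
    if (alt == edited) count <- count + 1L
  }
  count - 1L
}

# independent left-alignment of a deletion interval
oracle_left_align <- function(s, e, seqn) {
  while (s > 0 && substr(seqn, s, s) == substr(seqn, e, e)) {
    s <- s - 1; e <- e - 1
  }
  c(s, e)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# shared synthetic references, built once per test run
test_locus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_synthetic_locus(seed = 101L)
    cache
  }
})
test_vector <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_synthetic_vector(seed = 7L)
    cache
  }
})

# fixture bundles, generated once per test run into a shared tempdir
fixtures_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "crispaav-fixtures")
      make_fixtures(d)
      cache <<- d
    }
    cache
  }
})

read_truth <- function(name) {
  read.delim(file.path(fixtures_dir(), name, paste0(name, "_truth.tsv")),
             stringsAsFactors = FALSE)
}

run_fixture <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      out <- file.path(tempdir(), paste0("crispaav-run-", name))
      cfg <- fixture_run_config(fixtures_dir(), name, out)
      cache[[name]] <<- run_pipeline(cfg)
    }
    cache[[name]]
  }
})
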