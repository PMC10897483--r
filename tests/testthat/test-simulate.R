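test_that("synthetic vector layout follows the declared arithmetic", {
  vec <- build_synthetic_vector(c(A = 20L, B = 10L, C = 10L, D = 10L),
                                stuffer_length = 500L, seed = 7L)
  expect_equal(nchar(vec$sequence), 2L * (2L * 20L + 2L * 10L + 2L * 10L +
                                          10L) + 500L)
  # palindromic ITRs: 3' ITR is the reverse complement of the 5' ITR
  itr5 <- substr(vec$sequence, 1, 90)
  itr3 <- substr(vec$sequence, 680 - 90 + 1, 680)
  expect_equal(itr3, revcomp(itr5))
  expect_setequal(vec$boundaries$label,
                  c("ITR5_ApA_boundary", "ITR5_BpB_boundary",
                    "ITR3_ApA_boundary", "ITR3_BpB_boundary"))
  # zero stuffer: ITRs adjacent, still annotated
  v0 <- build_synthetic_vector(stuffer_length = 0L, seed = 7L)
  expect_equal(nchar(v0$sequence), 180L)
  expect_equal(nrow(itr_intervals(v0)), 14L)
  # same seed, same sequence
  expect_identical(build_synthetic_vector(seed = 3L)$sequence,
                   build_synthetic_vector(seed = 3L)$sequence)
})

test_that("pure class mixes produce exactly the constructed reads", {
  locus <- test_locus(); vec <- test_vector()
  d <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 40, class_mix = c(wildtype = 1),
                    sub_error_rate = 0, seed = 5L)
  out <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d, "wt")
  reads <- as.character(Biostrings::readDNAStringSet(out$fastq,
                                                     format = "fastq"))
  expect_true(all(reads == locus$amplicon$sequence))
  cfg2 <- sim_config(n_reads = 40,
                     class_mix = c(internick_deletion = 1),
                     sub_error_rate = 0, seed = 5L)
  out2 <- simulate_dataset(cfg2, locus$amplicon, vec, locus$pair, d, "ind")
  reads2 <- as.character(Biostrings::readDNAStringSet(out2$fastq,
                                                      format = "fastq"))
  n1 <- min(locus$amplicon$cut_sites); n2 <- max(locus$amplicon$cut_sites)
  expected <- paste0(substr(locus$amplicon$sequence, 1, n1),
                     substr(locus$amplicon$sequence, n2 + 1,
                            nchar(locus$amplicon$sequence)))
  expect_true(all(reads2 == expected))
  expect_equal(nchar(expected),
               nchar(locus$amplicon$sequence) - 64L)
})

test_that("simulation is byte-identical under a fixed seed", {
  locus <- test_locus(); vec <- test_vector()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 150, seed = 42L)
  o1 <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d1, "s")
  o2 <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d2, "s")
  expect_identical(unname(tools::md5sum(o1$fastq)),
                   unname(tools::md5sum(o2$fastq)))
  expect_identical(readLines(o1$truth_path), readLines(o2$truth_path))
})

test_that("truth records reproduce every emitted read", {
  locus <- test_locus(); vec <- test_vector()
  truth <- read_truth("paired_nickase_mix")
  fq <- file.path(fixtures_dir(), "paired_nickase_mix",
                  "paired_nickase_mix.fastq")
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  names(reads) <- sub("\\s.*$", "", names(reads))
  idx <- sample(nrow(truth), 400)   # spot-check a large subsample
  for (i in idx) {
    expect_identical(truth_read_sequence(truth[i, ], locus$amplicon, vec),
                     unname(reads[truth$read_id[i]]),
                     label = truth$read_id[i])
  }
})

test_that("realized class counts concentrate around the configured mix", {
  locus <- test_locus(); vec <- test_vector()
  d <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 10000, seed = 77L)
  out <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d, "big")
  n <- cfg$n_reads
  for (cl in names(cfg$class_mix)) {
    p <- cfg$class_mix[[cl]]
    if (p == 0) { expect_equal(out$class_counts[[cl]], 0L); next }
    sd3 <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(out$class_counts[[cl]] / n - p), sd3)
  }
})

test_that("impossible microhomology requests fail with the available lengths", {
  locus <- test_locus(); vec <- test_vector()
  d <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 10, class_mix = c(mmej_deletion = 1),
                    mmej_mh_lengths = 8L, mmej_mh_weights = 1,
                    seed = 9L)
  expect_error(simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d),
               "available lengths")
})
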