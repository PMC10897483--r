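write_test_fastq <- function(seqs, quals, path) {
  # quals: list of integer vectors
  ss <- Biostrings::DNAStringSet(setNames(seqs, sprintf("q%03d",
                                                        seq_along(seqs))))
  qs <- Biostrings::BStringSet(vapply(quals, function(q)
    rawToChar(as.raw(q + 33L)), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qs)
  path
}

test_that("sliding-window trimming cuts at the first failing window", {
  d <- withr::local_tempdir()
  seqs <- c("ACGTACGTAC",          # uniformly high quality
            "ACGTACGTAC",          # low-quality tail
            "ACGTACGTAC")          # trims below min_length
  quals <- list(rep(30L, 10),
                c(rep(30L, 6), rep(8L, 4)),
                c(rep(30L, 2), rep(2L, 8)))
  fq <- write_test_fastq(seqs, quals, file.path(d, "t.fastq"))
  # windows of 4 over read 2: means 30,30,30,24.5,19,13.5,8 -> first
  # failing window starts at base 6, so 5 bases are kept
  pre <- preprocess_reads(fq, qual_threshold = 15, min_length = 4,
                          window = 4)
  expect_equal(unname(pre$reads[["q001"]]), "ACGTACGTAC")
  expect_equal(unname(pre$reads[["q002"]]), "ACGTA")
  expect_false("q003" %in% names(pre$reads))
  expect_equal(pre$log$filtered_short, 1L)
  expect_equal(pre$log$kept, 2L)
  expect_error(preprocess_reads(file.path(d, "missing.fastq")),
               "failed reading")
})

test_that("paired reads merge by overlap", {
  d <- withr::local_tempdir()
  set.seed(501)
  full <- random_dna(120)
  r1 <- substr(full, 1, 80)
  r2 <- revcomp(substr(full, 41, 120))
  write_test_fastq(r1, list(rep(30L, 80)), file.path(d, "r1.fastq"))
  write_test_fastq(r2, list(rep(30L, 80)), file.path(d, "r2.fastq"))
  pre <- preprocess_reads(c(file.path(d, "r1.fastq"),
                            file.path(d, "r2.fastq")),
                          merge_pairs = TRUE, min_length = 50)
  expect_equal(unname(pre$reads[[1]]), full)
})

test_that("constructed reads are classified by the decision rule", {
  locus <- test_locus(); vec <- test_vector()
  amp <- locus$amplicon
  # exact amplicon substring
  reads <- c(amp_only = substr(amp$sequence, 100, 400))
  # amplicon left flank + ITR fragment + right flank
  n1 <- min(amp$cut_sites)
  reads["chimeric"] <- paste0(
    substr(amp$sequence, n1 - 59, n1),
    substr(vec$sequence, 1, 40),
    substr(amp$sequence, n1 + 1, n1 + 50))
  # pure vector fragment
  reads["vector_only"] <- substr(vec$sequence, 100, 250)
  # random read sharing no 15-mer with either reference
  set.seed(502)
  k15 <- function(x) seq_kmers(x, 15)
  refk <- c(k15(amp$sequence), k15(revcomp(amp$sequence)),
            k15(vec$sequence), k15(revcomp(vec$sequence)))
  repeat {
    rnd <- random_dna(60)
    if (!any(k15(rnd) %in% refk)) break
  }
  reads["unaligned"] <- rnd
  rc <- classify_reads(reads, amp, vec)
  expect_equal(rc$calls$class,
               c("amplicon_only", "chimeric", "vector_only", "unaligned"))
  chim <- rc$calls[2, ]
  itr5 <- itr_intervals(vec)
  itr5 <- itr5[grepl("^ITR5_", itr5$label), ]
  expect_true(chim$vec_start >= 0 && chim$vec_end <= max(itr5$end))
})

test_that("classification partitions reads and recovers truth at zero error", {
  locus <- test_locus(); vec <- test_vector()
  d <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 600, sub_error_rate = 0, seed = 55L)
  out <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d, "z")
  pre <- preprocess_reads(out$fastq)
  rc <- classify_reads(pre$reads, locus$amplicon, vec)
  # conservation: one class per read, counts sum to input
  expect_equal(nrow(rc$calls), length(pre$reads))
  expect_equal(sum(table(rc$calls$class)) + length(pre$filtered),
               sum(out$class_counts))
  truth <- out$truth
  names(truth)[names(truth) == "class"] <- "class.y"
  m <- merge(rc$calls, truth, by = "read_id")
  # exact truth-class recovery for the unambiguous classes
  for (tc in c("wildtype", "internick_deletion")) {
    expect_true(all(m$class[m$class.y == tc] == "amplicon_only"),
                label = tc)
  }
  expect_true(all(m$class[m$class.y == "vector_insertion"] == "chimeric"))
})

test_that("raising the vector length threshold only shrinks the vector classes", {
  locus <- test_locus(); vec <- test_vector()
  d <- withr::local_tempdir()
  cfg <- sim_config(n_reads = 200, seed = 66L,
                    class_mix = c(wildtype = 0.4, vector_insertion = 0.4,
                                  nhej_indel = 0.2))
  out <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d, "m")
  pre <- preprocess_reads(out$fastq)
  p1 <- classify_params()
  p2 <- p1; p2$vector_min_len <- 70L
  rc1 <- classify_reads(pre$reads, locus$amplicon, vec, p1)
  rc2 <- classify_reads(pre$reads, locus$amplicon, vec, p2)
  in_vec <- function(rc) rc$calls$read_id[rc$calls$class %in%
                                          c("chimeric", "vector_only")]
  expect_true(all(in_vec(rc2) %in% in_vec(rc1)))
  expect_lt(length(in_vec(rc2)), length(in_vec(rc1)))
})
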