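test_that("variant calls follow the edit-window rule", {
  locus <- test_locus()
  amp <- locus$amplicon
  win <- amp$quant_window
  n1 <- min(amp$cut_sites); n2 <- max(amp$cut_sites)
  # exact reference read: unedited
  wt <- align_to_amplicon(amp$sequence, amp)
  v <- call_variant(wt, win)
  expect_equal(v$type, "none")
  expect_false(v$edited)
  # single deletion spanning both cut sites, length = inter-nick distance
  del64 <- paste0(substr(amp$sequence, 1, n1),
                  substr(amp$sequence, n2 + 1, nchar(amp$sequence)))
  v64 <- call_variant(align_to_amplicon(del64, amp), win)
  expect_equal(v64$type, "deletion")
  expect_equal(v64$size, 64L)
  expect_true(v64$edited)
  # one deletion plus one insertion, both in window: complex
  cplx <- paste0(substr(amp$sequence, 1, n1 - 6),
                 substr(amp$sequence, n1 + 1, n2), "TTTTACGT",
                 substr(amp$sequence, n2 + 1, nchar(amp$sequence)))
  vc <- call_variant(align_to_amplicon(cplx, amp), win)
  expect_equal(vc$type, "complex")
  # indel outside the window: unedited but flagged
  off <- paste0(substr(amp$sequence, 1, 50), "ACGTACGT",
                substr(amp$sequence, 51, nchar(amp$sequence)))
  voff <- call_variant(align_to_amplicon(off, amp), win)
  expect_false(voff$edited)
  expect_equal(voff$offwindow_indels, 1L)
})

test_that("aggregation arithmetic matches the two-denominator definition", {
  locus <- test_locus(); vec <- test_vector()
  amp <- locus$amplicon
  n1 <- min(amp$cut_sites); n2 <- max(amp$cut_sites)
  wt <- amp$sequence
  del <- paste0(substr(wt, 1, n1), substr(wt, n2 + 1, nchar(wt)))
  chi <- paste0(substr(wt, 1, n1), substr(vec$sequence, 1, 60),
                substr(wt, n1 + 1, nchar(wt)))
  reads <- setNames(c(rep(wt, 50), rep(del, 40), rep(chi, 10)),
                    sprintf("r%03d", 1:100))
  rc <- classify_reads(reads, amp, vec)
  agg <- aggregate_variants(rc, amp, pair = locus$pair, vector = vec)
  s <- agg$summary
  expect_equal(s$n_total, 100L)
  expect_equal(s$indel_frequency, 0.5)
  expect_equal(s$integration_frequency_reads, 0.10)
  expect_equal(s$integration_frequency_indels, 0.20)
  # conservation: supports sum to classified locus reads
  expect_equal(sum(agg$variants$support), 100L)
  # denominator identity
  expect_equal(s$integration_frequency_indels,
               s$integration_frequency_reads / s$indel_frequency)
  # zero chimeric reads
  agg0 <- aggregate_variants(
    classify_reads(reads[1:90], amp, vec), amp)
  expect_equal(agg0$summary$integration_frequency_reads, 0)
})

test_that("op lists reconstruct reads and supports are conserved on fixtures", {
  res <- run_fixture("paired_nickase_mix")
  rc <- res$read_calls
  cl <- table(rc$calls$class)
  expect_equal(sum(res$variants$support),
               as.integer(cl[["amplicon_only"]] + cl[["chimeric"]]))
  s <- res$summary
  expect_equal(s$integration_frequency_indels,
               s$integration_frequency_reads / s$indel_frequency,
               tolerance = 1e-12)
  # reconstruction on error-free reads
  locus <- test_locus()
  truth <- read_truth("paired_nickase_mix")
  clean <- truth$read_id[truth$err_str == "" | is.na(truth$err_str)]
  clean <- intersect(clean, names(rc$alignments))
  for (id in sample(clean, 100))
    expect_identical(reconstruct_read(rc$alignments[[id]],
                                      locus$amplicon$sequence),
                     rc$alignments[[id]]$read, label = id)
})

test_that("deletion coverage profile equals truth-derived fractions", {
  locus <- test_locus(); vec <- test_vector()
  amp <- locus$amplicon
  d <- withr::local_tempdir()
  # all wildtype: all zeros
  cfgw <- sim_config(n_reads = 30, class_mix = c(wildtype = 1),
                     sub_error_rate = 0, seed = 8L)
  outw <- simulate_dataset(cfgw, amp, vec, locus$pair, d, "w")
  rcw <- classify_reads(preprocess_reads(outw$fastq)$reads, amp, vec)
  profw <- deletion_coverage_profile(rcw, amp)
  expect_true(all(profw$fraction == 0))
  # pure inter-nick deletion: exactly 1 on the inter-nick interval
  cfgd <- sim_config(n_reads = 30,
                     class_mix = c(internick_deletion = 1),
                     sub_error_rate = 0, seed = 8L)
  outd <- simulate_dataset(cfgd, amp, vec, locus$pair, d, "dd")
  rcd <- classify_reads(preprocess_reads(outd$fastq)$reads, amp, vec)
  profd <- deletion_coverage_profile(rcd, amp)
  n1 <- min(amp$cut_sites); n2 <- max(amp$cut_sites)
  inside <- profd$pos >= n1 & profd$pos < n2
  expect_true(all(profd$fraction[inside] == 1))
  expect_true(all(profd$fraction[!inside] == 0))
  # mixed error-free run: equals fractions recomputed from the truth ops
  cfgm <- sim_config(n_reads = 300, sub_error_rate = 0, seed = 12L)
  outm <- simulate_dataset(cfgm, amp, vec, locus$pair, d, "mm")
  rcm <- classify_reads(preprocess_reads(outm$fastq)$reads, amp, vec)
  profm <- deletion_coverage_profile(rcm, amp)
  len <- nchar(amp$sequence)
  del_truth <- integer(len)
  for (ops in strsplit(outm$truth$op_str, ";", fixed = TRUE)) {
    for (tok in ops) {
      f <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (length(f) && f[1] == "D") {
        s <- as.integer(f[2]); l <- as.integer(f[3])
        del_truth[(s + 1):(s + l)] <- del_truth[(s + 1):(s + l)] + 1L
      }
    }
  }
  expect_equal(profm$deleted, del_truth)
  expect_true(all(profm$coverage == nrow(outm$truth)))
})
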