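# rotation depth of a vector insertion at amplicon position p: the
# number of left-shifts indel normalization can apply at the junction
rotation_depth <- function(frag, p, amp_seq) {
  r <- 0L; k <- nchar(frag); ins <- frag
  while (p > 0L && substr(ins, k, k) == substr(amp_seq, p, p)) {
    ins <- paste0(substr(amp_seq, p, p), substr(ins, 1L, k - 1L))
    p <- p - 1L; r <- r + 1L
  }
  r
}

test_that("junctions recover simulated truth intervals", {
  locus <- test_locus(); vec <- test_vector()
  res <- run_fixture("itr_hotspot")          # error-free vector bundle
  truth <- read_truth("itr_hotspot")
  truth <- truth[truth$class == "vector_insertion", ]
  ev <- res$events
  expect_equal(sort(ev$read_id), sort(truth$read_id))
  m <- merge(ev, truth, by = "read_id")
  ins_pos <- as.integer(sub("^V:(\\d+):.*$", "\\1", m$op_str))
  frag <- substr(rep(vec$sequence, nrow(m)), m$vec_start.y + 1L,
                 m$vec_end.y)
  r <- mapply(rotation_depth, frag, ins_pos,
              MoreArgs = list(amp_seq = locus$amplicon$sequence))
  exact <- r == 0L
  expect_gt(mean(exact), 0.5)   # most junctions are rotation-free
  expect_true(all(m$vec_start.x[exact] == m$vec_start.y[exact]))
  expect_true(all(m$vec_end.x[exact] == m$vec_end.y[exact]))
  # rotated junctions shift the resolved interval by the rotation depth,
  # plus a small geometric allowance for chance matches of the rotated-in
  # flank bases against the vector
  expect_true(all(abs(m$vec_start.x - m$vec_start.y) +
                  abs(m$vec_end.x - m$vec_end.y) <= r + 4L))
  # both amplicon breakpoints present for internal insertions
  expect_true(all(!is.na(m$left_bp) & !is.na(m$right_bp)))
})

test_that("single-sided and ambiguous events are handled by the tie rules", {
  locus <- test_locus(); vec <- test_vector()
  amp <- locus$amplicon
  n1 <- min(amp$cut_sites)
  # vector fragment at the read end: one junction only
  one_sided <- paste0(substr(amp$sequence, 150, n1),
                      substr(vec$sequence, 1, 45))
  # insertion matching both ITRs identically (whole A' arm, forward in
  # both due to the palindrome)
  ap <- substr(vec$sequence, 61, 80)
  amb <- paste0(substr(amp$sequence, 100, n1), ap,
                substr(amp$sequence, n1 + 1, 500))
  rc <- classify_reads(c(oneside = one_sided, amb = amb), amp, vec)
  expect_equal(rc$calls$class, c("chimeric", "chimeric"))
  jn <- resolve_junctions(rc, amp, vec)
  ev <- jn$events
  expect_true(is.na(ev$right_bp[ev$read_id == "oneside"]))
  expect_false(is.na(ev$left_bp[ev$read_id == "oneside"]))
  amb_ev <- ev[ev$read_id == "amb", ]
  expect_true(amb_ev$ambiguous)
  expect_false(is.na(amb_ev$alt_start))
  # two identical ambiguous events: each tied location reaches weight 1
  cov <- vector_coverage(rbind(amb_ev, amb_ev), vec)
  covered <- cov$coverage$coverage
  expect_equal(sum(covered > 0), 40)         # both 20 bp locations
  expect_true(all(covered[covered > 0] == 1))
})

test_that("coverage mass is conserved and bounded by event count", {
  vec <- test_vector()
  res <- run_fixture("itr_hotspot")
  ev <- res$events
  cov <- vector_coverage(ev, vec)
  w <- ifelse(ev$ambiguous, 0.5, 1)
  expected <- sum(w * (ev$vec_end - ev$vec_start)) +
    sum(ifelse(ev$ambiguous & !is.na(ev$alt_start),
               0.5 * (ev$alt_end - ev$alt_start), 0))
  expect_equal(sum(cov$coverage$coverage), expected)
  expect_lte(sum(cov$breakpoint_hist), 2L * nrow(ev))
})

test_that("ITR fraction reflects the simulated fragment source", {
  locus <- test_locus(); vec <- test_vector()
  d <- withr::local_tempdir()
  # all fragments from the ITRs
  res <- run_fixture("itr_hotspot")
  expect_equal(res$summary$itr_fraction, 1.0)
  # half from the stuffer
  cfg <- sim_config(n_reads = 400, seed = 31L, sub_error_rate = 0,
                    class_mix = c(wildtype = 0.2, vector_insertion = 0.8),
                    vector_itr_fraction = 0.5)
  out <- simulate_dataset(cfg, locus$amplicon, vec, locus$pair, d, "st")
  rc <- classify_reads(preprocess_reads(out$fastq)$reads,
                       locus$amplicon, vec)
  jn <- resolve_junctions(rc, locus$amplicon, vec)
  frac <- itr_fraction(jn$events, vec)
  n <- nrow(jn$events)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # no events: missing
  expect_true(is.na(itr_fraction(jn$events[0, ], vec)))
})
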