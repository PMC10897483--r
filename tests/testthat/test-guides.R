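test_that("paired-nickase geometry predicts overhangs and perfect deletions", {
  locus <- test_locus()
  geo <- predict_cut_geometry(locus$pair, "D10A_nickase")
  expect_equal(geo$polarity, "5p")
  expect_equal(geo$length, 64L)
  expect_equal(geo$expected_deletion, 64L)
  expect_equal(diff(geo$spans), 64L)
  # nuclease pair: blunt ends, expected deletion = inter-cut distance
  nuc <- predict_cut_geometry(locus$pair, "nuclease")
  expect_equal(nuc$polarity, "blunt")
  expect_equal(nuc$expected_deletion, 64L)
  # PAM-in mirror: 3' overhang, same length
  gp <- guide_spec("p", strrep("ACGTT", 4), "AAGAAT", "+", 100L, 3L)
  gm <- guide_spec("m", strrep("ACGTT", 4), "AAGAAT", "-", 150L, 3L)
  pin <- guide_pair(gp, gm)
  expect_equal(pin$orientation, "PAM-in")
  geo_in <- predict_cut_geometry(pin, "D10A_nickase")
  expect_equal(geo_in$polarity, "3p")
  expect_equal(geo_in$length, pin$inter_nick_distance)
  # coincident nicks: blunt, zero deletion
  g0p <- guide_spec("p", strrep("ACGTT", 4), "AAGAAT", "+", 100L, 3L)
  g0m <- guide_spec("m", strrep("ACGTT", 4), "AAGAAT", "-", 114L, 3L)
  pair0 <- guide_pair(g0p, g0m)
  expect_equal(pair0$inter_nick_distance, 0L)
  expect_equal(predict_cut_geometry(pair0, "D10A_nickase")$polarity,
               "blunt")
  # tandem pair in nickase mode: no DSB expected
  expect_warning(predict_cut_geometry(guide_pair(gp, gp), "D10A_nickase"),
                 "no DSB")
})

test_that("geometry is invariant under reverse complementation", {
  set.seed(401)
  len <- 400L
  for (i in 1:10) {
    st1 <- sample(50:150, 1); st2 <- sample(200:300, 1)
    g1 <- guide_spec("g1", random_dna(21), "AAGAAT", "-", st1, 3L)
    g2 <- guide_spec("g2", random_dna(21), "AAGAAT", "+", st2, 3L)
    fwd <- predict_cut_geometry(guide_pair(g1, g2), "D10A_nickase")
    # mirrored layout: positions reflected, strands flipped, roles swapped
    m1 <- guide_spec("g2m", g2$protospacer, "AAGAAT", "-",
                     len - (st2 + 21L), 3L)
    m2 <- guide_spec("g1m", g1$protospacer, "AAGAAT", "+",
                     len - (st1 + 21L), 3L)
    rev <- predict_cut_geometry(guide_pair(m1, m2), "D10A_nickase")
    expect_equal(rev$polarity, fwd$polarity)
    expect_equal(rev$length, fwd$length)
    expect_equal(rev$expected_deletion, fwd$expected_deletion)
  }
})

test_that("insertion origin distinguishes locus-templated, vector and other", {
  locus <- test_locus(); vec <- test_vector()
  amp <- locus$amplicon; pair <- locus$pair
  n1 <- min(amp$cut_sites)
  ins_locus <- substr(amp$sequence, n1 + 10, n1 + 21)  # 12 bp inter-nick
  expect_equal(
    classify_insertion_origin(ins_locus, amp, pair, vec)$origin,
    "locus_templated")
  ins_itr <- substr(vec$sequence, 21, 40)              # 20 bp ITR fragment
  expect_equal(
    classify_insertion_origin(ins_itr, amp, pair, vec)$origin, "vector")
  set.seed(402)
  repeat {
    rnd <- random_dna(10)
    if (!grepl(rnd, amp$sequence, fixed = TRUE) &&
        !grepl(revcomp(rnd), amp$sequence, fixed = TRUE) &&
        !grepl(rnd, vec$sequence, fixed = TRUE) &&
        !grepl(revcomp(rnd), vec$sequence, fixed = TRUE)) break
  }
  expect_equal(classify_insertion_origin(rnd, amp, pair, vec)$origin,
               "other")
})

test_that("off-target identity handles degenerate PAM bases", {
  g <- guide_spec("g", strrep("ACGTGCA", 3), "AAGAAT", "+", 0L, 3L)
  site_perfect <- paste0(g$protospacer, "AAGAAT")
  expect_equal(offtarget_identity(site_perfect, g), 100)
  # G-position mismatch in the PAM: 26/27
  site_pam <- paste0(g$protospacer, "AACAAT")
  expect_equal(offtarget_identity(site_pam, g), 100 * 26 / 27)
  # all-N site: only the PAM N positions match
  expect_equal(offtarget_identity(strrep("N", 27), g), 100 * 2 / 27)
  # monotone non-increasing in protospacer mismatches
  prev <- 100
  site <- site_perfect
  for (k in 1:5) {
    substr(site, k, k) <- setdiff(c("A", "C", "G", "T"),
                                  substr(site, k, k))[1]
    id <- offtarget_identity(site, g)
    expect_lt(id, prev)
    prev <- id
  }
  expect_error(offtarget_identity("ACGT", g), "length")
})
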