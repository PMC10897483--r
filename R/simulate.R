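# Truth-tagged synthetic amplicon reads.
#
# The generator emulates the outcome spectrum of a paired-nickase (or
# nuclease) amplicon experiment: wildtype reads, small end-joining
# indels at the nicks, clean inter-nick deletions, MMEJ deletions at
# sites with real flanking microhomology, locus-templated insertions,
# truncated-ITR vector insertions with a breakpoint hotspot at an ITR
# arm boundary, and combined (complex) events. Errors are substitution
# only by default; every read carries a truth record sufficient to
# reconstruct it exactly.

sim_classes <- c("wildtype", "nhej_indel", "internick_deletion",
                 "mmej_deletion", "templated_insertion",
                 "vector_insertion", "combined")

#' Simulation configuration
#'
#' @param n_reads number of reads to emit.
#' @param class_mix named probabilities over the seven read classes
#'   (must sum to 1). The default mix reflects a paired-nickase
#'   experiment with 60% edited reads of heterogeneous type, of which
#'   10% of all reads carry a vector insertion.
#' @param sub_error_rate per-base substitution error probability.
#' @param read_length read length; `NULL` emits full-length (merged)
#'   amplicon reads.
#' @param paired emit R1/R2 pairs instead of single-end reads.
#' @param base_quality constant Phred quality for emitted bases.
#' @param itr_breakpoint_bias probability that a vector-insertion
#'   breakpoint falls exactly at the A'-A arm-boundary hotspot of the
#'   chosen ITR (otherwise uniform within the ITR).
#' @param mmej_mh_lengths,mmej_mh_weights microhomology lengths used for
#'   `mmej_deletion` reads and their mixing weights.
#' @param vector_itr_fraction probability that a vector fragment is a
#'   truncated ITR (otherwise an internal fragment of the stuffer).
#' @param vector_revcomp_prob probability a vector fragment is inserted
#'   reverse-complemented. Default 0: the palindromic ITRs make
#'   orientation non-identifiable, so forward insertion keeps truth
#'   comparisons exact.
#' @param min_vector_fragment minimum vector fragment length (keeps
#'   junction fragments above the detection threshold and whole-arm
#'   palindromic ambiguity out of the default bundles).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `SimConfig` object.
#' @export
sim_config <- function(n_reads,
                       class_mix = c(wildtype = 0.40, nhej_indel = 0.08,
                                     internick_deletion = 0.10,
                                     mmej_deletion = 0.17,
                                     templated_insertion = 0.08,
                                     vector_insertion = 0.10,
                                     combined = 0.07),
                       sub_error_rate = 0.001,
                       read_length = NULL, paired = FALSE,
                       base_quality = 30L,
                       itr_breakpoint_bias = 0.8,
                       mmej_mh_lengths = c(0L, 4L, 5L),
                       mmej_mh_weights = rep(1 / 3, 3),
                       vector_itr_fraction = 1.0,
                       vector_revcomp_prob = 0,
                       min_vector_fragment = 25L,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_reads >= 0, all(names(class_mix) %in% sim_classes))
  mix <- setNames(numeric(length(sim_classes)), sim_classes)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9)
    stop("class_mix probabilities must lie in [0,1] and sum to 1")
  if (sub_error_rate < 0 || sub_error_rate > 1)
    stop("sub_error_rate must be in [0,1]")
  if (itr_breakpoint_bias < 0 || itr_breakpoint_bias > 1)
    stop("itr_breakpoint_bias must be in [0,1]")
  stopifnot(length(mmej_mh_lengths) == length(mmej_mh_weights))
  structure(list(n_reads = as.integer(n_reads), class_mix = mix,
                 sub_error_rate = sub_error_rate,
                 read_length = read_length, paired = paired,
                 base_quality = as.integer(base_quality),
                 itr_breakpoint_bias = itr_breakpoint_bias,
                 mmej_mh_lengths = as.integer(mmej_mh_lengths),
                 mmej_mh_weights = mmej_mh_weights / sum(mmej_mh_weights),
                 vector_itr_fraction = vector_itr_fraction,
                 vector_revcomp_prob = vector_revcomp_prob,
                 min_vector_fragment = as.integer(min_vector_fragment),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return a `SimConfig`.
#' @export
sim_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$class_mix)) args$class_mix <- unlist(args$class_mix)
  do.call(sim_config, args)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Build a synthetic AAV vector genome
#'
#' Constructs a vector with two palindromic ITRs flanking a random
#' stuffer. Each ITR is laid out as arms A B B' C C' A' D (5' ITR; the
#' 3' ITR is its reverse complement), with annotated arm intervals and
#' the A'-A and B'-B arm-boundary positions used for breakpoint
#' statistics.
#'
#' @param itr_arm_lengths named lengths `c(A=, B=, C=, D=)`.
#' @param stuffer_length stuffer length between the ITRs.
#' @param seed integer seed.
#' @return a [vector_ref()].
#' @export
build_synthetic_vector <- function(itr_arm_lengths = c(A = 20L, B = 10L,
                                                       C = 10L, D = 10L),
                                   stuffer_length = 500L, seed = 1L) {
  stopifnot(all(itr_arm_lengths > 0L), stuffer_length >= 0L)
  a <- itr_arm_lengths
  withr_seed <- function(expr) { set.seed(seed); expr }
  arms <- withr_seed(list(A = rand_dna(a["A"]), B = rand_dna(a["B"]),
                          C = rand_dna(a["C"]), D = rand_dna(a["D"]),
                          stuffer = rand_dna(stuffer_length)))
  itr5 <- paste0(arms$A, arms$B, revcomp(arms$B), arms$C, revcomp(arms$C),
                 revcomp(arms$A), arms$D)
  itr3 <- revcomp(itr5)
  seqn <- paste0(itr5, arms$stuffer, itr3)
  L <- nchar(seqn); itr_len <- nchar(itr5)
  w5 <- c(A = a[["A"]], B = a[["B"]], Bp = a[["B"]], C = a[["C"]],
          Cp = a[["C"]], Ap = a[["A"]], D = a[["D"]])
  e5 <- cumsum(w5); s5 <- e5 - w5
  # 3' ITR layout mirrors the 5' one
  w3 <- rev(w5); names(w3) <- rev(names(w5))
  e3 <- (L - itr_len) + cumsum(w3); s3 <- e3 - w3
  feats <- rbind(
    data.frame(label = paste0("ITR5_", names(w5)), start = s5, end = e5,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(label = "stuffer", start = itr_len, end = L - itr_len,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(label = paste0("ITR3_", names(w3)), start = s3, end = e3,
               strand = "-", stringsAsFactors = FALSE))
  bpb5 <- a[["A"]] + a[["B"]]               # B|B' junction
  apa5 <- e5[["Cp"]]                        # hairpin-block | A' junction
  bnd <- data.frame(
    label = c("ITR5_BpB_boundary", "ITR5_ApA_boundary",
              "ITR3_BpB_boundary", "ITR3_ApA_boundary"),
    start = c(bpb5, apa5, L - bpb5, L - apa5),
    stringsAsFactors = FALSE)
  bnd$end <- bnd$start; bnd$strand <- "+"
  vector_ref("synthetic_vector", seqn, rbind(feats, bnd))
}

#' Build a synthetic on-target locus with a PAM-out guide pair
#'
#' Generates a random amplicon carrying two SaCas9-style guide sites on
#' opposite strands in PAM-out orientation with nicks `inter_nick`
#' apart, and plants two microhomology-flanked deletion sites inside the
#' inter-nick region: a 23 bp deletion with a 4 bp microhomology and a
#' 10 bp deletion with a 5 bp microhomology, the two recurrent
#' MMEJ-compatible events such designs produce. The construction is
#' validated with [scan_mh()] and resampled until the planted sites are
#' left-aligned with exactly the requested microhomology.
#'
#' @param length amplicon length (default 646, a typical on-target
#'   amplicon).
#' @param inter_nick inter-nick distance (default 64).
#' @param protospacer_len,pam protospacer length and PAM used for both
#'   guides (SaCas9: 21 nt, NNGRRT-compatible PAM).
#' @param nick_offset nick placement, nt from the PAM-proximal
#'   protospacer end.
#' @param seed integer seed.
#' @return `list(amplicon, pair, mh_sites)` where `mh_sites` is a
#'   data.frame of the planted deletions (`start`, `end`, `mh_length`).
#' @export
build_synthetic_locus <- function(length = 646L, inter_nick = 64L,
                                  protospacer_len = 21L, pam = "AAGAAT",
                                  nick_offset = 3L, seed = 101L) {
  stopifnot(length >= 200L, inter_nick >= 20L)
  n1 <- as.integer(length / 2 - inter_nick / 2)
  n2 <- n1 + inter_nick
  # guide footprints (0-based): g1 minus strand, PAM to its left;
  # g2 plus strand, PAM to its right
  g1_start <- n1 - nick_offset
  g2_start <- n2 + nick_offset - protospacer_len
  pam_len <- nchar(pam)
  mh4 <- list(motif_len = 4L, del_len = 23L, start = n1 + 9L)
  mh5 <- list(motif_len = 5L, del_len = 10L, start = n2 - 25L)
  for (attempt in 1:200) {
    set.seed(seed + attempt - 1L)
    s <- strsplit(rand_dna(length), "")[[1]]
    # plant PAMs
    s[(g1_start - pam_len + 1):g1_start] <- strsplit(revcomp(pam), "")[[1]]
    s[(g2_start + protospacer_len + 1):(g2_start + protospacer_len +
                                          pam_len)] <- strsplit(pam, "")[[1]]
    # plant microhomology pairs (copy left motif over right position)
    for (m in list(mh4, mh5)) {
      src <- (m$start + 1):(m$start + m$motif_len)
      s[src + m$del_len] <- s[src]
    }
    seqn <- paste(s, collapse = "")
    amp <- amplicon_ref("synthetic_locus", seqn,
                        cut_sites = c(n1, n2))
    # the perfect inter-nick deletion must be left-aligned as drawn so
    # its normalized signature sits exactly on the nick coordinates
    if (normalize_deletion(n1, n2, seqn)[1] != n1) next
    ok <- TRUE
    for (m in list(mh4, mh5)) {
      del <- normalize_deletion(m$start, m$start + m$del_len, seqn)
      call <- scan_mh(del[1], del[2], amp)
      if (del[1] != m$start || call$mh_length != m$motif_len) ok <- FALSE
    }
    if (!ok) next
    g1 <- guide_spec("g1", revcomp(substr(seqn, g1_start + 1L,
                                          g1_start + protospacer_len)),
                     pam, "-", g1_start, nick_offset, amplicon = amp)
    g2 <- guide_spec("g2", substr(seqn, g2_start + 1L,
                                  g2_start + protospacer_len),
                     pam, "+", g2_start, nick_offset, amplicon = amp)
    pair <- guide_pair(g1, g2)
    if (pair$orientation != "PAM-out" ||
        pair$inter_nick_distance != inter_nick) next
    return(list(amplicon = amp, pair = pair,
                mh_sites = data.frame(
                  start = c(mh4$start, mh5$start),
                  end = c(mh4$start + mh4$del_len, mh5$start + mh5$del_len),
                  mh_length = c(mh4$motif_len, mh5$motif_len))))
  }
  stop("could not construct a consistent synthetic locus")
}

# left-align a deletion interval on a raw sequence (0-based half-open)
normalize_deletion <- function(s, e, seqn) {
  while (s > 0L && substr(seqn, s, s) == substr(seqn, e, e)) {
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

#' Find microhomology-flanked deletion sites on an amplicon
#'
#' Enumerates left-aligned deletion intervals within a window whose
#' flanks carry exactly the requested microhomology length.
#'
#' @param amplicon an [amplicon_ref()].
#' @param mh_length requested microhomology length (>= 0).
#' @param size_range deletion sizes to consider, `c(min, max)`.
#' @param window half-open interval the deletion must overlap; defaults
#'   to the amplicon quantification window.
#' @return data.frame `start`, `end`, `size`, `mh_length`, `mh_sequence`.
#' @export
find_mh_sites <- function(amplicon, mh_length, size_range = c(8L, 30L),
                          window = NULL) {
  window <- window %||% amplicon$quant_window
  len <- nchar(amplicon$sequence)
  out <- list()
  for (s in seq.int(max(0L, window[1] - 5L), window[2])) {
    for (size in seq.int(size_range[1], size_range[2])) {
      e <- s + size
      if (e + mh_length + 1L > len) next
      if (e <= window[1] || s >= window[2]) next
      norm <- normalize_deletion(s, e, amplicon$sequence)
      if (norm[1] != s) next                       # not left-aligned
      call <- scan_mh(s, e, amplicon)
      if (call$mh_length == mh_length)
        out[[length(out) + 1L]] <-
          data.frame(start = s, end = e, size = size,
                     mh_length = mh_length,
                     mh_sequence = call$mh_sequence,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0), mh_length = integer(0),
                      mh_sequence = character(0)))
  do.call(rbind, out)
}

# canonicalize an op string: deletions left-aligned, insertions rotated
# to their leftmost equivalent placement, so truth coordinates coincide
# with the pipeline's normalized variant keys (the reconstructed read is
# unchanged). Vector ops are left untouched: their interval is the
# physical truth.
canonicalize_op_str <- function(op_str, amplicon) {
  if (!nzchar(op_str)) return(op_str)
  seqn <- amplicon$sequence
  toks <- strsplit(strsplit(op_str, ";", fixed = TRUE)[[1]], ":",
                   fixed = TRUE)
  out <- vapply(toks, function(t) {
    p <- as.integer(t[2])
    if (t[1] == "D") {
      len <- as.integer(t[3])
      norm <- normalize_deletion(p, p + len, seqn)
      sprintf("D:%d:%d", norm[1], len)
    } else if (t[1] == "I") {
      ins <- t[4]
      k <- nchar(ins)
      while (p > 0L && substr(ins, k, k) == substr(seqn, p, p)) {
        ins <- paste0(substr(seqn, p, p), substr(ins, 1L, k - 1L))
        p <- p - 1L
      }
      sprintf("I:%d:%d:%s", p, k, ins)
    } else paste(t, collapse = ":")
  }, character(1))
  paste(out, collapse = ";")
}

# ---- truth op encoding -------------------------------------------------
# op tokens: D:<start>:<len>  I:<pos>:<len>:<SEQ>  V:<pos>:<vs>:<ve>:<orient>
# err tokens: <readpos>:<BASE>  (0-based, post-op read coordinates)

apply_truth_ops <- function(op_str, amplicon, vector) {
  ref <- amplicon$sequence
  if (!nzchar(op_str)) return(ref)
  toks <- strsplit(strsplit(op_str, ";", fixed = TRUE)[[1]], ":",
                   fixed = TRUE)
  # apply right-to-left so earlier coordinates stay valid
  pos <- vapply(toks, function(t) as.integer(t[2]), integer(1))
  for (t in toks[order(pos, decreasing = TRUE)]) {
    p <- as.integer(t[2])
    if (t[1] == "D") {
      len <- as.integer(t[3])
      ref <- paste0(substr(ref, 1, p), substr(ref, p + len + 1L,
                                              nchar(ref)))
    } else if (t[1] == "I") {
      ref <- paste0(substr(ref, 1, p), t[4], substr(ref, p + 1L,
                                                    nchar(ref)))
    } else if (t[1] == "V") {
      frag <- substr(vector$sequence, as.integer(t[3]) + 1L,
                     as.integer(t[4]))
      if (t[5] == "-") frag <- revcomp(frag)
      ref <- paste0(substr(ref, 1, p), frag, substr(ref, p + 1L,
                                                    nchar(ref)))
    } else stop("unknown truth op: ", t[1])
  }
  ref
}

apply_truth_errors <- function(read, err_str) {
  if (!nzchar(err_str)) return(read)
  for (t in strsplit(strsplit(err_str, ";", fixed = TRUE)[[1]], ":",
                     fixed = TRUE)) {
    p <- as.integer(t[1])
    substr(read, p + 1L, p + 1L) <- t[2]
  }
  read
}

#' Reconstruct the emitted read from a truth record
#'
#' Applies a truth record's ops to the reference, then its recorded
#' substitution errors; the result must equal the emitted read.
#' @param truth_row one row of a truth table.
#' @param amplicon,vector the references the dataset was simulated from.
#' @return the read sequence.
#' @export
truth_read_sequence <- function(truth_row, amplicon, vector) {
  apply_truth_errors(apply_truth_ops(truth_row$op_str, amplicon, vector),
                     truth_row$err_str)
}

# draw one vector fragment; returns list(vs, ve, orient, at_hotspot)
draw_vector_fragment <- function(cfg, vector) {
  L <- nchar(vector$sequence)
  itrs <- itr_intervals(vector)
  itr5_end <- max(itrs$end[grepl("^ITR5_", itrs$label)])
  itr3_start <- min(itrs$start[grepl("^ITR3_", itrs$label)])
  minf <- cfg$min_vector_fragment
  if (runif(1) >= cfg$vector_itr_fraction) {
    # internal stuffer fragment
    len <- sample(minf:(2L * minf + 10L), 1L)
    vs <- sample(itr5_end:(itr3_start - len), 1L)
    return(list(vs = vs, ve = vs + len, at_hotspot = FALSE))
  }
  five <- runif(1) < 0.5
  hot <- runif(1) < cfg$itr_breakpoint_bias
  if (five) {
    b <- if (hot)
      vector$boundaries$pos[vector$boundaries$label == "ITR5_ApA_boundary"]
    else sample(minf:itr5_end, 1L)
    list(vs = 0L, ve = as.integer(b), at_hotspot = hot)
  } else {
    b <- if (hot)
      vector$boundaries$pos[vector$boundaries$label == "ITR3_ApA_boundary"]
    else sample(itr3_start:(L - minf), 1L)
    list(vs = as.integer(b), ve = L, at_hotspot = hot)
  }
}

# draw the op string (and annotations) for one read of a given class
draw_read_ops <- function(class, cfg, amplicon, vector, pair, mh_cache) {
  n1 <- min(amplicon$cut_sites); n2 <- max(amplicon$cut_sites)
  switch(class,
    wildtype = list(op_str = "", mh = NA_integer_),
    nhej_indel = {
      nick <- sample(c(n1, n2), 1L)
      if (runif(1) < 0.5) {
        len <- sample(1:10, 1L)
        s <- max(0L, nick - sample(0:len, 1L))
        list(op_str = sprintf("D:%d:%d", s, len), mh = NA_integer_)
      } else {
        len <- sample(1:5, 1L)
        list(op_str = sprintf("I:%d:%d:%s", nick, len, rand_dna(len)),
             mh = NA_integer_)
      }
    },
    internick_deletion =
      list(op_str = sprintf("D:%d:%d", n1, n2 - n1), mh = NA_integer_),
    mmej_deletion = {
      m <- sample(cfg$mmej_mh_lengths, 1L, prob = cfg$mmej_mh_weights)
      sites <- mh_cache[[as.character(m)]]
      site <- sites[sample(nrow(sites), 1L), ]
      list(op_str = sprintf("D:%d:%d", site$start, site$end - site$start),
           mh = m)
    },
    templated_insertion = {
      len <- sample(5:25, 1L)
      src <- sample(n1:(n2 - len), 1L)
      ins <- substr(amplicon$sequence, src + 1L, src + len)
      list(op_str = sprintf("I:%d:%d:%s", sample(c(n1, n2), 1L), len, ins),
           mh = NA_integer_)
    },
    vector_insertion = {
      fr <- draw_vector_fragment(cfg, vector)
      orient <- if (runif(1) < cfg$vector_revcomp_prob) "-" else "+"
      list(op_str = sprintf("V:%d:%d:%d:%s", sample(c(n1, n2), 1L),
                            fr$vs, fr$ve, orient),
           mh = NA_integer_, at_hotspot = fr$at_hotspot)
    },
    combined = {
      dlen <- sample(3:12, 1L); ilen <- sample(3:8, 1L)
      list(op_str = sprintf("D:%d:%d;I:%d:%d:%s", n1, dlen, n2, ilen,
                            rand_dna(ilen)),
           mh = NA_integer_)
    })
}

write_fastq <- function(ids, seqs, qual_char, path) {
  ss <- Biostrings::DNAStringSet(setNames(seqs, ids))
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep(qual_char, n), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate a truth-tagged amplicon dataset
#'
#' Draws class counts multinomially from the configured mix, builds each
#' read by applying its class-specific ops to the amplicon (vector
#' fragments for `vector_insertion` reads), overlays substitution
#' errors, and writes FASTQ plus a truth TSV. `mmej_deletion` reads are
#' only generated at reference positions where the requested flanking
#' microhomology truly exists; if none exists the call fails listing the
#' available microhomology lengths.
#'
#' @param cfg a [sim_config()].
#' @param amplicon,vector,pair references (see [build_synthetic_locus()]
#'   and [build_synthetic_vector()]).
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return list with `fastq` (character vector of paths), `truth_path`,
#'   `truth` (data.frame) and `class_counts`.
#' @export
simulate_dataset <- function(cfg, amplicon, vector, pair, dir,
                             prefix = "sim") {
  stopifnot(inherits(cfg, "SimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  counts <- as.integer(rmultinom(1, cfg$n_reads, cfg$class_mix))
  names(counts) <- sim_classes
  # microhomology site catalogue for the requested lengths
  mh_cache <- list()
  if (counts[["mmej_deletion"]] > 0L) {
    for (m in unique(cfg$mmej_mh_lengths)) {
      sites <- find_mh_sites(amplicon, m)
      if (!nrow(sites)) {
        avail <- Filter(function(x) nrow(find_mh_sites(amplicon, x)) > 0,
                        0:8)
        stop("no deletion site with a ", m, " bp microhomology exists ",
             "in the quantification window; available lengths: ",
             paste(avail, collapse = ", "))
      }
      mh_cache[[as.character(m)]] <- sites
    }
  }
  classes <- sample(rep(sim_classes, counts))
  n <- length(classes)
  ids <- sprintf("r%06d", seq_len(n))
  op_str <- character(n); err_str <- character(n)
  mh_len <- rep(NA_integer_, n)
  vec_start <- rep(NA_integer_, n); vec_end <- rep(NA_integer_, n)
  vec_orient <- rep(NA_character_, n); at_hotspot <- rep(NA, n)
  seqs <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    d <- draw_read_ops(classes[i], cfg, amplicon, vector, pair, mh_cache)
    d$op_str <- canonicalize_op_str(d$op_str, amplicon)
    op_str[i] <- d$op_str
    mh_len[i] <- d$mh
    if (classes[i] == "vector_insertion") {
      t <- strsplit(sub("^V:", "", d$op_str), ":", fixed = TRUE)[[1]]
      vec_start[i] <- as.integer(t[2]); vec_end[i] <- as.integer(t[3])
      vec_orient[i] <- t[4]; at_hotspot[i] <- d$at_hotspot
    }
    read <- apply_truth_ops(d$op_str, amplicon, vector)
    if (cfg$sub_error_rate > 0) {
      nerr <- rbinom(1, nchar(read), cfg$sub_error_rate)
      if (nerr > 0L) {
        pos <- sort(sample(nchar(read), nerr))
        errs <- character(nerr)
        for (k in seq_len(nerr)) {
          old <- substr(read, pos[k], pos[k])
          new <- sample(setdiff(bases, old), 1L)
          substr(read, pos[k], pos[k]) <- new
          errs[k] <- sprintf("%d:%s", pos[k] - 1L, new)
        }
        err_str[i] <- paste(errs, collapse = ";")
      }
    }
    seqs[i] <- read
  }
  truth <- data.frame(read_id = ids, class = classes, op_str = op_str,
                      err_str = err_str, mh_length = mh_len,
                      vec_start = vec_start, vec_end = vec_end,
                      vec_orient = vec_orient, at_hotspot = at_hotspot,
                      stringsAsFactors = FALSE)
  qual_char <- rawToChar(as.raw(cfg$base_quality + 33L))
  if (cfg$paired) {
    rl <- cfg$read_length %||% max(nchar(seqs))
    r1 <- substr(seqs, 1L, rl)
    r2 <- vapply(seqs, function(x)
      revcomp(substr(x, max(1L, nchar(x) - rl + 1L), nchar(x))),
      character(1), USE.NAMES = FALSE)
    fq <- c(file.path(dir, paste0(prefix, "_R1.fastq")),
            file.path(dir, paste0(prefix, "_R2.fastq")))
    write_fastq(ids, r1, qual_char, fq[1])
    write_fastq(ids, r2, qual_char, fq[2])
  } else {
    emitted <- if (is.null(cfg$read_length)) seqs
               else substr(seqs, 1L, cfg$read_length)
    fq <- file.path(dir, paste0(prefix, ".fastq"))
    write_fastq(ids, emitted, qual_char, fq)
  }
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(fastq = fq, truth_path = truth_path, truth = truth,
       class_counts = counts)
}
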