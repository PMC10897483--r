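# Read preprocessing and two-pass classification.
#
# Reads are first anchored on the amplicon; portions the amplicon
# alignment cannot absorb (large insertion segments, or whole unanchored
# reads) are screened against a k-mer index of the vector genome and, on
# a seed hit, aligned locally to the vector on both strands. A read is
# chimeric only when both an adequate amplicon anchor and a qualifying
# vector hit exist.

#' Default classification parameters
#'
#' `anchor_min`: minimum gapless amplicon block (nt) at
#' `anchor_min_ident` identity for a read to count as locus-anchored.
#' `vector_min_len` / `vector_min_ident`: minimum length and identity of
#' a vector hit. `kmer`: seed length for the vector prescreen. At these
#' defaults the chance of a spurious vector hit per read is negligible
#' for kb-scale vectors.
#' @return named list of parameters.
#' @export
classify_params <- function() {
  list(anchor_min = 25L, anchor_min_ident = 0.90,
       vector_min_len = 15L, vector_min_ident = 0.90, kmer = 12L)
}

#' Quality-trim and length-filter FASTQ reads
#'
#' Sliding-window quality trimming from the 5' end: the read is
#' truncated at the start of the first window whose mean Phred quality
#' falls below `qual_threshold`. Reads shorter than `min_length` after
#' trimming are dropped and counted. Paired files are optionally merged
#' by overlap (suffix of R1 vs prefix of reverse-complemented R2, at
#' most 10% mismatches over at least `min_overlap` bases); pairs that do
#' not merge are dropped and counted.
#'
#' @param fastq_in path to FASTQ(.gz), or `c(R1, R2)` with
#'   `merge_pairs = TRUE`.
#' @param qual_threshold mean window quality below which the read is
#'   cut.
#' @param min_length minimum post-trim read length.
#' @param window sliding window width.
#' @param merge_pairs merge R1/R2 by overlap.
#' @param min_overlap minimum overlap for pair merging.
#' @return list with `reads` (named character vector of sequences),
#'   `log` (input/trimmed/filtered counts) and `filtered` (read ids
#'   dropped).
#' @export
preprocess_reads <- function(fastq_in, qual_threshold = 15L,
                             min_length = 50L, window = 4L,
                             merge_pairs = FALSE, min_overlap = 10L) {
  read_fq <- function(path) {
    x <- tryCatch(
      withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        # Biostrings notes that the per-record mcols are dropped when
        # rebuilding the set; nothing we use is lost
        warning = function(w) {
          if (grepl("metadata columns", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e)
        stop("failed reading FASTQ ", path, ": ", conditionMessage(e)))
    list(ids = sub("\\s.*$", "", names(x)),
         seqs = as.character(x),
         quals = as(Biostrings::quality(x), "IntegerList"))
  }
  trim_one <- function(seqn, qual, w, thr) {
    n <- length(qual)
    if (n < w) return(if (mean(qual) < thr) "" else seqn)
    mw <- vapply(seq_len(n - w + 1L), function(i) mean(qual[i:(i + w - 1L)]),
                 numeric(1))
    bad <- which(mw < thr)
    if (!length(bad)) seqn else substr(seqn, 1L, bad[1] - 1L)
  }
  if (merge_pairs) {
    stopifnot(length(fastq_in) == 2L)
    r1 <- read_fq(fastq_in[1]); r2 <- read_fq(fastq_in[2])
    if (!identical(r1$ids, r2$ids))
      stop("R1/R2 read ids do not correspond")
    n_in <- length(r1$ids)
    merged <- character(n_in); ok <- logical(n_in)
    for (i in seq_len(n_in)) {
      a <- r1$seqs[i]; b <- revcomp(r2$seqs[i])
      la <- nchar(a); lb <- nchar(b)
      for (ov in seq.int(min(la, lb), min_overlap)) {
        sa <- substr(a, la - ov + 1L, la); sb <- substr(b, 1L, ov)
        mism <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
        if (mism <= 0.1 * ov) {
          merged[i] <- paste0(a, substr(b, ov + 1L, lb)); ok[i] <- TRUE
          break
        }
      }
    }
    ids <- r1$ids[ok]; seqs <- merged[ok]
    quals <- NULL
    unmerged <- sum(!ok)
    trimmed <- setNames(seqs, ids)  # merged reads pass quality implicitly
  } else {
    fq <- read_fq(fastq_in[1])
    n_in <- length(fq$ids); unmerged <- 0L
    trimmed <- setNames(vapply(seq_len(n_in), function(i)
      trim_one(fq$seqs[i], fq$quals[[i]], window, qual_threshold),
      character(1)), fq$ids)
  }
  short <- nchar(trimmed) < min_length
  list(reads = trimmed[!short],
       log = list(input = n_in, unmerged = as.integer(unmerged),
                  filtered_short = as.integer(sum(short)),
                  kept = as.integer(sum(!short))),
       filtered = names(trimmed)[short])
}

#' Build a k-mer prescreen index for the vector genome
#' @param vector a [vector_ref()].
#' @param k seed length.
#' @return set of k-mers present on either strand (environment-backed).
#' @export
vector_kmer_index <- function(vector, k = 12L) {
  kmers <- unique(c(seq_kmers(vector$sequence, k),
                    seq_kmers(revcomp(vector$sequence), k)))
  env <- new.env(hash = TRUE, size = length(kmers))
  for (km in kmers) assign(km, TRUE, envir = env)
  structure(list(env = env, k = k), class = "KmerIndex")
}

kmer_hit <- function(index, segment) {
  for (km in seq_kmers(segment, index$k))
    if (exists(km, envir = index$env, inherits = FALSE)) return(TRUE)
  FALSE
}

# identity and aligned length of an AlignmentResult
aln_stats <- function(aln) {
  ops <- aln$ops
  matched <- sum(ops$length[ops$op == "match"])
  aligned <- sum(ops$length[ops$op %in% c("match", "substitution")])
  list(matched = matched, aligned = aligned,
       identity = if (aligned > 0L) matched / aligned else 0)
}

# longest gapless block (consecutive match/substitution ops) passing an
# identity threshold; returns its length
best_anchor_block <- function(ops, min_ident) {
  best <- 0L
  i <- 1L; n <- nrow(ops)
  while (i <= n) {
    if (ops$op[i] %in% c("match", "substitution")) {
      j <- i
      while (j < n && ops$op[j + 1L] %in% c("match", "substitution"))
        j <- j + 1L
      len <- sum(ops$length[i:j])
      matched <- sum(ops$length[i:j][ops$op[i:j] == "match"])
      if (len > best && matched / len >= min_ident) best <- len
      i <- j + 1L
    } else i <- i + 1L
  }
  best
}

# Candidate vector segments of an anchored read. Internal foreign
# sequence must appear as an insertion op (rejoining the diagonal makes
# smearing more expensive than the gap), but a terminal foreign segment
# can be absorbed against the free reference overhang as scattered
# mismatches and deletions. Terminal candidates are therefore taken as
# everything outside the outermost clean match runs (length >= run_min).
# Returns a list of lists (read_start, read_end, kind, left_bp,
# right_bp, keep_ops).
candidate_segments <- function(aln, min_len, run_min = 15L) {
  ops <- aln$ops
  n_ops <- nrow(ops)
  read_len <- nchar(aln$read)
  clean <- which(ops$op == "match" & ops$length >= run_min)
  cands <- list()
  if (length(clean)) {
    j0 <- clean[1]; j1 <- clean[length(clean)]
    if (j0 > 1L) {
      consumes <- ops$op[seq_len(j0 - 1L)] != "deletion"
      if (any(consumes)) {
        seg_end <- ops$read_start[j0]
        if (seg_end >= min_len)
          cands[[length(cands) + 1L]] <- list(
            read_start = 0L, read_end = seg_end, kind = "prefix",
            left_bp = NA_integer_, right_bp = ops$ref_start[j0],
            keep_ops = j0:n_ops)
      }
    }
    if (j1 < n_ops) {
      tail_ops <- (j1 + 1L):n_ops
      seg_start <- min(ops$read_start[tail_ops][
        ops$op[tail_ops] != "deletion"], read_len)
      if (read_len - seg_start >= min_len)
        cands[[length(cands) + 1L]] <- list(
          read_start = seg_start, read_end = read_len, kind = "suffix",
          left_bp = ops$ref_start[j1] + ops$length[j1],
          right_bp = NA_integer_, keep_ops = 1L:j1)
    }
  }
  ins <- which(ops$op == "insertion" & ops$length >= min_len)
  for (r in ins) {
    rs <- ops$read_start[r]; re <- rs + ops$length[r]
    dup <- any(vapply(cands, function(cc)
      rs >= cc$read_start && re <= cc$read_end, logical(1)))
    if (!dup)
      cands[[length(cands) + 1L]] <- list(
        read_start = rs, read_end = re, kind = "insertion",
        left_bp = ops$ref_start[r], right_bp = ops$ref_start[r],
        keep_ops = seq_len(n_ops))
  }
  cands
}

# local-align a segment against the vector, both strands, and detect
# equal-score alternative locations (palindromic ITRs). Deterministic
# preference: forward orientation, then smallest vector start.
scan_vector_segment <- function(segment, vector, params, index = NULL,
                                scoring = default_scoring()) {
  if (!is.null(index) && !kmer_hit(index, segment)) return(NULL)
  L <- nchar(vector$sequence)
  fwd <- affine_align(segment, vector$sequence, scoring, "local")
  rev <- affine_align(segment, revcomp(vector$sequence), scoring, "local")
  use_fwd <- fwd$score >= rev$score
  best <- if (use_fwd) fwd else rev
  st <- aln_stats(best)
  if (st$aligned < params$vector_min_len ||
      st$identity < params$vector_min_ident)
    return(NULL)
  vs <- if (use_fwd) best$ref_start else L - best$ref_end
  ve <- if (use_fwd) best$ref_end else L - best$ref_start
  # alternative location: mask the primary interval and realign
  masked <- vector$sequence
  substr(masked, vs + 1L, ve) <- strrep("N", ve - vs)
  alt_f <- affine_align(segment, masked, scoring, "local")
  alt_r <- affine_align(segment, revcomp(masked), scoring, "local")
  alt <- if (alt_f$score >= alt_r$score) alt_f else alt_r
  ambiguous <- alt$score == best$score
  alt_int <- if (ambiguous) {
    if (alt_f$score >= alt_r$score) c(alt$ref_start, alt$ref_end)
    else c(L - alt$ref_end, L - alt$ref_start)
  } else c(NA_integer_, NA_integer_)
  list(vec_start = vs, vec_end = ve,
       orient = if (use_fwd) "+" else "-",
       identity = st$identity, matched_len = st$aligned,
       score = best$score, ambiguous = ambiguous,
       alt_start = alt_int[1], alt_end = alt_int[2])
}

#' Classify reads against the amplicon and the vector genome
#'
#' Two-pass partition of preprocessed reads into `amplicon_only`,
#' `chimeric`, `vector_only` and `unaligned` (every read gets exactly
#' one class). Pass 1 aligns each read glocally to the amplicon; the
#' read is locus-anchored if it contains a gapless aligned block of at
#' least `anchor_min` nt at `anchor_min_ident` identity. Pass 2 screens
#' the unexplained portions — insertion segments of anchored reads, or
#' the whole read otherwise — against the vector k-mer index and, on a
#' seed hit, aligns them locally to the vector on both strands.
#'
#' @param reads named character vector from [preprocess_reads()].
#' @param amplicon an [amplicon_ref()].
#' @param vector a [vector_ref()].
#' @param params see [classify_params()].
#' @param scoring see [default_scoring()].
#' @return a `ReadCalls` object: list with `calls` (one row per read:
#'   class, anchor and vector-hit metrics) and `alignments` (named list
#'   of `AlignmentResult`s for anchored reads).
#' @export
classify_reads <- function(reads, amplicon, vector,
                           params = classify_params(),
                           scoring = default_scoring()) {
  index <- vector_kmer_index(vector, params$kmer)
  n <- length(reads)
  cls <- character(n)
  anchor <- integer(n); ident <- rep(NA_real_, n)
  vhit <- rep(list(NULL), n)
  alns <- rep(list(NULL), n)
  for (i in seq_len(n)) {
    aln <- align_to_amplicon(reads[[i]], amplicon, scoring)
    anchor[i] <- best_anchor_block(aln$ops, params$anchor_min_ident)
    ident[i] <- aln_stats(aln)$identity
    anchored <- anchor[i] >= params$anchor_min
    hit <- NULL
    if (anchored) {
      cands <- candidate_segments(aln, params$vector_min_len)
      lens <- vapply(cands, function(cc) cc$read_end - cc$read_start,
                     integer(1))
      for (cc in cands[order(-lens)]) {
        seg <- substr(aln$read, cc$read_start + 1L, cc$read_end)
        hit <- scan_vector_segment(seg, vector, params, index, scoring)
        if (!is.null(hit)) {
          hit$seg_kind <- cc$kind
          hit$left_bp <- cc$left_bp; hit$right_bp <- cc$right_bp
          if (cc$kind != "insertion") {
            # truncate the stored alignment at the junction so the
            # smeared terminal segment cannot leak into profiles
            aln$ops <- aln$ops[cc$keep_ops, , drop = FALSE]
            rownames(aln$ops) <- NULL
            aln$ref_start <- min(aln$ops$ref_start)
            last <- nrow(aln$ops)
            aln$ref_end <- aln$ops$ref_start[last] +
              ifelse(aln$ops$op[last] == "insertion", 0L,
                     aln$ops$length[last])
          }
          break
        }
      }
      alns[[i]] <- aln
      cls[i] <- if (is.null(hit)) "amplicon_only" else "chimeric"
    } else {
      hit <- scan_vector_segment(reads[[i]], vector, params, index,
                                 scoring)
      cls[i] <- if (is.null(hit)) "unaligned" else "vector_only"
    }
    if (!is.null(hit)) vhit[[i]] <- hit
  }
  getv <- function(field, default) vapply(vhit, function(h) {
    v <- if (is.null(h)) NULL else h[[field]]
    if (is.null(v)) default else v
  }, default)
  calls <- data.frame(
    read_id = names(reads) %||% sprintf("read%06d", seq_len(n)),
    class = cls, anchor_len = anchor, amplicon_identity = ident,
    vec_start = getv("vec_start", NA_integer_),
    vec_end = getv("vec_end", NA_integer_),
    vec_orient = getv("orient", NA_character_),
    vec_identity = getv("identity", NA_real_),
    vec_matched_len = getv("matched_len", NA_integer_),
    ambiguous = getv("ambiguous", NA),
    alt_start = getv("alt_start", NA_integer_),
    alt_end = getv("alt_end", NA_integer_),
    seg_kind = getv("seg_kind", NA_character_),
    left_bp = getv("left_bp", NA_integer_),
    right_bp = getv("right_bp", NA_integer_),
    stringsAsFactors = FALSE)
  names(alns) <- calls$read_id
  structure(list(calls = calls,
                 alignments = alns[!vapply(alns, is.null, logical(1))]),
            class = "ReadCalls")
}

#' @export
print.ReadCalls <- function(x, ...) {
  print(table(x$calls$class))
  invisible(x)
}
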