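# Affine-gap alignment of reads against the amplicon.
#
# Scoring follows the convention score = +match per identity, -mismatch
# per substitution, and -(gap_open + k * gap_extend) for a gap of length
# k. Defaults {5, 4, 25, 1} are the parameter set used for amplicon
# variant alignment throughout the package; the heavy gap-open keeps
# scattered 1-bp gaps from fragmenting real indels.

#' Default alignment scoring
#' @return named list `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (all penalties positive).
#' @export
default_scoring <- function() {
  list(match = 5L, mismatch = 4L, gap_open = 25L, gap_extend = 1L)
}

#' Affine-gap pairwise alignment
#'
#' Optimal alignment of a read against a reference under affine gap
#' costs. `mode = "glocal"` is global in the read and local in the
#' reference (free reference overhangs; every read base is placed);
#' `mode = "local"` is Smith-Waterman. Tie-breaking is deterministic
#' (diagonal preferred over deletion over insertion; smallest reference
#' coordinate on equal end scores).
#'
#' @param read,ref DNA strings (read may contain N; N never matches).
#' @param scoring see [default_scoring()].
#' @param mode `"glocal"` or `"local"`.
#' @return an `AlignmentResult`: list with `score`, `ops` (data.frame
#'   `op`, `ref_start`, `read_start`, `length`; coordinates 0-based),
#'   `ref_start`, `ref_end`, `read_start`, `read_end`, `read`.
#' @export
affine_align <- function(read, ref, scoring = default_scoring(),
                         mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  if (!nzchar(read)) stop("empty read")
  res <- affine_align_cpp(read, ref, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend, mode)
  res$read <- read
  class(res) <- "AlignmentResult"
  res
}

#' Align an amplicon-only read
#'
#' Glocal affine-gap alignment (read global, amplicon local) with indels
#' left-aligned to their minimal reference start, so that equivalent
#' placements of the same indel collapse onto one normalized signature.
#' Reads that are exact substrings of the amplicon short-circuit the
#' dynamic program.
#'
#' @param read DNA string.
#' @param amplicon an [amplicon_ref()].
#' @param scoring see [default_scoring()].
#' @return a normalized `AlignmentResult`.
#' @export
align_to_amplicon <- function(read, amplicon, scoring = default_scoring()) {
  if (!nzchar(read)) stop("empty read")
  fast <- ungapped_alignment(read, amplicon$sequence, scoring)
  if (!is.null(fast)) return(fast)
  normalize_ops(affine_align(read, amplicon$sequence, scoring, "glocal"),
                amplicon)
}

# Ungapped placement with <= 2 mismatches. Under the default scoring a
# gap costs at least gap_open + gap_extend while converting a mismatch
# into a match regains only match + mismatch per base, so for k
# mismatches with k * (match + mismatch) < gap_open + gap_extend the
# ungapped placement is provably the optimal glocal alignment.
ungapped_alignment <- function(read, ref, scoring) {
  n <- nchar(read)
  max_mm <- min(2L, (scoring$gap_open + scoring$gap_extend - 1L) %/%
                      (scoring$match + scoring$mismatch))
  if (max_mm < 0L) return(NULL)
  hit <- Biostrings::matchPattern(read, ref, max.mismatch = max_mm)
  if (length(hit) == 0L) return(NULL)
  rb <- strsplit(read, "")[[1]]
  # best placement = fewest mismatches, leftmost on ties
  cand <- lapply(Biostrings::start(hit) - 1L, function(s) {
    tb <- strsplit(substr(ref, s + 1L, s + n), "")[[1]]
    list(s = s, is_match = rb == tb & rb %in% c("A", "C", "G", "T"))
  })
  mm <- vapply(cand, function(x) sum(!x$is_match), integer(1))
  pick <- cand[[which.min(mm)]]
  s <- pick$s; is_match <- pick$is_match
  if (sum(!is_match) > max_mm) return(NULL)     # N-containing edge case
  runs <- rle(is_match)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
  ops <- data.frame(
    op = ifelse(runs$values, "match", "substitution"),
    ref_start = s + starts, read_start = starts,
    length = runs$lengths, stringsAsFactors = FALSE)
  structure(list(
    score = scoring$match * sum(is_match) -
      scoring$mismatch * sum(!is_match),
    ref_start = s, ref_end = s + n, read_start = 0L, read_end = n,
    ops = ops, read = read), class = "AlignmentResult")
}

# merge adjacent ops of the same type that are contiguous on both axes
merge_ops <- function(ops) {
  if (nrow(ops) < 2L) return(ops)
  keep <- rep(TRUE, nrow(ops))
  i <- 1L
  for (j in 2:nrow(ops)) {
    same <- ops$op[j] == ops$op[i]
    contig <- switch(ops$op[j],
      insertion = ops$read_start[j] == ops$read_start[i] + ops$length[i],
      deletion = ops$ref_start[j] == ops$ref_start[i] + ops$length[i],
      ops$ref_start[j] == ops$ref_start[i] + ops$length[i] &&
        ops$read_start[j] == ops$read_start[i] + ops$length[i])
    if (same && contig && ops$length[j] > 0L) {
      ops$length[i] <- ops$length[i] + ops$length[j]
      keep[j] <- FALSE
    } else if (ops$length[j] > 0L) i <- j
    else keep[j] <- FALSE
  }
  ops <- ops[keep & ops$length > 0L, , drop = FALSE]
  rownames(ops) <- NULL
  ops
}

#' Left-align indels in an alignment
#'
#' Shifts every insertion and deletion to its minimal reference start
#' among sequence-equivalent placements (the reconstruction of the read
#' from the ops is unchanged). Idempotent. Shifts only pass through
#' matching columns, so alignments around substitutions are preserved.
#'
#' @param aln an `AlignmentResult`.
#' @param amplicon the [amplicon_ref()] (or any object with a
#'   `$sequence`) the alignment refers to.
#' @return the normalized `AlignmentResult`.
#' @export
normalize_ops <- function(aln, amplicon) {
  ref <- if (is.character(amplicon)) amplicon else amplicon$sequence
  ops <- aln$ops
  read <- aln$read
  i <- 1L
  while (i <= nrow(ops)) {
    if (ops$op[i] %in% c("insertion", "deletion") && i > 1L &&
        ops$op[i - 1L] == "match" && ops$length[i - 1L] > 0L) {
      shifted <- 0L
      while (ops$length[i - 1L] - shifted > 0L) {
        s <- ops$ref_start[i] - shifted    # current 0-based indel ref start
        k <- ops$length[i]
        ok <- if (ops$op[i] == "deletion") {
          s > 0L && substr(ref, s, s) == substr(ref, s + k, s + k)
        } else {
          rs <- ops$read_start[i] - shifted
          s > 0L && substr(read, rs + k, rs + k) == substr(ref, s, s)
        }
        if (!ok) break
        shifted <- shifted + 1L
      }
      if (shifted > 0L) {
        d <- shifted
        trail <- data.frame(op = "match",
                            ref_start = ops$ref_start[i] +
                              (if (ops$op[i] == "deletion") ops$length[i] else 0L) - d,
                            read_start = ops$read_start[i] +
                              (if (ops$op[i] == "insertion") ops$length[i] else 0L) - d,
                            length = d, stringsAsFactors = FALSE)
        ops$length[i - 1L] <- ops$length[i - 1L] - d
        ops$ref_start[i] <- ops$ref_start[i] - d
        ops$read_start[i] <- ops$read_start[i] - d
        ops <- rbind(ops[seq_len(i), , drop = FALSE], trail,
                     ops[-seq_len(i), , drop = FALSE])
        ops <- merge_ops(ops)
        i <- 1L  # restart: merges can enable further shifts
        next
      }
    }
    i <- i + 1L
  }
  aln$ops <- merge_ops(ops)
  rownames(aln$ops) <- NULL
  aln
}

# inserted sequence of an insertion op row
op_seq <- function(aln, row) {
  substr(aln$read, aln$ops$read_start[row] + 1L,
         aln$ops$read_start[row] + aln$ops$length[row])
}

#' Reconstruct a read from its alignment ops
#'
#' Applies the op list to the reference; used by truth-consistency and
#' reconstruction checks.
#' @param aln an `AlignmentResult`.
#' @param ref reference sequence (string or object with `$sequence`).
#' @return the reconstructed read string.
#' @export
reconstruct_read <- function(aln, ref) {
  ref <- if (is.character(ref)) ref else ref$sequence
  parts <- character(0)
  for (r in seq_len(nrow(aln$ops))) {
    o <- aln$ops[r, ]
    parts <- c(parts, switch(o$op,
      match = substr(ref, o$ref_start + 1L, o$ref_start + o$length),
      substitution = substr(aln$read, o$read_start + 1L,
                            o$read_start + o$length),
      insertion = substr(aln$read, o$read_start + 1L,
                         o$read_start + o$length),
      deletion = ""))
  }
  paste(parts, collapse = "")
}
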