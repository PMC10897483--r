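# Microhomology at deletion junctions.
#
# The microhomology length of a deletion [s, e) is its
# placement-ambiguity length: the largest m for which the m bases at the
# deletion start equal the m bases immediately after the deletion end.
# It is computed on the reference only, after left-alignment, so it is a
# property of the deletion itself and robust to read errors.

#' Score microhomology at a deletion junction
#'
#' @param s,e deletion interval `[s, e)` on the amplicon, 0-based
#'   half-open, left-aligned.
#' @param amplicon an [amplicon_ref()] (or a plain sequence string).
#' @return an `MHCall`: list with `start`, `end`, `mh_length`,
#'   `mh_sequence`.
#' @export
scan_mh <- function(s, e, amplicon) {
  seqn <- if (is.character(amplicon)) amplicon else amplicon$sequence
  len <- nchar(seqn)
  s <- as.integer(s); e <- as.integer(e)
  if (s < 0L || s >= e || e > len)
    stop("deletion interval [", s, ",", e, ") out of bounds for length ",
         len)
  m <- 0L
  while (e + m < len &&
         substr(seqn, s + m + 1L, s + m + 1L) ==
         substr(seqn, e + m + 1L, e + m + 1L))
    m <- m + 1L
  structure(list(start = s, end = e, mh_length = m,
                 mh_sequence = if (m > 0L) substr(seqn, s + 1L, s + m)
                               else ""),
            class = "MHCall")
}

#' Summarise microhomology across a variant table
#'
#' Computes, over pure-deletion variants weighted by read support, the
#' fraction of deletions whose junction microhomology exceeds
#' `mh_threshold` bp, a support-weighted histogram of deletions by
#' microhomology length (0, 1, 2, 3, 4, >=5), and the most frequent
#' microhomology-associated deletions.
#'
#' @param variant_table table from [aggregate_variants()]; rows of
#'   `type == "deletion"` are scored.
#' @param amplicon the [amplicon_ref()] the table refers to.
#' @param mh_threshold strictly-greater-than threshold for the headline
#'   fraction (default 2 bp).
#' @param top_n how many recurrent deletions to list.
#' @return list with `fraction_gt` (NA when there are no deletions),
#'   `histogram` (named support counts), `table` (per-deletion
#'   microhomology calls) and `top` (by support).
#' @export
mh_summary <- function(variant_table, amplicon, mh_threshold = 2L,
                       top_n = 5L) {
  del <- variant_table[variant_table$type == "deletion", , drop = FALSE]
  bins <- c("0", "1", "2", "3", "4", ">=5")
  if (!nrow(del))
    return(list(fraction_gt = NA_real_,
                histogram = setNames(rep(0, length(bins)), bins),
                table = data.frame(), top = data.frame()))
  calls <- lapply(seq_len(nrow(del)), function(i)
    scan_mh(del$start[i], del$start[i] + del$size[i], amplicon))
  del$mh_length <- vapply(calls, `[[`, integer(1), "mh_length")
  del$mh_sequence <- vapply(calls, `[[`, character(1), "mh_sequence")
  w <- del$support
  hist <- setNames(rep(0, length(bins)), bins)
  bin_of <- ifelse(del$mh_length >= 5L, ">=5", as.character(del$mh_length))
  for (b in unique(bin_of)) hist[b] <- sum(w[bin_of == b])
  ord <- order(-del$support)
  list(fraction_gt = sum(w[del$mh_length > mh_threshold]) / sum(w),
       histogram = hist,
       table = del[ord, c("signature", "start", "size", "mh_length",
                          "mh_sequence", "support"), drop = FALSE],
       top = utils::head(del[ord, , drop = FALSE], top_n))
}
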