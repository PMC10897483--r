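# Paired-nickase geometry, insertion-origin classification and
# degenerate-PAM off-target identity.

#' Predict cut-site geometry of a guide pair
#'
#' For paired D10A nickases the two nicks on opposite strands form a
#' staggered double-strand break spanning the inter-nick interval:
#' PAM-out pairs leave 5' overhangs, PAM-in pairs 3' overhangs, each of
#' length equal to the inter-nick distance, and clean excision of the
#' inter-nick segment produces the signature "perfect" deletion of that
#' length. Nuclease pairs cut bluntly at both sites, with the expected
#' perfect deletion equal to the inter-cut distance. A tandem
#' (same-strand) pair in nickase mode nicks only one strand and no DSB
#' is expected.
#'
#' @param pair a [guide_pair()].
#' @param enzyme_mode `"D10A_nickase"` or `"nuclease"`.
#' @return an `OverhangPrediction`: list with `polarity` (`"5p"`,
#'   `"3p"`, `"blunt"` or `"none"`), `length`, `spans` (inter-nick
#'   interval on the amplicon), `expected_deletion` and
#'   `inter_nick_distance`.
#' @export
predict_cut_geometry <- function(pair,
                                 enzyme_mode = c("D10A_nickase",
                                                 "nuclease")) {
  enzyme_mode <- match.arg(enzyme_mode)
  stopifnot(inherits(pair, "GuidePair"))
  n1 <- nick_position(pair$g1); n2 <- nick_position(pair$g2)
  spans <- c(min(n1, n2), max(n1, n2))
  d <- pair$inter_nick_distance
  if (enzyme_mode == "nuclease") {
    out <- list(polarity = "blunt", length = 0L, spans = spans,
                expected_deletion = d, inter_nick_distance = d)
  } else if (pair$orientation == "tandem") {
    warning("tandem same-strand pair in nickase mode: no DSB expected")
    out <- list(polarity = "none", length = 0L, spans = spans,
                expected_deletion = NA_integer_,
                inter_nick_distance = d)
  } else if (d == 0L) {
    out <- list(polarity = "blunt", length = 0L, spans = spans,
                expected_deletion = 0L, inter_nick_distance = 0L)
  } else {
    out <- list(polarity = if (pair$orientation == "PAM-out") "5p"
                           else "3p",
                length = d, spans = spans, expected_deletion = d,
                inter_nick_distance = d)
  }
  structure(out, class = "OverhangPrediction")
}

#' @export
print.OverhangPrediction <- function(x, ...) {
  cat(sprintf(paste0("OverhangPrediction: %s overhang, %d bp, ",
                     "expected perfect deletion %s bp\n"),
              x$polarity, x$length, x$expected_deletion))
  invisible(x)
}

#' Classify the origin of an inserted sequence
#'
#' Decides whether an insertion copies the locus between the two nicks
#' (`locus_templated`), derives from the vector genome (`vector`), or
#' neither (`other`). Insertions shorter than 10 bp must match exactly
#' (short random matches are otherwise likely); longer insertions
#' qualify at `min_ident` identity over at least 90% of their length.
#' Forward and reverse-complement matches both count. Ties resolve to
#' `locus_templated`.
#'
#' @param inserted_seq the inserted sequence (length >= 1).
#' @param amplicon an [amplicon_ref()].
#' @param pair the [guide_pair()] defining the inter-nick region.
#' @param vector a [vector_ref()].
#' @param min_ident identity threshold for insertions >= 10 bp.
#' @return list with `origin` and `interval` (matched interval on the
#'   source sequence, or `NULL`).
#' @export
classify_insertion_origin <- function(inserted_seq, amplicon, pair,
                                      vector, min_ident = 0.90) {
  stopifnot(nchar(inserted_seq) >= 1L)
  n1 <- nick_position(pair$g1); n2 <- nick_position(pair$g2)
  region <- substr(amplicon$sequence, min(n1, n2) + 1L, max(n1, n2))
  match_against <- function(target) {
    len <- nchar(inserted_seq)
    if (len < 10L) {
      for (q in unique(c(inserted_seq, revcomp(inserted_seq)))) {
        hit <- regexpr(q, target, fixed = TRUE)
        if (hit > 0L)
          return(c(as.integer(hit) - 1L, as.integer(hit) - 1L + len))
      }
      return(NULL)
    }
    if (len > nchar(target) * 2L && !grepl(substr(inserted_seq, 1, 10),
                                           target, fixed = TRUE))
      return(NULL)
    best <- NULL
    for (q in unique(c(inserted_seq, revcomp(inserted_seq)))) {
      a <- affine_align(q, target, mode = "local")
      st <- aln_stats(a)
      if (st$aligned >= 0.9 * len && st$identity >= min_ident &&
          (is.null(best) || a$score > best$score))
        best <- list(score = a$score,
                     interval = c(a$ref_start, a$ref_end))
    }
    if (is.null(best)) NULL else best$interval
  }
  iv <- match_against(region)
  if (!is.null(iv))
    return(list(origin = "locus_templated",
                interval = iv + min(n1, n2)))
  iv <- match_against(vector$sequence)
  if (!is.null(iv)) return(list(origin = "vector", interval = iv))
  list(origin = "other", interval = NULL)
}

#' Percent identity of a candidate off-target site to a guide
#'
#' Position-by-position identity over the protospacer plus PAM, where a
#' PAM position matches if the site base falls within the IUPAC
#' degenerate class of the PAM pattern (all positions weighted
#' equally). For the site, an N matches only a pattern N.
#'
#' @param site_seq candidate site, protospacer followed by PAM (same
#'   length as `guide$protospacer` plus `pam_pattern`).
#' @param guide a [guide_spec()].
#' @param pam_pattern IUPAC PAM pattern (default the SaCas9 `"NNGRRT"`).
#' @return percent identity in `[0, 100]`.
#' @export
offtarget_identity <- function(site_seq, guide, pam_pattern = "NNGRRT") {
  site_seq <- toupper(site_seq)
  proto <- guide$protospacer
  lp <- nchar(proto); lm <- nchar(pam_pattern)
  if (nchar(site_seq) != lp + lm)
    stop("site length ", nchar(site_seq), " != protospacer + PAM length ",
         lp + lm)
  sp <- strsplit(site_seq, "")[[1]]
  matches <- sum(sp[seq_len(lp)] == strsplit(proto, "")[[1]])
  pam_site <- sp[lp + seq_len(lm)]
  pat <- strsplit(toupper(pam_pattern), "")[[1]]
  for (i in seq_len(lm)) {
    site_class <- iupac_class(pam_site[i])
    if (all(site_class %in% iupac_class(pat[i])))
      matches <- matches + 1L
  }
  100 * matches / (lp + lm)
}
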