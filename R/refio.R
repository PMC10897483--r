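# Reference objects and coordinate conventions.
#
# All coordinates are 0-based and half-open; cut and nick sites are
# between-base integers in [0, len]. A nick at position p falls between
# bases p-1 and p (0-based), so a deletion of [p1, p2) removes exactly
# the inter-nick segment.

#' Amplicon reference
#'
#' An on-target amplicon with its expected cut sites and the window
#' within which indels count as edits.
#'
#' @param name identifier.
#' @param sequence uppercase DNA string (A/C/G/T only; curated references
#'   must not contain N).
#' @param cut_sites integer vector of between-base positions in
#'   `[0, len]`.
#' @param quant_window half-open interval `c(lo, hi)` on the amplicon
#'   that must contain all cut sites. Defaults to
#'   `[min(cut_sites) - 5, max(cut_sites) + 5)`, wide enough to capture
#'   both nick sites plus end-joining jitter.
#' @return an `AmpliconRef` object.
#' @export
amplicon_ref <- function(name, sequence, cut_sites = integer(0),
                         quant_window = NULL) {
  sequence <- check_dna(sequence, paste0("amplicon '", name, "'"),
                        allow_n = FALSE)
  len <- nchar(sequence)
  cut_sites <- as.integer(cut_sites)
  if (any(cut_sites < 0L | cut_sites > len))
    stop("cut sites must lie in [0, ", len, "]")
  if (is.null(quant_window)) {
    quant_window <- if (length(cut_sites))
      c(max(0L, min(cut_sites) - 5L), min(len, max(cut_sites) + 5L))
    else c(0L, len)
  }
  quant_window <- as.integer(quant_window)
  if (length(quant_window) != 2L || quant_window[1] < 0L ||
      quant_window[2] > len || quant_window[1] >= quant_window[2])
    stop("quant_window must be a half-open interval within [0, ", len, ")")
  if (length(cut_sites) &&
      (min(cut_sites) < quant_window[1] || max(cut_sites) > quant_window[2]))
    stop("quant_window must contain all cut sites")
  structure(list(name = name, sequence = sequence,
                 cut_sites = sort(cut_sites), quant_window = quant_window),
            class = "AmpliconRef")
}

#' @export
print.AmpliconRef <- function(x, ...) {
  cat(sprintf("AmpliconRef '%s': %d bp, cut sites [%s], window [%d,%d)\n",
              x$name, nchar(x$sequence),
              paste(x$cut_sites, collapse = ","),
              x$quant_window[1], x$quant_window[2]))
  invisible(x)
}

#' Guide specification
#'
#' A protospacer/PAM record anchored on the amplicon. The protospacer
#' must map exactly (no mismatches) at the declared strand and position.
#'
#' @param name guide identifier.
#' @param protospacer DNA string, as read on the protospacer strand.
#' @param pam PAM sequence on the protospacer strand (3' of the
#'   protospacer).
#' @param strand `"+"` or `"-"` relative to the amplicon.
#' @param protospacer_start 0-based start of the protospacer footprint
#'   on the amplicon (plus strand coordinates for both strands).
#' @param nick_offset distance (nt) of the nick from the PAM-proximal
#'   protospacer end, measured into the protospacer. Default 3, the
#'   conventional Cas9 cut placement 3 nt 5' of the PAM; the offset is a
#'   parameter, not an assertion.
#' @param amplicon optional [amplicon_ref()]; when given the protospacer
#'   placement is verified against the sequence.
#' @return a `GuideSpec` object.
#' @export
guide_spec <- function(name, protospacer, pam, strand, protospacer_start,
                       nick_offset = 3L, amplicon = NULL) {
  protospacer <- check_dna(protospacer, paste0("guide '", name, "'"))
  pam <- toupper(pam)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  protospacer_start <- as.integer(protospacer_start)
  nick_offset <- as.integer(nick_offset)
  if (nick_offset < 0L || nick_offset > nchar(protospacer))
    stop("nick_offset must be in [0, protospacer length]")
  g <- structure(list(name = name, protospacer = protospacer, pam = pam,
                      strand = strand, protospacer_start = protospacer_start,
                      nick_offset = nick_offset),
                 class = "GuideSpec")
  if (!is.null(amplicon)) {
    L <- nchar(protospacer)
    if (protospacer_start < 0L ||
        protospacer_start + L > nchar(amplicon$sequence))
      stop("guide '", name, "': protospacer footprint outside amplicon")
    found <- substr(amplicon$sequence, protospacer_start + 1L,
                    protospacer_start + L)
    expected <- if (strand == "+") protospacer else revcomp(protospacer)
    if (found != expected)
      stop("guide '", name, "': protospacer not found on amplicon at ",
           "position ", protospacer_start, " (", strand, " strand)")
    np <- nick_position(g)
    if (np < 0L || np > nchar(amplicon$sequence))
      stop("guide '", name, "': nick position outside amplicon")
  }
  g
}

#' Nick position of a guide
#'
#' Between-base coordinate of the single-strand nick on the amplicon.
#' The nick sits `nick_offset` nt from the PAM-proximal protospacer end,
#' measured into the protospacer on the protospacer strand. For a plus
#' strand guide the PAM-proximal end is the right protospacer boundary;
#' for a minus-strand guide it is the left boundary, so positions are
#' strand-symmetric under reverse complementation of the amplicon.
#'
#' @param g a [guide_spec()].
#' @return integer between-base position.
#' @export
nick_position <- function(g) {
  stopifnot(inherits(g, "GuideSpec"))
  L <- nchar(g$protospacer)
  if (g$strand == "+") g$protospacer_start + L - g$nick_offset
  else g$protospacer_start + g$nick_offset
}

#' Paired-guide record
#'
#' Derives (never takes on trust) the pair orientation from the guide
#' strands and PAM placements, and the inter-nick distance from the two
#' nick positions.
#'
#' Orientation classes: `PAM-out` when the guides sit on opposite
#' strands with both PAMs facing away from the inter-guide interval,
#' `PAM-in` when they face each other, `tandem` when both guides are on
#' the same strand.
#'
#' @param g1,g2 [guide_spec()] objects.
#' @return a `GuidePair` object with fields `orientation` and
#'   `inter_nick_distance`.
#' @export
guide_pair <- function(g1, g2) {
  stopifnot(inherits(g1, "GuideSpec"), inherits(g2, "GuideSpec"))
  n1 <- nick_position(g1); n2 <- nick_position(g2)
  orientation <- if (g1$strand == g2$strand) "tandem" else {
    # PAM side on the amplicon: right of footprint for +, left for -
    left <- if (g1$protospacer_start <= g2$protospacer_start) g1 else g2
    right <- if (g1$protospacer_start <= g2$protospacer_start) g2 else g1
    if (left$strand == "-" && right$strand == "+") "PAM-out" else "PAM-in"
  }
  structure(list(g1 = g1, g2 = g2, orientation = orientation,
                 inter_nick_distance = abs(n2 - n1)),
            class = "GuidePair")
}

#' @export
print.GuidePair <- function(x, ...) {
  cat(sprintf("GuidePair %s/%s: %s, inter-nick distance %d bp\n",
              x$g1$name, x$g2$name, x$orientation, x$inter_nick_distance))
  invisible(x)
}

#' Vector genome reference
#'
#' An AAV vector genome with feature annotation. ITR arm features use
#' labels of the form `ITR5_A`, `ITR5_Ap`, ... `ITR3_D` (`p` marks the
#' prime arm). Arm-boundary positions (the A'-A and B'-B junctions used
#' for breakpoint statistics) are annotated as zero-length features
#' labelled `ITR5_ApA_boundary`, `ITR5_BpB_boundary`, `ITR3_ApA_boundary`
#' and `ITR3_BpB_boundary`.
#'
#' @param name identifier.
#' @param sequence DNA string.
#' @param features data.frame with columns `label`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @return a `VectorRef` object; `$boundaries` holds the arm-boundary
#'   table split out of the features.
#' @export
vector_ref <- function(name, sequence, features) {
  sequence <- check_dna(sequence, paste0("vector '", name, "'"))
  len <- nchar(sequence)
  stopifnot(is.data.frame(features),
            all(c("label", "start", "end", "strand") %in% names(features)))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 0L | features$end > len |
          features$start > features$end))
    stop("vector feature intervals must lie within [0, ", len, "]")
  is_boundary <- grepl("_boundary$", features$label)
  boundaries <- features[is_boundary, , drop = FALSE]
  arms <- features[!is_boundary, , drop = FALSE]
  itr_arms <- arms[grepl("^ITR[53]_", arms$label), , drop = FALSE]
  if (nrow(itr_arms)) {
    for (itr in unique(sub("_.*$", "", itr_arms$label))) {
      need <- paste0(itr, c("_ApA_boundary", "_BpB_boundary"))
      if (!all(need %in% boundaries$label))
        stop("vector '", name, "': ", itr,
             " lacks annotated ApA/BpB arm boundaries")
    }
  }
  structure(list(name = name, sequence = sequence,
                 features = arms,
                 boundaries = data.frame(label = boundaries$label,
                                         pos = boundaries$start,
                                         stringsAsFactors = FALSE)),
            class = "VectorRef")
}

#' @export
print.VectorRef <- function(x, ...) {
  cat(sprintf("VectorRef '%s': %d bp, %d features, %d arm boundaries\n",
              x$name, nchar(x$sequence), nrow(x$features),
              nrow(x$boundaries)))
  invisible(x)
}

# intervals of ITR features (label, start, end)
itr_intervals <- function(vec) {
  vec$features[grepl("^ITR[53]_", vec$features$label), , drop = FALSE]
}

read_fasta_one <- function(path, what) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop(what, ": no sequences in ", path)
  if (anyDuplicated(names(ss)))
    stop(what, ": duplicate sequence names in ", path)
  if (length(ss) > 1L)
    stop(what, ": expected a single sequence in ", path,
         ", found ", length(ss))
  list(name = sub("\\s.*$", "", names(ss)[1]),
       sequence = toupper(as.character(ss[[1]])))
}

read_tsv_checked <- function(path, required, what) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#"),
                  error = function(e)
                    stop("malformed TSV ", path, ": ", conditionMessage(e)))
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(what, " file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  tab
}

#' Load and validate pipeline references
#'
#' Reads the amplicon FASTA, the vector FASTA with its BED-like feature
#' TSV, and the guides TSV, validates them against each other, computes
#' nick positions and derives the pair orientation. Cut sites on the
#' returned amplicon are the two nick positions.
#'
#' @param amplicon_path single-record FASTA.
#' @param vector_path single-record FASTA for the vector genome.
#' @param guides_path TSV with columns `name`, `protospacer`, `pam`,
#'   `strand`, `start`, `nick_offset` (exactly two rows).
#' @param vector_features_path 4+ column TSV (`label`, `start`, `end`,
#'   `strand`) annotating the vector, including ITR arms and arm
#'   boundaries (see [vector_ref()]).
#' @param quant_window optional override for the edit-counting window.
#' @return `list(amplicon, vector, pair)`.
#' @export
load_references <- function(amplicon_path, vector_path, guides_path,
                            vector_features_path, quant_window = NULL) {
  for (p in c(amplicon_path, vector_path, guides_path,
              vector_features_path))
    if (!file.exists(p)) stop("file not found: ", p)
  amp <- read_fasta_one(amplicon_path, "amplicon")
  vec <- read_fasta_one(vector_path, "vector")
  gtab <- read_tsv_checked(guides_path,
                           c("name", "protospacer", "pam", "strand",
                             "start", "nick_offset"), "guides")
  if (nrow(gtab) != 2L)
    stop("guides file ", guides_path, ": expected 2 guides, found ",
         nrow(gtab))
  amp0 <- amplicon_ref(amp$name, amp$sequence)
  guides <- lapply(seq_len(2), function(i)
    guide_spec(gtab$name[i], gtab$protospacer[i], gtab$pam[i],
               gtab$strand[i], gtab$start[i], gtab$nick_offset[i],
               amplicon = amp0))
  pair <- guide_pair(guides[[1]], guides[[2]])
  cuts <- sort(c(nick_position(guides[[1]]), nick_position(guides[[2]])))
  amplicon <- amplicon_ref(amp$name, amp$sequence, cut_sites = cuts,
                           quant_window = quant_window)
  ftab <- read_tsv_checked(vector_features_path,
                           c("label", "start", "end", "strand"),
                           "vector features")
  vector <- vector_ref(vec$name, vec$sequence, ftab)
  list(amplicon = amplicon, vector = vector, pair = pair)
}

#' Write pipeline references to disk
#'
#' Inverse of [load_references()]: emits the amplicon FASTA, vector
#' FASTA, vector feature TSV and guides TSV so a reference bundle can be
#' round-tripped.
#'
#' @param amplicon,vector,pair objects as returned by
#'   [load_references()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of file paths written.
#' @export
write_references <- function(amplicon, vector, pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    amplicon = file.path(dir, "amplicon.fa"),
    vector = file.path(dir, "vector.fa"),
    guides = file.path(dir, "guides.tsv"),
    vector_features = file.path(dir, "vector_features.tsv"))
  amp_ss <- Biostrings::DNAStringSet(setNames(amplicon$sequence,
                                              amplicon$name))
  Biostrings::writeXStringSet(amp_ss, paths$amplicon)
  vec_ss <- Biostrings::DNAStringSet(setNames(vector$sequence, vector$name))
  Biostrings::writeXStringSet(vec_ss, paths$vector)
  gtab <- do.call(rbind, lapply(list(pair$g1, pair$g2), function(g)
    data.frame(name = g$name, protospacer = g$protospacer, pam = g$pam,
               strand = g$strand, start = g$protospacer_start,
               nick_offset = g$nick_offset, stringsAsFactors = FALSE)))
  write.table(gtab, paths$guides, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ftab <- rbind(vector$features,
                data.frame(label = vector$boundaries$label,
                           start = vector$boundaries$pos,
                           end = vector$boundaries$pos,
                           strand = "+", stringsAsFactors = FALSE))
  write.table(ftab, paths$vector_features, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
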