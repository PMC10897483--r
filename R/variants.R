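# Variant calling on amplicon-only reads and aggregation into editing
# and integration summaries.
#
# A read is "edited" iff at least one indel op of its normalized
# alignment overlaps the quantification window; substitutions never
# count as edits. Chimeric reads are included as vector_insertion
# variants and counted as edited, so integration can be reported both
# as % of total reads and as % of edited reads.

indel_overlaps_window <- function(ops, window) {
  lo <- window[1]; hi <- window[2]
  is_del <- ops$op == "deletion"
  is_ins <- ops$op == "insertion"
  (is_del & ops$ref_start < hi & ops$ref_start + ops$length > lo) |
    (is_ins & ops$ref_start >= lo & ops$ref_start <= hi)
}

#' Call the variant carried by one aligned read
#'
#' @param aln normalized `AlignmentResult` from [align_to_amplicon()].
#' @param quant_window half-open interval within which indels count as
#'   edits.
#' @return list with `signature` (stable normalized op key; `"WT"` when
#'   unedited), `type` (`none`, `deletion`, `insertion` or `complex`),
#'   `size` (net indel size in the window), `start`, `edited`, and
#'   `offwindow_indels` (indels present but outside the window; such
#'   reads are unedited but flagged).
#' @export
call_variant <- function(aln, quant_window) {
  ops <- aln$ops
  indel <- ops$op %in% c("insertion", "deletion")
  inwin <- indel_overlaps_window(ops, quant_window)
  win_ops <- ops[indel & inwin, , drop = FALSE]
  offwindow <- sum(indel & !inwin)
  if (!nrow(win_ops))
    return(list(signature = "WT", type = "none", size = 0L,
                start = NA_integer_, edited = FALSE,
                offwindow_indels = offwindow))
  toks <- vapply(seq_len(nrow(win_ops)), function(r) {
    o <- win_ops[r, ]
    if (o$op == "deletion") sprintf("D:%d:%d", o$ref_start, o$length)
    else sprintf("I:%d:%d:%s", o$ref_start, o$length,
                 substr(aln$read, o$read_start + 1L,
                        o$read_start + o$length))
  }, character(1))
  type <- if (nrow(win_ops) > 1L) "complex"
          else if (win_ops$op[1] == "deletion") "deletion" else "insertion"
  net <- sum(ifelse(win_ops$op == "insertion", win_ops$length,
                    -win_ops$length))
  list(signature = paste(toks, collapse = ";"), type = type,
       size = if (type == "deletion") win_ops$length[1]
              else if (type == "insertion") win_ops$length[1]
              else net,
       start = win_ops$ref_start[1], edited = TRUE,
       offwindow_indels = offwindow)
}

#' Aggregate read calls into a variant table and summary report
#'
#' Amplicon-only reads contribute normalized indel variants; chimeric
#' reads contribute `vector_insertion` variants keyed by their vector
#' interval and are counted as edited. Frequencies are computed against
#' both denominators: all locus reads (amplicon-only plus chimeric) and
#' edited reads.
#'
#' @param read_calls a `ReadCalls` object from [classify_reads()].
#' @param amplicon an [amplicon_ref()].
#' @param pair,vector optional; when both are given, insertion variants
#'   are annotated with their origin via [classify_insertion_origin()].
#' @param quant_window override for the edit window (defaults to the
#'   amplicon's).
#' @return list with `variants` (data.frame), `per_read` (per-read call
#'   table) and `summary` (a `SummaryReport`).
#' @export
aggregate_variants <- function(read_calls, amplicon, pair = NULL,
                               vector = NULL, quant_window = NULL) {
  window <- quant_window %||% amplicon$quant_window
  calls <- read_calls$calls
  amp_ids <- calls$read_id[calls$class == "amplicon_only"]
  chi_ids <- calls$read_id[calls$class == "chimeric"]
  rows <- list(); per_read <- list()
  for (id in amp_ids) {
    v <- call_variant(read_calls$alignments[[id]], window)
    per_read[[id]] <- data.frame(read_id = id, class = "amplicon_only",
                                 signature = v$signature, type = v$type,
                                 edited = v$edited,
                                 offwindow_indels = v$offwindow_indels,
                                 stringsAsFactors = FALSE)
    rows[[id]] <- v
  }
  for (id in chi_ids) {
    cc <- calls[calls$read_id == id, ]
    sig <- sprintf("VEC:%d-%d:%s", cc$vec_start, cc$vec_end,
                   cc$vec_orient)
    per_read[[id]] <- data.frame(read_id = id, class = "chimeric",
                                 signature = sig,
                                 type = "vector_insertion", edited = TRUE,
                                 offwindow_indels = 0L,
                                 stringsAsFactors = FALSE)
    rows[[id]] <- list(signature = sig, type = "vector_insertion",
                       size = cc$vec_end - cc$vec_start,
                       start = NA_integer_, edited = TRUE,
                       offwindow_indels = 0L)
  }
  per_read <- if (length(per_read)) do.call(rbind, per_read)
              else data.frame(read_id = character(0))
  n_total <- length(amp_ids) + length(chi_ids)
  if (n_total == 0L) {
    variants <- data.frame(signature = character(0), type = character(0),
                           size = integer(0), start = integer(0),
                           support = integer(0), freq_total = numeric(0),
                           freq_edited = numeric(0))
    summary <- summary_report(0L, 0L, 0L, variants, window)
    return(list(variants = variants, per_read = per_read,
                summary = summary))
  }
  sig <- vapply(rows, `[[`, character(1), "signature")
  tab <- data.frame(signature = sig,
                    type = vapply(rows, `[[`, character(1), "type"),
                    size = vapply(rows, function(r) as.integer(r$size),
                                  integer(1)),
                    start = vapply(rows, function(r)
                      as.integer(r$start %||% NA_integer_), integer(1)),
                    edited = vapply(rows, `[[`, logical(1), "edited"),
                    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(tab, tab$signature), function(d)
    data.frame(signature = d$signature[1], type = d$type[1],
               size = d$size[1], start = d$start[1], support = nrow(d),
               stringsAsFactors = FALSE)))
  n_edited <- sum(tab$edited)
  agg$freq_total <- agg$support / n_total
  agg$freq_edited <- if (n_edited > 0L) {
    ifelse(agg$signature == "WT", NA_real_, agg$support / n_edited)
  } else NA_real_
  agg <- agg[order(-agg$support, agg$signature), , drop = FALSE]
  rownames(agg) <- NULL
  if (!is.null(pair) && !is.null(vector)) {
    agg$origin <- NA_character_
    ins <- which(agg$type == "insertion")
    for (i in ins) {
      seqi <- sub("^I:\\d+:\\d+:", "", agg$signature[i])
      agg$origin[i] <- classify_insertion_origin(seqi, amplicon, pair,
                                                 vector)$origin
    }
  }
  n_chimeric <- length(chi_ids)
  summary <- summary_report(n_total, n_edited, n_chimeric, agg, window)
  list(variants = agg, per_read = per_read, summary = summary)
}

# build the SummaryReport object
summary_report <- function(n_total, n_edited, n_chimeric, variants,
                           window) {
  structure(list(
    n_total = as.integer(n_total), n_edited = as.integer(n_edited),
    n_chimeric = as.integer(n_chimeric),
    indel_frequency = if (n_total > 0L) n_edited / n_total else NA_real_,
    integration_frequency_reads =
      if (n_total > 0L) n_chimeric / n_total else NA_real_,
    integration_frequency_indels =
      if (n_edited > 0L) n_chimeric / n_edited else NA_real_,
    size_histogram = size_histogram(variants),
    quant_window = as.integer(window)),
    class = "SummaryReport")
}

# support-weighted indel size histogram; complex variants are
# decomposed into their individual ops
size_histogram <- function(variants) {
  out <- list()
  add <- function(type, size, count)
    out[[length(out) + 1L]] <<- data.frame(type = type, size = size,
                                           count = count,
                                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$type %in% c("deletion", "insertion"))
      add(v$type, v$size, v$support)
    else if (v$type == "vector_insertion")
      add("vector", v$size, v$support)
    else if (v$type == "complex") {
      for (tok in strsplit(v$signature, ";", fixed = TRUE)[[1]]) {
        f <- strsplit(tok, ":", fixed = TRUE)[[1]]
        add(if (f[1] == "D") "deletion" else "insertion",
            as.integer(f[3]), v$support)
      }
    }
  }
  if (!length(out))
    return(data.frame(type = character(0), size = integer(0),
                      count = integer(0)))
  h <- do.call(rbind, out)
  agg <- stats::aggregate(count ~ type + size, data = h, FUN = sum)
  agg[order(agg$type, agg$size), , drop = FALSE]
}

#' @export
print.SummaryReport <- function(x, ...) {
  cat(sprintf(paste0(
    "SummaryReport: %d locus reads, %d edited (%.1f%%)\n",
    "  vector integration: %.2f%% of reads, %.2f%% of edited reads\n"),
    x$n_total, x$n_edited, 100 * x$indel_frequency,
    100 * x$integration_frequency_reads,
    100 * x$integration_frequency_indels))
  invisible(x)
}

#' Per-position deletion coverage profile
#'
#' For each amplicon position, the fraction of covering reads whose
#' alignment carries a deletion at that position. Positions with zero
#' coverage are emitted as `NA`. Both amplicon-only and chimeric reads
#' contribute through their amplicon alignments.
#'
#' @param read_calls a `ReadCalls` object.
#' @param amplicon an [amplicon_ref()].
#' @return data.frame `pos` (0-based), `coverage`, `deleted`,
#'   `fraction`.
#' @export
deletion_coverage_profile <- function(read_calls, amplicon) {
  len <- nchar(amplicon$sequence)
  cov <- integer(len); del <- integer(len)
  for (aln in read_calls$alignments) {
    if (aln$ref_end > aln$ref_start)
      cov[(aln$ref_start + 1L):aln$ref_end] <-
        cov[(aln$ref_start + 1L):aln$ref_end] + 1L
    dops <- aln$ops[aln$ops$op == "deletion", , drop = FALSE]
    for (r in seq_len(nrow(dops)))
      del[(dops$ref_start[r] + 1L):(dops$ref_start[r] + dops$length[r])] <-
        del[(dops$ref_start[r] + 1L):(dops$ref_start[r] + dops$length[r])] + 1L
  }
  data.frame(pos = seq_len(len) - 1L, coverage = cov, deleted = del,
             fraction = ifelse(cov > 0L, del / cov, NA_real_))
}
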