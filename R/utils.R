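#' Reverse-complement a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar, the reverse complement.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' IUPAC degenerate base classes
#'
#' Expansion of one IUPAC code into the set of unambiguous bases it
#' stands for.
#' @param code single IUPAC character.
#' @return character vector of bases in the class.
#' @keywords internal
iupac_class <- function(code) {
  classes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"))
  cls <- classes[[toupper(code)]]
  if (is.null(cls)) stop("unknown IUPAC code: ", code)
  cls
}

# validated uppercase DNA, optionally allowing N
check_dna <- function(x, what, allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L)
    stop(what, ": sequence must be a nonempty character scalar")
  x <- toupper(x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  if (nchar(bad) > 0L)
    stop(what, ": sequence contains characters outside {",
         paste(strsplit(alphabet, "")[[1]], collapse = ","), "}")
  x
}

# all k-mers of a sequence (character vector, possibly empty)
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
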