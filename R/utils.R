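#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cohort allele frequencies and
#' identity percentages in this package follow the half-up convention
#' instead (1/144 prints as 0.69, 61/144 as 42.36).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# IUPAC two-base ambiguity codes used by diploid Sanger consensus sequences.
IUPAC_PAIRS <- c(
  "AC" = "M", "AG" = "R", "AT" = "W",
  "CG" = "S", "CT" = "Y", "GT" = "K"
)
IUPAC_DECODE <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT"
)

#' Encode a diploid base pair as a single consensus symbol
#'
#' @param a,b character vectors of bases over A/C/G/T.
#' @return character vector: the base itself where `a == b`, otherwise the
#'   IUPAC two-base ambiguity code.
#' @export
iupac_encode <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("non-ACGT haplotype base at position(s) ", paste(which(!ok), collapse = ", "))
  }
  out <- a
  het <- a != b
  if (any(het)) {
    key <- ifelse(a[het] < b[het], paste0(a[het], b[het]), paste0(b[het], a[het]))
    out[het] <- unname(IUPAC_PAIRS[key])
  }
  out
}

#' Decode an IUPAC symbol into its constituent bases
#'
#' @param code single-character IUPAC symbol (plain base or two-base code).
#' @return character vector of 1 or 2 bases.
#' @export
iupac_decode <- function(code) {
  bases <- IUPAC_DECODE[code]
  if (any(is.na(bases))) {
    stop("invalid IUPAC symbol: ", paste(code[is.na(bases)], collapse = ", "))
  }
  strsplit(unname(bases), "")
}

#' Translate a coding sequence codon-by-codon
#'
#' @param cds nucleotide string with length a multiple of 3.
#' @return character vector of one-letter amino acids (`*` for stop).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length ", n, " is not a multiple of 3")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (any(is.na(aa))) stop("untranslatable codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  unname(aa)
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# collapse a character vector of bases back to a string
chars_seq <- function(x) paste(x, collapse = "")

# stop codons in the standard genetic code
STOP_CODONS <- c("TAA", "TAG", "TGA")
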