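#' Gene models in gene-local coordinates
#'
#' A `gene_model` bundles a gene-local genomic sequence with its ordered
#' exon spans. All coordinates are 1-based and inclusive, with g.1 the A of
#' the ATG start codon ("from ATG" convention); spliced-CDS coordinates
#' (c.) likewise start at 1. Loci are modeled on the coding strand.
#'
#' @param name gene identifier, e.g. `"CYP2D50-1"`.
#' @param sequence nucleotide string over A/C/G/T.
#' @param exons data frame with columns `index`, `start`, `end` (gene-local,
#'   1-based inclusive), ordered, non-overlapping, strictly increasing.
#' @param validate_cds check that the spliced CDS starts with ATG and has
#'   length divisible by 3 (disable for partial/fused constructs).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, sequence, exons, validate_cds = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  sequence <- toupper(sequence)
  exons <- as.data.frame(exons)
  stopifnot(all(c("index", "start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nchar(sequence)
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (any(exons$start < 1L) || any(exons$end > n)) {
    bad <- which(exons$start < 1L | exons$end > n)[1]
    stop("exon ", exons$index[bad], " outside sequence [1, ", n, "]")
  }
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("overlapping or unordered exons")
  }
  gm <- structure(
    list(name = name, sequence = sequence, exons = exons, atg_position = 1L),
    class = "gene_model"
  )
  if (validate_cds) {
    cds <- splice_cds(gm)$cds
    if (substr(cds, 1, 3) != "ATG") stop("spliced CDS does not start with ATG")
    if (nchar(cds) %% 3 != 0) stop("spliced CDS length not a multiple of 3")
  }
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(
    "<gene_model> ", x$name, ": ", nchar(x$sequence), " bp, ",
    nrow(x$exons), " exons, CDS ", sum(x$exons$end - x$exons$start + 1L),
    " nt\n",
    sep = ""
  )
  invisible(x)
}

#' Build exon spans from exon and intron lengths
#'
#' Convenience constructor: exon 1 starts at g.1; each intron's length sets
#' the offset to the next exon.
#'
#' @param exon_lengths integer vector of exon lengths.
#' @param intron_lengths integer vector of length `length(exon_lengths) - 1`.
#' @return exon data frame suitable for [gene_model()].
#' @export
exon_table <- function(exon_lengths, intron_lengths) {
  k <- length(exon_lengths)
  stopifnot(length(intron_lengths) == k - 1L)
  start <- integer(k)
  end <- integer(k)
  pos <- 1L
  for (i in seq_len(k)) {
    start[i] <- pos
    end[i] <- pos + exon_lengths[i] - 1L
    pos <- end[i] + 1L + if (i < k) intron_lengths[i] else 0L
  }
  data.frame(index = seq_len(k), start = start, end = end)
}

#' Splice a gene model into its coding sequence
#'
#' Concatenates the exon subsequences in order and returns the spliced CDS
#' together with the splice map relating every exonic g. position to its
#' c. position.
#'
#' @param gene a [gene_model()].
#' @return list with `cds` (nucleotide string) and `map` (data frame with
#'   columns `g_pos`, `c_pos`, `exon`), covering every CDS base.
#' @export
splice_cds <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nchar(gene$sequence)
  ex <- gene$exons
  if (any(ex$end > n)) {
    bad <- which(ex$end > n)[1]
    stop("exon ", ex$index[bad], " extends beyond sequence end")
  }
  g_pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
  map <- data.frame(
    g_pos = g_pos,
    c_pos = seq_along(g_pos),
    exon = rep(ex$index, ex$end - ex$start + 1L)
  )
  cds <- paste(substring(gene$sequence, ex$start, ex$end), collapse = "")
  list(cds = cds, map = map)
}

#' Map a gene-local genomic position to its spliced-CDS position
#'
#' @param map splice map from [splice_cds()] (or a `gene_model`, in which
#'   case the map is built on the fly).
#' @param g gene-local position (1-based from the A of ATG).
#' @return the integer c. position for an exonic `g`; for intronic
#'   positions, the character token `"intronic"` carrying a
#'   `flanking_exons` attribute with the indices of the surrounding exons.
#' @export
g_to_c <- function(map, g) {
  if (inherits(map, "gene_model")) {
    gene_len <- nchar(map$sequence)
    map <- splice_cds(map)$map
  } else {
    gene_len <- max(map$g_pos)
  }
  stopifnot(length(g) == 1L)
  if (g < 1L || (g > gene_len && g > max(map$g_pos))) {
    stop("position g.", g, " out of range [1, ", gene_len, "]")
  }
  i <- match(g, map$g_pos)
  if (!is.na(i)) {
    return(map$c_pos[i])
  }
  prev_exon <- if (any(map$g_pos < g)) max(map$exon[map$g_pos < g]) else 0L
  structure("intronic", flanking_exons = c(prev_exon, prev_exon + 1L))
}

#' Map a spliced-CDS position back to its gene-local genomic position
#'
#' @param map splice map from [splice_cds()] or a `gene_model`.
#' @param c_pos c. position in 1..CDS length.
#' @return the integer g. position.
#' @export
c_to_g <- function(map, c_pos) {
  if (inherits(map, "gene_model")) map <- splice_cds(map)$map
  i <- match(c_pos, map$c_pos)
  if (is.na(i)) stop("c.", c_pos, " outside CDS [1, ", max(map$c_pos), "]")
  map$g_pos[i]
}

#' Label a diploid genotype relative to a reference base
#'
#' Uses the HET/HOM/MUT notation of Sanger-based cohort reports:
#' HET when the two alleles differ, HOM when both equal the reference,
#' MUT when both carry the same non-reference allele.
#'
#' @param alleles character vector of length 2 (unordered allele pair).
#' @param ref reference base (or indel token) at the position.
#' @return `"HET"`, `"HOM"` or `"MUT"`.
#' @export
genotype_label <- function(alleles, ref) {
  stopifnot(length(alleles) == 2L)
  if (alleles[1] != alleles[2]) "HET" else if (alleles[1] == ref) "HOM" else "MUT"
}

#' Write a gene model as FASTA plus GFF3
#'
#' The sequence goes to `<stem>.fasta`; exon features go to `<stem>.gff3`
#' with `seqid` equal to the gene name and 1-based inclusive coordinates.
#'
#' @param gene a [gene_model()].
#' @param stem output path stem (without extension).
#' @return invisibly, the two file paths.
#' @export
write_gene_model <- function(gene, stem) {
  stopifnot(inherits(gene, "gene_model"))
  fa <- paste0(stem, ".fasta")
  gff <- paste0(stem, ".gff3")
  seq <- Biostrings::DNAStringSet(gene$sequence)
  names(seq) <- gene$name
  Biostrings::writeXStringSet(seq, fa)
  gr <- GenomicRanges::GRanges(
    seqnames = gene$name,
    ranges = IRanges::IRanges(start = gene$exons$start, end = gene$exons$end),
    strand = "+",
    type = "exon",
    ID = paste0(gene$name, ":exon", gene$exons$index)
  )
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}

#' Read a gene model from FASTA plus GFF3
#'
#' @param fasta path to a single-record FASTA with the gene-local sequence.
#' @param gff3 path to a GFF3 file with the exon features.
#' @param validate_cds passed to [gene_model()].
#' @return a [gene_model()].
#' @export
read_gene_model <- function(fasta, gff3, validate_cds = TRUE) {
  seq <- Biostrings::readDNAStringSet(fasta)
  stopifnot(length(seq) == 1L)
  name <- sub("\\s.*$", "", names(seq)[1])
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "exon"]
  ord <- order(GenomicRanges::start(gr))
  exons <- data.frame(
    index = seq_along(ord),
    start = GenomicRanges::start(gr)[ord],
    end = GenomicRanges::end(gr)[ord]
  )
  gene_model(name, as.character(seq[[1]]), exons, validate_cds = validate_cds)
}

#' Export a splice map as two-column TSV
#'
#' @param map splice map from [splice_cds()] or a `gene_model`.
#' @param path output file.
#' @export
write_splice_map <- function(map, path) {
  if (inherits(map, "gene_model")) map <- splice_cds(map)$map
  utils::write.table(map[, c("g_pos", "c_pos")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
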