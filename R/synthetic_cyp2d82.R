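#' @name synthetic_cyp2d82
#' @title Stand-alone synthetic model of the CYP2D82-like gene
#'
#' @description
#' A second sequenced gene of the family, modeled outside the focal tandem
#' pair, hosts the multi-nucleotide and frameshift worked examples: a fully
#' substituted lysine codon (AAG>GGA) and an 11-bp exonic deletion causing
#' a frameshift at codon 378. Its synthetic intron lengths place the
#' canonical gene-local positions in their published codons (g.83 in codon
#' 28 of exon 1, g.2673-2675 as codon 248 in exon 5, g.3474-3484 inside
#' exon 7, g.4104 in exon 8).
NULL

# same exon lengths as the focal scaffold; intron lengths chosen to honor
# the g./c. correspondences of the canonical CYP2D82 variants
CYP2D82_INTRON_LENGTHS <- c(700L, 812L, 91L, 328L, 169L, 240L, 515L, 105L)

CYP2D82_FIXED_CODONS <- c(
  "1" = "ATG", "28" = "CGG", "29" = "CGC", "126" = "CGG", "127" = "TAC",
  "158" = "GAG", "204" = "CTG", "233" = "CTT", "235" = "CAC", "239" = "GTG",
  "240" = "GCG", "248" = "AAG", "254" = "CTG", "258" = "CTG", "268" = "ACC",
  "279" = "CTG", "355" = "TGC", "377" = "TTG", "378" = "ACC", "379" = "CAC",
  "380" = "ATG", "381" = "ACA", "382" = "TTC", "385" = "ATC", "417" = "CGC",
  "429" = "CGT", "501" = "TAA"
)

#' Build the synthetic CYP2D82-shaped gene model
#'
#' @param seed integer seed for the random background sequence.
#' @return a [gene_model()] named `CYP2D82`.
#' @export
simulate_cyp2d82_model <- function(seed = 1L) {
  set.seed(seed)
  exons <- exon_table(FOCAL_EXON_LENGTHS, CYP2D82_INTRON_LENGTHS)
  gene_len <- exons$end[nrow(exons)]
  g_pos <- unlist(mapply(seq.int, exons$start, exons$end, SIMPLIFY = FALSE))
  bases <- c("A", "C", "G", "T")
  non_stop <- setdiff(
    apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
    STOP_CODONS
  )
  codons <- sample(non_stop, length(g_pos) %/% 3L, replace = TRUE)
  idx <- as.integer(names(CYP2D82_FIXED_CODONS))
  codons[idx] <- unname(CYP2D82_FIXED_CODONS)
  cds <- seq_chars(paste(codons, collapse = ""))
  seq <- character(gene_len)
  seq[g_pos] <- cds
  intronic <- setdiff(seq_len(gene_len), g_pos)
  seq[intronic] <- sample(bases, length(intronic), replace = TRUE)
  for (i in seq_len(nrow(exons) - 1L)) {
    seq[exons$end[i] + 1:2] <- c("G", "T")
    seq[exons$start[i + 1L] - (2:1)] <- c("A", "G")
  }
  gene_model("CYP2D82", chars_seq(seq), exons)
}

#' Default cohort variant panel for the CYP2D82-shaped gene
#'
#' Mirrors the canonical amino-acid-changing variants of the second
#' sequenced gene, with allele counts out of 144 reproducing the published
#' cohort frequencies; includes one codon-sized MNV (AAG>GGA at codon 248)
#' and one 11-bp deletion (CCACATGACAT at g.3474-3484).
#'
#' @param model the [simulate_cyp2d82_model()] gene.
#' @return data frame with columns `gene`, `g_pos`, `ref`, `alt`,
#'   `allele_count` (deletions use `alt = "del"`).
#' @export
default_cyp2d82_variants <- function(model) {
  v <- data.frame(
    g_pos = c(
      83L, 85L, 1888L, 1892L, 1984L, 2214L, 2628L, 2635L, 2646L, 2650L,
      2673L, 2674L, 2691L, 2703L, 2733L, 2767L, 3403L, 3469L, 3472L,
      3493L, 4104L, 4141L
    ),
    alt = c(
      "A", "T", "G", "C", "C", "G", "T", "G", "C", "T",
      "G", "G", "G", "G", "G", "A", "C", "G", "G",
      "G", "T", "A"
    ),
    allele_count = c(
      26L, 1L, 18L, 2L, 8L, 8L, 2L, 2L, 1L, 1L,
      8L, 79L, 98L, 49L, 2L, 2L, 98L, 14L, 14L,
      99L, 32L, 8L
    ),
    stringsAsFactors = FALSE
  )
  v$ref <- substring(model$sequence, v$g_pos, v$g_pos)
  mnv <- data.frame(
    g_pos = 2673L, alt = "GGA", allele_count = 1L,
    ref = substring(model$sequence, 2673L, 2675L), stringsAsFactors = FALSE
  )
  del <- data.frame(
    g_pos = 3474L, alt = "del", allele_count = 1L,
    ref = substring(model$sequence, 3474L, 3484L), stringsAsFactors = FALSE
  )
  out <- rbind(v, mnv, del)
  out$gene <- model$name
  out[, c("gene", "g_pos", "ref", "alt", "allele_count")]
}
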