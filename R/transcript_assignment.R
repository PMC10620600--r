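#' Genotype pattern of a consensus CDS against a reference CDS
#'
#' One call per position where the (possibly IUPAC-ambiguous) consensus
#' differs from the reference: HET where the two decoded alleles differ,
#' MUT where both carry the same non-reference base.
#'
#' @param consensus_cds IUPAC consensus string (spliced CDS).
#' @param reference_cds plain reference CDS of equal length.
#' @return data frame with columns `c_pos`, `ref`, `allele1`, `allele2`,
#'   `label`; positions strictly increasing.
#' @export
genotype_pattern <- function(consensus_cds, reference_cds) {
  if (nchar(consensus_cds) != nchar(reference_cds)) {
    stop(
      "length mismatch: consensus ", nchar(consensus_cds),
      " vs reference ", nchar(reference_cds)
    )
  }
  cons <- seq_chars(toupper(consensus_cds))
  ref <- seq_chars(toupper(reference_cds))
  diff <- which(cons != ref)
  if (!length(diff)) {
    return(empty_pattern())
  }
  rows <- lapply(diff, function(p) {
    alleles <- iupac_decode(cons[p])[[1]]
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    data.frame(
      c_pos = p, ref = ref[p], allele1 = alleles[1], allele2 = alleles[2],
      label = genotype_label(alleles, ref[p]), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

empty_pattern <- function() {
  data.frame(
    c_pos = integer(0), ref = character(0), allele1 = character(0),
    allele2 = character(0), label = character(0), stringsAsFactors = FALSE
  )
}

allele_set <- function(a1, a2) paste(sort(c(a1, a2)), collapse = "/")

#' Assign a transcript to its source paralog by pattern replication
#'
#' A candidate gene is consistent with a transcript iff, at every position
#' of the transcript's polymorphism pattern, the candidate's CDS genotype
#' is identical as an unordered allele pair — genotype-level equality, not
#' mere allele containment, since exclusion of a fused annotation rests on
#' HET-versus-HOM mismatches. Candidates without a call at an assayed
#' position default to homozygous for their own reference base (patterns
#' list only polymorphic positions). The verdict is `assigned` when exactly
#' one candidate is consistent, `ambiguous` for more, `unassigned` for
#' none.
#'
#' @param transcript_pattern a [genotype_pattern()] data frame for the
#'   transcript.
#' @param candidates named list; each element is either a pattern data
#'   frame or a list with elements `pattern` and (optionally) `cds`, the
#'   candidate's reference CDS used to fill default homozygous-reference
#'   genotypes. Without a `cds`, the transcript pattern's own `ref` column
#'   supplies the default base.
#' @return object of class `assignment_result`: list with `verdict`
#'   (`assigned`/`ambiguous`/`unassigned`), `gene` (assigned gene or
#'   consistent set), and `mismatches` (per-candidate data frames of
#'   disagreeing positions).
#' @export
assign_transcript <- function(transcript_pattern, candidates) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  tp <- transcript_pattern
  mism <- list()
  consistent <- character(0)
  for (g in names(candidates)) {
    cand <- candidates[[g]]
    if (is.data.frame(cand)) cand <- list(pattern = cand)
    cp <- cand$pattern
    bad <- list()
    for (i in seq_len(nrow(tp))) {
      pos <- tp$c_pos[i]
      want <- allele_set(tp$allele1[i], tp$allele2[i])
      j <- match(pos, cp$c_pos)
      if (!is.na(j)) {
        got <- allele_set(cp$allele1[j], cp$allele2[j])
      } else if (!is.null(cand$cds)) {
        b <- substring(cand$cds, pos, pos)
        got <- allele_set(b, b)
      } else {
        got <- allele_set(tp$ref[i], tp$ref[i])
      }
      if (got != want) {
        bad[[length(bad) + 1L]] <- data.frame(
          c_pos = pos, transcript = want, candidate = got, stringsAsFactors = FALSE
        )
      }
    }
    mism[[g]] <- if (length(bad)) do.call(rbind, bad) else data.frame(
      c_pos = integer(0), transcript = character(0), candidate = character(0)
    )
    if (nrow(mism[[g]]) == 0L) consistent <- c(consistent, g)
  }
  verdict <- if (length(consistent) == 1L) "assigned" else if (length(consistent) > 1L) "ambiguous" else "unassigned"
  structure(
    list(verdict = verdict, gene = consistent, mismatches = mism),
    class = "assignment_result"
  )
}

#' Assign a transcript consensus sequence to candidate genes
#'
#' Sequence-level front end: the transcript is aligned to each candidate's
#' reference CDS (coordinate collisions between paralogs of unequal CDS
#' length are resolved through the alignment, never by raw position
#' equality), its pattern is derived in that candidate's own c-coordinate
#' system, and [assign_transcript()] compares it with the candidate's gene
#' CDS genotype.
#'
#' @param transcript_seq IUPAC consensus of the sequenced transcript.
#' @param candidates named list; each element a list with `cds` (reference
#'   CDS string) and `genotype` (the gene's own [genotype_pattern()] in its
#'   c coordinates).
#' @return an `assignment_result`.
#' @export
assign_transcript_seq <- function(transcript_seq, candidates) {
  results <- list()
  for (g in names(candidates)) {
    cand <- candidates[[g]]
    if (nchar(transcript_seq) == nchar(cand$cds)) {
      tp <- genotype_pattern(transcript_seq, cand$cds)
    } else {
      cmap <- build_coordinate_map(cand$cds, transcript_seq)
      sub <- cmap[!is.na(cmap$pos_a) & !is.na(cmap$pos_b), ]
      tp_rows <- list()
      for (i in which(sub$base_a != sub$base_b)) {
        alleles <- iupac_decode(sub$base_b[i])[[1]]
        if (length(alleles) == 1L) alleles <- c(alleles, alleles)
        if (identical(sort(alleles), sort(c(sub$base_a[i], sub$base_a[i])))) next
        tp_rows[[length(tp_rows) + 1L]] <- data.frame(
          c_pos = sub$pos_a[i], ref = sub$base_a[i],
          allele1 = alleles[1], allele2 = alleles[2],
          label = genotype_label(alleles, sub$base_a[i]), stringsAsFactors = FALSE
        )
      }
      tp <- if (length(tp_rows)) do.call(rbind, tp_rows) else empty_pattern()
    }
    res <- assign_transcript(tp, stats::setNames(
      list(list(pattern = cand$genotype, cds = cand$cds)), g
    ))
    results[[g]] <- res$mismatches[[g]]
  }
  consistent <- names(results)[vapply(results, nrow, integer(1)) == 0L]
  verdict <- if (length(consistent) == 1L) "assigned" else if (length(consistent) > 1L) "ambiguous" else "unassigned"
  structure(
    list(verdict = verdict, gene = consistent, mismatches = results),
    class = "assignment_result"
  )
}

#' Read the bundled printed transcript-genotype table
#'
#' Per-horse transcript polymorphism patterns with the corresponding CDS
#' genotypes of the three candidate structures (the two proposed paralogs
#' and the fused annotation), shipped as a plain-text fixture.
#'
#' @return data frame with columns `horse`, `c_pos`, `ref`, `transcript`,
#'   `cyp2d50_1`, `cyp2d50_2`, `ncbi`.
#' @export
read_transcript_genotypes <- function() {
  path <- system.file("extdata", "transcript_genotypes.tsv", package = "paralocus")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# parse "HET (C/A)" or "C/A" into an allele pair
parse_genotype_entry <- function(x) {
  m <- regmatches(x, regexpr("[ACGT-]+/[ACGT-]+", x))
  if (!length(m)) stop("cannot parse genotype entry: ", x)
  strsplit(m, "/", fixed = TRUE)[[1]]
}

# build a genotype_pattern data frame from fixture rows and one column
pattern_from_entries <- function(rows, column) {
  if (!nrow(rows)) {
    return(empty_pattern())
  }
  al <- t(vapply(rows[[column]], parse_genotype_entry, character(2)))
  data.frame(
    c_pos = rows$c_pos, ref = rows$ref,
    allele1 = al[, 1], allele2 = al[, 2],
    label = vapply(
      seq_len(nrow(rows)),
      function(i) genotype_label(al[i, ], rows$ref[i]), character(1)
    ),
    stringsAsFactors = FALSE
  )
}

#' Assign the printed per-horse transcript patterns
#'
#' Runs [assign_transcript()] for every horse in the bundled genotype
#' table against the three candidate CDS genotype columns.
#'
#' @param genotypes data frame as from [read_transcript_genotypes()].
#' @return named list of `assignment_result`s, one per horse.
#' @export
assign_printed_transcripts <- function(genotypes = read_transcript_genotypes()) {
  out <- list()
  for (h in unique(genotypes$horse)) {
    rows <- genotypes[genotypes$horse == h, , drop = FALSE]
    tp <- pattern_from_entries(rows, "transcript")
    candidates <- list(
      "CYP2D50-1" = pattern_from_entries(rows, "cyp2d50_1"),
      "CYP2D50-2" = pattern_from_entries(rows, "cyp2d50_2"),
      "CYP2D50-NCBI" = pattern_from_entries(rows, "ncbi")
    )
    out[[as.character(h)]] <- assign_transcript(tp, candidates)
  }
  out
}

#' Infer expressed and non-expressed loci from transcript assignments
#'
#' A locus is `detected` when at least one transcript is assigned to it;
#' `not_detected` when some assay could have co-amplified it (it appears in
#' a used assay's co-amplifiable set) yet no transcript was assigned to it
#' — the indirect non-expression argument; `untested` otherwise.
#'
#' @param assignments data frame with columns `transcript`, `verdict`,
#'   `gene`, `assay`.
#' @param assays named list: assay name -> character vector of loci the
#'   assay can co-amplify.
#' @return data frame with columns `locus`, `status`.
#' @export
detect_expressed_loci <- function(assignments, assays) {
  stopifnot(is.list(assays), !is.null(names(assays)))
  covered <- unique(unlist(assays))
  assigned <- assignments[assignments$verdict == "assigned", , drop = FALSE]
  for (i in seq_len(nrow(assigned))) {
    a <- assigned$assay[i]
    if (!a %in% names(assays)) stop("assignment references unknown assay: ", a)
    if (!assigned$gene[i] %in% assays[[a]]) {
      stop(
        "consistency error: transcript ", assigned$transcript[i],
        " assigned to ", assigned$gene[i], " which assay ", a, " cannot amplify"
      )
    }
  }
  used_assays <- unique(assignments$assay)
  amplifiable <- unique(unlist(assays[intersect(used_assays, names(assays))]))
  status <- vapply(covered, function(l) {
    if (l %in% assigned$gene) {
      "detected"
    } else if (l %in% amplifiable) "not_detected" else "untested"
  }, character(1))
  data.frame(locus = covered, status = unname(status), stringsAsFactors = FALSE)
}
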