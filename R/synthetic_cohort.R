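#' Default cohort variant panel for the acceptor paralog
#'
#' The panel mirrors the canonical acceptor-gene polymorphisms: ten
#' missense substitutions in exons 1, 5, 7 and 9 plus one intron-2 variant
#' fixed in the cohort, with allele counts out of 144 chosen to reproduce
#' the published cohort frequencies (e.g. 5/144 = 3.47%, 61 total alleles
#' at the exon-9 diagnostic position = 42.36%). The count at g.4240 covers
#' only non-hybrid haplotypes; hybrid alleles contribute the remaining
#' copies of that allele.
#'
#' @param model the acceptor [gene_model()] (used to fill reference bases).
#' @return data frame with columns `gene`, `g_pos`, `ref`, `alt`,
#'   `allele_count`.
#' @export
default_cohort_variants <- function(model) {
  pos <- c(92L, 134L, 1096L, 2605L, 3328L, 4192L, 4226L, 4228L, 4235L, 4240L, 4255L)
  alt <- c("A", "A", "C", "A", "C", "A", "T", "G", "T", "G", "A")
  count <- c(5L, 1L, 144L, 2L, 1L, 2L, 11L, 11L, 1L, 19L, 11L)
  data.frame(
    gene = model$name,
    g_pos = pos,
    ref = substring(model$sequence, pos, pos),
    alt = alt,
    allele_count = count,
    stringsAsFactors = FALSE
  )
}

#' Cohort specification for the diploid genotyping simulator
#'
#' @param n_samples number of diploid individuals (default 72; the
#'   published frequencies all have denominator 144 alleles).
#' @param variants data frame (`gene`, `g_pos`, `ref`, `alt`,
#'   `allele_count`) of substitutions to plant; `NULL` for the default
#'   panel of the acceptor paralog.
#' @param hybrid_allele_count number of haplotypes carrying the gene
#'   conversion tract (42 of 144 alleles reproduces 29.17%).
#' @param sampling_mode `"exact_counts"` places each variant on exactly
#'   `allele_count` haplotypes; `"binomial"` draws carriers independently
#'   with probability `allele_count / (2 * n_samples)`.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 72L, variants = NULL,
                        hybrid_allele_count = 42L,
                        sampling_mode = c("exact_counts", "binomial"),
                        seed = 1L) {
  sampling_mode <- match.arg(sampling_mode)
  structure(
    list(
      n_samples = as.integer(n_samples),
      variants = variants,
      hybrid_allele_count = as.integer(hybrid_allele_count),
      sampling_mode = sampling_mode,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# observed donor base at each diagnostic site after applying the donor
# population's own fixed polymorphisms (the confounded site keeps the
# acceptor base)
hybrid_template_bases <- function(sites, donor_offset, donor_variants) {
  obs <- sites$donor
  if (!is.null(donor_variants) && nrow(donor_variants)) {
    fixed <- donor_variants[donor_variants$frequency_pct >= 100, , drop = FALSE]
    pos_b <- sites$pos_a + donor_offset
    hit <- match(pos_b, fixed$g_pos)
    obs[!is.na(hit)] <- fixed$alt[stats::na.omit(hit)]
  }
  obs
}

#' Simulate a diploid genotyping cohort with a truth table
#'
#' Generates per-sample haplotype pairs of the acceptor paralog (and of any
#' other gene named in the variant panel), plants substitutions at exact
#' allele counts (or binomially), converts the requested number of
#' haplotypes into tail-conversion hybrids — every diagnostic site from the
#' first converted site to the gene end takes the donor's observed base —
#' and emits IUPAC consensus sequences plus a truth table of every planted
#' event.
#'
#' Variants falling inside the conversion region are planted on non-hybrid
#' haplotypes, so planted counts and hybrid alleles add up without overlap.
#'
#' @param family a [simulate_family()] result (focal constraints on), or a
#'   single [gene_model()] for hybrid-free cohorts.
#' @param spec a [cohort_spec()].
#' @return object of class `cohort_sim`: list with `consensus` (named list
#'   gene -> character vector of per-sample IUPAC strings), `haplotypes`
#'   (gene -> list of per-sample character pairs), and `truth` (data frame
#'   of per-sample calls, hybrid table, the spec).
#' @export
simulate_cohort <- function(family, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  if (inherits(family, "gene_model")) {
    models <- stats::setNames(list(family), family$name)
    sites <- NULL
    donor_offset <- 0L
    donor_variants <- NULL
  } else {
    stopifnot(inherits(family, "paralog_family"))
    models <- family$models
    sites <- family$truth$diagnostic_sites
    donor_offset <- family$truth$donor_offset
    donor_variants <- family$truth$donor_variants
  }
  acceptor <- if (inherits(family, "paralog_family")) family$config$focal_pair[1] else names(models)[1]
  variants <- spec$variants
  if (is.null(variants)) variants <- default_cohort_variants(models[[acceptor]])
  genes <- unique(c(acceptor, variants$gene))
  if (!all(genes %in% names(models))) {
    stop("variant panel names unknown gene(s): ", paste(setdiff(genes, names(models)), collapse = ", "))
  }
  n <- spec$n_samples
  n_hap <- 2L * n
  if (any(variants$allele_count > n_hap) || spec$hybrid_allele_count > n_hap) {
    stop("allele count exceeds 2 * n_samples = ", n_hap)
  }
  variants$g_end <- variants$g_pos + nchar(variants$ref) - 1L
  bad_ref <- substring(
    vapply(variants$gene, function(g) models[[g]]$sequence, character(1)),
    variants$g_pos, variants$g_end
  ) != variants$ref
  if (any(bad_ref)) {
    stop("variant ref mismatch at g.", paste(variants$g_pos[bad_ref], collapse = ", g."))
  }

  # haplotype matrices: one character matrix (position x haplotype) per gene
  haps <- lapply(genes, function(g) {
    matrix(rep(seq_chars(models[[g]]$sequence), n_hap), ncol = n_hap)
  })
  names(haps) <- genes

  # hybrid haplotypes on the acceptor gene: heterozygous carriers first
  hybrid_haps <- integer(0)
  if (spec$hybrid_allele_count > 0L) {
    if (is.null(sites)) stop("hybrid alleles requested but no diagnostic sites available")
    k <- spec$hybrid_allele_count
    first_sample_haps <- seq.int(1L, n_hap, by = 2L) # haplotype 1 of each sample
    if (k <= n) {
      hybrid_haps <- sort(sample(first_sample_haps, k))
    } else {
      hybrid_haps <- sort(c(first_sample_haps, sample(first_sample_haps + 1L, k - n)))
    }
    conv <- hybrid_template_bases(sites, donor_offset, donor_variants)
    haps[[acceptor]][sites$pos_a, hybrid_haps] <- conv
  }

  # plant variants; conversion-region variants go on non-hybrid haplotypes,
  # and variants whose footprints fall within one codon's reach of each
  # other go on disjoint haplotypes so planted events never coalesce
  suffix_start <- if (!is.null(sites)) min(sites$pos_a) else Inf
  touched <- lapply(genes, function(g) {
    data.frame(hap = integer(0), start = integer(0), end = integer(0))
  })
  names(touched) <- genes
  indel_rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    eligible <- seq_len(n_hap)
    if (v$gene == acceptor && v$g_pos >= suffix_start) {
      eligible <- setdiff(eligible, hybrid_haps)
    }
    tt <- touched[[v$gene]]
    win <- c(v$g_pos - 2L, v$g_end + 2L)
    clash <- unique(tt$hap[tt$end >= win[1] & tt$start <= win[2]])
    # exclude both haplotypes of a clashing sample: co-located variants on
    # opposite chromosomes are unphaseable in a diploid consensus
    clash_mate <- clash + ifelse(clash %% 2L == 1L, 1L, -1L)
    eligible <- setdiff(eligible, c(clash, clash_mate))
    carriers <- if (spec$sampling_mode == "exact_counts") {
      if (v$allele_count > length(eligible)) {
        stop("allele count ", v$allele_count, " at g.", v$g_pos, " exceeds eligible haplotypes")
      }
      if (v$allele_count == 0L) integer(0) else sample(eligible, v$allele_count)
    } else {
      eligible[stats::runif(length(eligible)) < v$allele_count / n_hap]
    }
    if (length(carriers)) {
      if (v$alt == "del") {
        zy <- vapply(unique((carriers + 1L) %/% 2L), function(s) {
          if (sum(carriers %in% c(2L * s - 1L, 2L * s)) == 2L) "MUT" else "HET"
        }, character(1))
        indel_rows[[length(indel_rows) + 1L]] <- data.frame(
          sample = sprintf("S%03d", unique((carriers + 1L) %/% 2L)),
          gene = v$gene, g_start = v$g_pos, g_end = v$g_end,
          deleted = v$ref, zygosity = zy, stringsAsFactors = FALSE
        )
      } else {
        alt_chars <- seq_chars(v$alt)
        haps[[v$gene]][v$g_pos:v$g_end, carriers] <- alt_chars
      }
      touched[[v$gene]] <- rbind(tt, data.frame(
        hap = carriers, start = v$g_pos, end = v$g_end
      ))
    }
  }

  # consensus and truth
  sample_ids <- sprintf("S%03d", seq_len(n))
  consensus <- list()
  hap_list <- list()
  truth_rows <- list()
  for (g in genes) {
    ref_chars <- seq_chars(models[[g]]$sequence)
    m <- haps[[g]]
    cons <- character(n)
    pairs <- vector("list", n)
    for (s in seq_len(n)) {
      h1 <- m[, 2L * s - 1L]
      h2 <- m[, 2L * s]
      cons[s] <- chars_seq(iupac_encode(h1, h2))
      pairs[[s]] <- list(chars_seq(h1), chars_seq(h2))
      diff <- which(h1 != ref_chars | h2 != ref_chars)
      if (length(diff)) {
        a1 <- h1[diff]
        a2 <- h2[diff]
        lab <- ifelse(a1 != a2, "HET", ifelse(a1 == ref_chars[diff], "HOM", "MUT"))
        alt <- ifelse(a1 != ref_chars[diff], a1, a2)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sample = sample_ids[s], gene = g, g_pos = diff,
          ref = ref_chars[diff], alt = alt,
          allele1 = a1, allele2 = a2, zygosity = lab,
          stringsAsFactors = FALSE
        )
      }
    }
    names(cons) <- sample_ids
    names(pairs) <- sample_ids
    consensus[[g]] <- cons
    hap_list[[g]] <- pairs
  }
  truth_calls <- if (length(truth_rows)) do.call(rbind, truth_rows) else {
    data.frame(
      sample = character(0), gene = character(0), g_pos = integer(0),
      ref = character(0), alt = character(0), allele1 = character(0),
      allele2 = character(0), zygosity = character(0)
    )
  }
  hybrid_count <- integer(n)
  if (length(hybrid_haps)) {
    tab <- table((hybrid_haps + 1L) %/% 2L)
    hybrid_count[as.integer(names(tab))] <- as.integer(tab)
  }

  structure(
    list(
      consensus = consensus,
      haplotypes = hap_list,
      truth = list(
        calls = truth_calls,
        hybrids = data.frame(sample = sample_ids, n_hybrid_alleles = hybrid_count),
        indels = if (length(indel_rows)) do.call(rbind, indel_rows) else data.frame(
          sample = character(0), gene = character(0), g_start = integer(0),
          g_end = integer(0), deleted = character(0), zygosity = character(0)
        ),
        planted_variants = variants,
        spec = spec
      ),
      models = models[genes],
      acceptor = acceptor
    ),
    class = "cohort_sim"
  )
}

#' Collapse a diploid haplotype pair into a Sanger-style consensus
#'
#' Positions where the haplotypes agree emit that base; heterozygous
#' positions emit the IUPAC two-base ambiguity code, as mixed peaks do in a
#' diploid Sanger trace. Haplotypes must be equal length; indels are
#' represented as recorded events, never as consensus characters.
#'
#' @param hap1,hap2 equal-length nucleotide strings over A/C/G/T.
#' @return consensus string with IUPAC codes at heterozygous positions.
#' @export
simulate_sanger_consensus <- function(hap1, hap2) {
  if (nchar(hap1) != nchar(hap2)) {
    stop("haplotypes differ in length; indels must be supplied as recorded events")
  }
  chars_seq(iupac_encode(seq_chars(hap1), seq_chars(hap2)))
}

#' Simulate spliced transcripts from the expressed loci of a family
#'
#' @param family a [simulate_family()] result.
#' @param expressed character vector of expressed locus names.
#' @param copy_counts integer vector (recycled) of transcript copies per
#'   expressed locus.
#' @return named character vector of spliced CDS sequences, names
#'   `<locus>|t<k>`.
#' @export
simulate_transcripts <- function(family, expressed, copy_counts = 1L) {
  stopifnot(inherits(family, "paralog_family"))
  unknown <- setdiff(expressed, names(family$models))
  if (length(unknown)) stop("unknown locus name(s): ", paste(unknown, collapse = ", "))
  if (length(expressed) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  copy_counts <- rep_len(as.integer(copy_counts), length(expressed))
  out <- character(0)
  for (i in seq_along(expressed)) {
    cds <- splice_cds(family$models[[expressed[i]]])$cds
    k <- copy_counts[i]
    if (k > 0L) {
      v <- rep(cds, k)
      names(v) <- sprintf("%s|t%d", expressed[i], seq_len(k))
      out <- c(out, v)
    }
  }
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
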