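#' Pipeline configuration
#'
#' Central configuration for the end-to-end synthetic run. Unknown keys
#' are rejected; the configuration round-trips through JSON unchanged.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param n_samples cohort size (diploid individuals).
#' @param hybrid_allele_count planted hybrid haplotypes.
#' @param intergenic_length spacer length of the fused locus.
#' @param min_identity minimum percent identity for the self-similarity
#'   scan.
#' @param min_run minimum converted-site run for hybrid calling.
#' @param sift_cutoff,provean_cutoff effect-classification thresholds.
#' @param true_ratio planted expression fold difference.
#' @param stages character vector of stages to run (subset of the default
#'   order).
#' @param quiet suppress stage messages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_samples = 72L,
                            hybrid_allele_count = 42L,
                            intergenic_length = 13000L,
                            min_identity = 85,
                            min_run = 2L,
                            sift_cutoff = 0.05,
                            provean_cutoff = -2.5,
                            true_ratio = 7.5,
                            stages = PIPELINE_STAGES,
                            quiet = FALSE) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  structure(
    list(
      seed = as.integer(seed), n_samples = as.integer(n_samples),
      hybrid_allele_count = as.integer(hybrid_allele_count),
      intergenic_length = as.integer(intergenic_length),
      min_identity = min_identity, min_run = as.integer(min_run),
      sift_cutoff = sift_cutoff, provean_cutoff = provean_cutoff,
      true_ratio = true_ratio, stages = stages, quiet = isTRUE(quiet)
    ),
    class = "pipeline_config"
  )
}

PIPELINE_STAGES <- c(
  "simulate", "discover_structure", "diagnostics", "call_variants",
  "assign_transcripts", "detect_hybrids", "classify_effects",
  "quantify_expression", "report"
)

# the loci whose transcripts are detectable in liver in the emulated study
EXPRESSED_LOCI <- c(
  "CYP2D50-1", "CYP2D50-2", "CYP2D84", "CYP2D86", "CYP2D82",
  "CYP2D14-LOC100070905"
)

#' Run the full synthetic pipeline
#'
#' Executes the stages in order — simulate, discover structure,
#' diagnostics, call variants, assign transcripts, detect hybrids,
#' classify effects, quantify expression, report — each stage feeding the
#' next, and returns the collected results. With `out_dir` set, the report
#' stage writes the result tables as TSV plus a JSON manifest recording
#' seed and parameters.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for the report stage.
#' @return named list of stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message("[paralocus] ", ...)
  res <- list(config = config)
  on <- function(stage) stage %in% config$stages

  if (on("simulate")) {
    say("simulate: family, cohort, transcripts, qPCR plates")
    family <- simulate_family(family_config(seed = config$seed))
    cohort <- simulate_cohort(family, cohort_spec(
      n_samples = config$n_samples,
      hybrid_allele_count = config$hybrid_allele_count,
      seed = config$seed + 1L
    ))
    transcripts <- simulate_transcripts(family, EXPRESSED_LOCI, copy_counts = 1L)
    qpcr <- simulate_qpcr(qpcr_spec(
      true_ratio = config$true_ratio, seed = config$seed + 2L
    ))
    res$family <- family
    res$cohort <- cohort
    res$transcripts <- transcripts
    res$qpcr <- qpcr
  }

  acc_name <- res$family$config$focal_pair[1]
  don_name <- res$family$config$focal_pair[2]
  acc <- res$family$models[[acc_name]]
  don <- res$family$models[[don_name]]

  if (on("discover_structure")) {
    say("discover_structure: self-similarity scan of the fused locus")
    fused <- simulate_fused_locus(res$family,
      intergenic_length = config$intergenic_length, seed = config$seed + 3L
    )
    matches <- self_similarity_scan(fused$locus$sequence,
      min_identity = config$min_identity
    )
    res$fused <- fused
    res$proposal <- propose_duplicate_structure(fused$locus, matches)
    res$exon_identity <- exon_identity_table(acc, don)
    res$gene_identity <- gene_identity_matrix(res$family)
  }

  if (on("diagnostics")) {
    say("diagnostics: inter-paralog diagnostic sites")
    sites <- find_diagnostic_sites(acc, don)
    res$sites <- mask_confounded_sites(sites, res$family$truth$donor_variants)
  }

  if (on("call_variants")) {
    say("call_variants: ", config$n_samples, " consensus sequences")
    cons <- res$cohort$consensus[[acc_name]]
    calls <- do.call(rbind, lapply(names(cons), function(s) {
      call_variants(cons[[s]], acc, sample = s)
    }))
    tab <- cohort_variant_table(calls, config$n_samples)
    tab$region <- vapply(tab$g_pos, function(p) {
      r <- classify_region(p, acc)
      paste(r$type, r$index)
    }, character(1))
    tab$effect <- vapply(seq_len(nrow(tab)), function(i) {
      annotate_effect(tab[i, ], acc)
    }, character(1))
    known <- read_known_variants()
    res$variant_calls <- calls
    res$variant_table <- annotate_novelty(tab, known)
  }

  if (on("assign_transcripts")) {
    say("assign_transcripts: ", length(res$transcripts), " transcripts")
    candidates <- lapply(res$family$models, function(m) {
      list(cds = splice_cds(m)$cds, genotype = empty_pattern())
    })
    assays <- list(panfamily = names(res$family$models))
    rows <- lapply(names(res$transcripts), function(id) {
      a <- assign_transcript_seq(res$transcripts[[id]], candidates)
      data.frame(
        transcript = id, verdict = a$verdict,
        gene = if (length(a$gene) == 1L) a$gene else NA_character_,
        assay = "panfamily", stringsAsFactors = FALSE
      )
    })
    res$assignments <- do.call(rbind, rows)
    res$expression_status <- detect_expressed_loci(res$assignments, assays)
  }

  if (on("detect_hybrids")) {
    say("detect_hybrids: diploid conversion-tract scoring")
    cons <- res$cohort$consensus[[acc_name]]
    counts <- vapply(cons, function(x) {
      call_hybrids_diploid(x, res$sites, min_run = config$min_run)
    }, integer(1))
    res$hybrid_counts <- counts
    res$hybrid_frequency <- hybrid_frequency(counts, config$n_samples)
  }

  if (on("classify_effects")) {
    say("classify_effects: SIFT/PROVEAN thresholds")
    scores <- read_effect_scores()
    res$effect_verdicts <- classify_deleterious(
      scores,
      sift_cutoff = config$sift_cutoff, provean_cutoff = config$provean_cutoff
    )
  }

  if (on("quantify_expression")) {
    say("quantify_expression: relative standard curve method")
    res$expression <- quantify_relative_expression(res$qpcr)
  }

  if (on("report") && !is.null(out_dir)) {
    say("report: writing tables to ", out_dir)
    render_reports(res, out_dir)
  }
  class(res) <- "pipeline_result"
  res
}

#' Read the bundled effect-score table
#'
#' The published per-variant PROVEAN and SIFT scores for the two sequenced
#' genes, shipped as a plain-text fixture (scores are pipeline inputs).
#'
#' @return data frame with gene, location, snp, aa_change, frequency_pct,
#'   rs_id, provean, sift and the reported flag columns.
#' @export
read_effect_scores <- function() {
  path <- system.file("extdata", "effect_scores.tsv", package = "paralocus")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read the bundled known-variant (rs identifier) table
#'
#' @return data frame with gene, g_pos, ref, alt, rs_id.
#' @export
read_known_variants <- function() {
  path <- system.file("extdata", "known_variants.tsv", package = "paralocus")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Render pipeline results as report tables
#'
#' Writes TSV reports in the canonical layouts: per-exon identity,
#' transcript assignment, the variant table (columns: Location, SNP
#' identified, Aminoacidic change, Frequency alleles containing the SNP
#' (%), rs number, PROVEAN result, SIFT results), diagnostic/conversion
#' sites, expression summary, and a JSON manifest.
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
render_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.table(d, p,
      sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
    )
    written <<- c(written, p)
  }
  if (!is.null(res$exon_identity)) tsv(res$exon_identity, "exon_identity.tsv")
  if (!is.null(res$gene_identity)) {
    tsv(
      cbind(locus = rownames(res$gene_identity), as.data.frame(res$gene_identity)),
      "gene_identity.tsv"
    )
  }
  if (!is.null(res$assignments)) tsv(res$assignments, "assignments.tsv")
  if (!is.null(res$expression_status)) tsv(res$expression_status, "expressed_loci.tsv")
  if (!is.null(res$variant_table)) {
    tsv(render_variant_report(res$variant_table), "variants.tsv")
  }
  if (!is.null(res$sites)) tsv(render_conversion_sites(res$sites), "conversion_sites.tsv")
  if (!is.null(res$hybrid_counts)) {
    tsv(
      data.frame(
        sample = names(res$hybrid_counts),
        n_hybrid_alleles = unname(res$hybrid_counts)
      ),
      "hybrids.tsv"
    )
    tsv(
      data.frame(hybrid_allele_frequency_pct = res$hybrid_frequency),
      "hybrid_frequency.tsv"
    )
  }
  if (!is.null(res$effect_verdicts)) tsv(res$effect_verdicts, "effect_verdicts.tsv")
  if (!is.null(res$expression)) {
    tsv(
      data.frame(
        fold_change = res$expression$fold_change,
        welch_t = res$expression$welch$t,
        welch_df = res$expression$welch$df,
        welch_p = res$expression$welch$p
      ),
      "expression_summary.tsv"
    )
  }
  manifest <- list(
    package = "paralocus",
    version = as.character(utils::packageVersion("paralocus")),
    seed = res$config$seed,
    parameters = res$config[setdiff(names(res$config), c("stages", "quiet"))],
    stages_run = res$config$stages,
    stages_skipped = setdiff(PIPELINE_STAGES, res$config$stages),
    files = basename(written)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(written, mp))
}

#' Format a cohort variant table in the canonical report layout
#'
#' @param tab annotated [cohort_variant_table()] output (with `effect` and
#'   `rs_id`).
#' @return data frame with the canonical columns.
#' @export
render_variant_report <- function(tab) {
  loc <- ifelse(tab$g_end > tab$g_pos,
    sprintf("g.%d-%d", tab$g_pos, tab$g_end), sprintf("g.%d", tab$g_pos)
  )
  snp <- ifelse(tab$type == "del",
    paste0(tab$ref, " del"), paste(tab$ref, ">", tab$alt)
  )
  aa <- ifelse(tab$effect %in% c("intronic", "synonymous"), "", tab$effect)
  out <- data.frame(
    Location = loc,
    `SNP identified` = snp,
    `Aminoacidic change` = aa,
    `Frequency alleles containing the SNP (%)` = sprintf("%.2f", tab$frequency_pct),
    `rs number` = ifelse(tab$rs_id == "novel", "", tab$rs_id),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!is.null(tab$provean)) {
    out$`PROVEAN result` <- tab$provean
    out$`SIFT results` <- tab$sift
  } else {
    out$`PROVEAN result` <- rep("", nrow(out))
    out$`SIFT results` <- rep("", nrow(out))
  }
  out
}

#' Format the diagnostic-site table in the canonical layout
#'
#' @param sites [find_diagnostic_sites()] output (optionally masked).
#' @param region restrict to acceptor positions within this range
#'   (default: all sites).
#' @return data frame with acceptor location, base change, donor base and
#'   informativeness.
#' @export
render_conversion_sites <- function(sites, region = NULL) {
  if (!is.null(region)) {
    sites <- sites[sites$pos_a >= region[1] & sites$pos_a <= region[2], , drop = FALSE]
  }
  data.frame(
    `Location (on gDNA acceptor)` = sprintf("g.%d", sites$pos_a),
    `SNP identified` = paste(sites$base_a, ">", sites$base_b),
    `Nucleotide on corresponding donor location` = sites$base_b,
    informative = sites$informative,
    reason = ifelse(is.na(sites$reason), "", sites$reason),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
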