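#' Find paralog-diagnostic sites between two gene models
#'
#' Aligns the two gene-local sequences and reports every non-gap column
#' where the bases differ, ordered by acceptor position. Each site carries
#' the corresponding donor coordinate through the alignment.
#'
#' @param gene_a acceptor [gene_model()].
#' @param gene_b donor [gene_model()].
#' @param cmap optional precomputed [build_coordinate_map()] for the pair.
#' @return data frame with columns `pos_a`, `pos_b`, `base_a`, `base_b`,
#'   `informative` (all TRUE), `reason` (NA).
#' @export
find_diagnostic_sites <- function(gene_a, gene_b, cmap = NULL) {
  if (is.null(cmap)) cmap <- build_coordinate_map(gene_a$sequence, gene_b$sequence)
  sub <- cmap[cmap$kind == "substitution", , drop = FALSE]
  out <- data.frame(
    pos_a = sub$pos_a, pos_b = sub$pos_b,
    base_a = sub$base_a, base_b = sub$base_b,
    informative = rep(TRUE, nrow(sub)), reason = rep(NA_character_, nrow(sub)),
    stringsAsFactors = FALSE
  )
  out[order(out$pos_a), , drop = FALSE]
}

#' Mask diagnostic sites confounded by donor-paralog polymorphism
#'
#' A site whose donor position carries a known polymorphism in the donor
#' population is uninformative for conversion scoring: if the donor allele
#' observed in the cohort equals the acceptor base, conversion at that site
#' is invisible (the published case: a fixed donor T>C makes the
#' corresponding acceptor position never appear converted).
#'
#' @param sites [find_diagnostic_sites()] output.
#' @param donor_variants data frame with `g_pos` (donor coordinates),
#'   `ref`, `alt`; or NULL.
#' @return `sites` with `informative`/`reason` updated.
#' @export
mask_confounded_sites <- function(sites, donor_variants) {
  if (is.null(donor_variants) || nrow(donor_variants) == 0L) {
    return(sites)
  }
  hit <- match(sites$pos_b, donor_variants$g_pos)
  conf <- !is.na(hit)
  sites$informative[conf] <- FALSE
  sites$reason[conf] <- sprintf(
    "donor polymorphism %s>%s at donor g.%d",
    donor_variants$ref[hit[conf]], donor_variants$alt[hit[conf]],
    donor_variants$g_pos[hit[conf]]
  )
  sites
}

#' Classify one haplotype at the informative diagnostic sites
#'
#' @param allele_seq haplotype string in acceptor coordinates.
#' @param sites diagnostic-site table (masked sites are skipped).
#' @return character vector over `acceptor`/`donor`/`other`, one entry per
#'   informative site, ordered by `pos_a`. `N` or gap characters score
#'   `other` with a warning.
#' @export
classify_allele_at_sites <- function(allele_seq, sites) {
  inf <- sites[sites$informative, , drop = FALSE]
  if (nrow(inf) && max(inf$pos_a) > nchar(allele_seq)) {
    stop("allele sequence does not cover all informative sites")
  }
  b <- substring(allele_seq, inf$pos_a, inf$pos_a)
  state <- ifelse(b == inf$base_a, "acceptor", ifelse(b == inf$base_b, "donor", "other"))
  if (any(b %in% c("N", "-"))) {
    warning("N or gap at diagnostic site(s); scored as 'other'")
  }
  state
}

#' Detect a gene-conversion tract in a diagnostic-site state vector
#'
#' The maximal run of consecutive donor states of length at least
#' `min_run` defines the conversion tract. A tract is labeled a hybrid
#' allele only when it extends to the last informative site (tail
#' conversion); interior tracts are reported as conversion segments without
#' the hybrid label. The switching interval is the open interval between
#' the last acceptor-state site before the tract and the first converted
#' site; when the tract starts at the first site, the lower endpoint falls
#' back to `upstream_boundary` (or 0 for sequence start). Isolated donor
#' states below `min_run` are ordinary variants, not conversion.
#'
#' @param states output of [classify_allele_at_sites()].
#' @param sites the diagnostic-site table the states were scored against.
#' @param min_run minimum number of consecutive converted sites (default
#'   2: a single converted site is indistinguishable from a point
#'   mutation).
#' @param upstream_boundary optional acceptor position of the last
#'   informative site upstream of `sites` (used when the tract starts at
#'   the first site).
#' @return object of class `conversion_call`: list with `is_hybrid`,
#'   `tract` (first/last converted acceptor positions or NULL),
#'   `switching_interval` (open interval, or NULL), `states`, and
#'   `segment_only` (TRUE for an interior, non-tail tract).
#' @export
detect_conversion_tract <- function(states, sites, min_run = 2L,
                                    upstream_boundary = NULL) {
  inf <- sites[sites$informative, , drop = FALSE]
  if (length(states) == 0L) {
    return(structure(
      list(
        is_hybrid = FALSE, tract = NULL, switching_interval = NULL,
        states = states, segment_only = FALSE
      ),
      class = "conversion_call"
    ))
  }
  stopifnot(length(states) == nrow(inf))
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  donor_runs <- which(r$values == "donor" & r$lengths >= min_run)
  if (!length(donor_runs)) {
    return(structure(
      list(
        is_hybrid = FALSE, tract = NULL, switching_interval = NULL,
        states = states, segment_only = FALSE
      ),
      class = "conversion_call"
    ))
  }
  best <- donor_runs[which.max(r$lengths[donor_runs])]
  first_i <- starts[best]
  last_i <- ends[best]
  tract <- c(inf$pos_a[first_i], inf$pos_a[last_i])
  is_tail <- last_i == length(states)
  lower <- if (first_i > 1L) {
    inf$pos_a[first_i - 1L]
  } else if (!is.null(upstream_boundary)) upstream_boundary else 0L
  structure(
    list(
      is_hybrid = is_tail,
      tract = tract,
      switching_interval = c(lower, inf$pos_a[first_i]),
      states = states,
      segment_only = !is_tail
    ),
    class = "conversion_call"
  )
}

#' @export
print.conversion_call <- function(x, ...) {
  if (is.null(x$tract)) {
    cat("<conversion_call> no conversion tract\n")
  } else {
    cat(
      "<conversion_call>", if (x$is_hybrid) "hybrid allele" else "conversion segment",
      sprintf(
        "; tract g.%d-g.%d; breakpoint between g.%d and g.%d\n",
        x$tract[1], x$tract[2], x$switching_interval[1], x$switching_interval[2] - 1L
      )
    )
  }
  invisible(x)
}

#' Count hybrid alleles in one diploid consensus
#'
#' Scores the diploid genotype at every informative diagnostic site: a
#' maximal tail run (length >= `min_run`) of sites all heterozygous
#' acceptor/donor is attributed to one hybrid haplotype (the phasing
#' assumption appropriate to Sanger-scored cohorts: an uninterrupted run of
#' heterozygous diagnostic sites is one hybrid chromosome, not two
#' reciprocal recombinants); a tail run of homozygous-donor sites counts
#' two hybrid alleles. A run mixing heterozygous and homozygous-donor
#' sites is flagged complex and counted conservatively as 1 with a
#' warning.
#'
#' @param consensus diploid IUPAC consensus in acceptor coordinates.
#' @param sites diagnostic-site table.
#' @param min_run minimum run length (default 2).
#' @return integer 0, 1 or 2.
#' @export
call_hybrids_diploid <- function(consensus, sites, min_run = 2L) {
  inf <- sites[sites$informative, , drop = FALSE]
  if (!nrow(inf)) {
    return(0L)
  }
  b <- substring(consensus, inf$pos_a, inf$pos_a)
  gt <- character(nrow(inf))
  for (i in seq_len(nrow(inf))) {
    alleles <- iupac_decode(b[i])[[1]]
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    has_a <- inf$base_a[i] %in% alleles
    has_d <- inf$base_b[i] %in% alleles
    gt[i] <- if (has_a && has_d && alleles[1] != alleles[2]) {
      "het"
    } else if (has_d && alleles[1] == alleles[2]) {
      "hom_donor"
    } else if (has_a && alleles[1] == alleles[2]) "hom_acceptor" else "other"
  }
  # maximal tail run of donor-bearing genotypes
  n <- length(gt)
  run_start <- n + 1L
  while (run_start > 1L && gt[run_start - 1L] %in% c("het", "hom_donor")) {
    run_start <- run_start - 1L
  }
  run <- gt[seq.int(run_start, length.out = n - run_start + 1L)]
  if (length(run) < min_run) {
    return(0L)
  }
  if (all(run == "het")) {
    return(1L)
  }
  if (all(run == "hom_donor")) {
    return(2L)
  }
  warning("complex diagnostic-site run (mixed het and hom-donor); counted as 1 hybrid allele")
  1L
}

#' Cohort hybrid allele frequency
#'
#' `100 * sum(counts) / (2 * n_samples)`, rounded half-up to two decimals
#' (42 hybrid alleles among 72 diploid samples read 29.17).
#'
#' @param counts per-sample hybrid allele counts (0, 1 or 2).
#' @param n_samples cohort size.
#' @return percentage with 2 decimals.
#' @export
hybrid_frequency <- function(counts, n_samples) {
  if (any(counts < 0L | counts > 2L)) stop("per-sample hybrid counts must be 0, 1 or 2")
  round_half_up(100 * sum(counts) / (2 * n_samples), 2)
}
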