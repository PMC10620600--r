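#' Scan a sequence for internal duplications
#'
#' Exact k-mer seeding followed by diagonal-band chaining and gapped
#' refinement: seed pairs sharing a k-mer are grouped by diagonal offset,
#' chained into candidate segment pairs, and each candidate is re-aligned
#' globally to measure identity. Only forward-orientation, non-overlapping
#' segment pairs of at least `min_len` bases and `min_identity` percent are
#' reported; the trivial self-diagonal never seeds a match.
#'
#' Defaults (k = 12, min identity 85, min length 300) are small enough to
#' catch exon-scale homology near 87 percent identity yet large enough that
#' a random 10 kb sequence yields no hits.
#'
#' @param seq nucleotide string.
#' @param k seed word size.
#' @param min_len minimum reported segment length (bases).
#' @param min_identity minimum percent identity of a reported match.
#' @param band_tol diagonal tolerance when chaining seeds (accommodates
#'   small indels between the copies).
#' @param max_gap maximum along-sequence gap between chained seeds.
#' @return data frame with columns `start_a`, `end_a`, `start_b`, `end_b`,
#'   `length`, `identity_pct`, `n_seeds`, ordered by `start_a`.
#' @export
self_similarity_scan <- function(seq, k = 12L, min_len = 300L, min_identity = 85,
                                 band_tol = 100L, max_gap = 1000L) {
  n <- nchar(seq)
  if (k >= n) stop("degenerate parameters: k >= sequence length")
  if (n <= 2L * min_len) stop("sequence shorter than twice min_len")
  starts <- seq_len(n - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  grp <- split(starts, words)
  grp <- grp[lengths(grp) >= 2L & lengths(grp) <= 10L]
  if (!length(grp)) {
    return(empty_segment_matches())
  }
  pair_i <- integer(0)
  pair_j <- integer(0)
  for (g in grp) {
    cmb <- utils::combn(sort(g), 2L)
    pair_i <- c(pair_i, cmb[1, ])
    pair_j <- c(pair_j, cmb[2, ])
  }
  diag_off <- pair_j - pair_i
  ord <- order(diag_off, pair_i)
  pair_i <- pair_i[ord]
  pair_j <- pair_j[ord]
  diag_off <- diag_off[ord]
  band_id <- cumsum(c(TRUE, diff(diag_off) > band_tol))
  out <- list()
  for (b in unique(band_id)) {
    sel <- band_id == b
    i <- pair_i[sel]
    j <- pair_j[sel]
    o <- order(i)
    i <- i[o]
    j <- j[o]
    seg_id <- cumsum(c(TRUE, diff(i) > max_gap))
    for (s in unique(seg_id)) {
      ii <- i[seg_id == s]
      jj <- j[seg_id == s]
      start_a <- min(ii)
      end_a <- max(ii) + k - 1L
      start_b <- min(jj)
      end_b <- max(jj) + k - 1L
      len <- max(end_a - start_a + 1L, end_b - start_b + 1L)
      if (len < min_len) next
      if (end_a >= start_b) next # overlapping copies: not a duplication
      idn <- alignment_identity(
        substring(seq, start_a, end_a),
        substring(seq, start_b, end_b)
      )
      if (idn$identity < min_identity) next
      out[[length(out) + 1L]] <- data.frame(
        start_a = start_a, end_a = end_a, start_b = start_b, end_b = end_b,
        length = len, identity_pct = idn$identity, n_seeds = length(ii)
      )
    }
  }
  if (!length(out)) {
    return(empty_segment_matches())
  }
  res <- do.call(rbind, out)
  res[order(res$start_a), , drop = FALSE]
}

empty_segment_matches <- function() {
  data.frame(
    start_a = integer(0), end_a = integer(0), start_b = integer(0),
    end_b = integer(0), length = integer(0), identity_pct = numeric(0),
    n_seeds = integer(0)
  )
}

#' Propose a two-gene structure for a fused annotation
#'
#' Given a fused gene model (exons 1-7 from the first copy of an internal
#' duplication, exons 8-9 from the second) and the self-similarity matches
#' on its sequence, projects the annotated exons through the duplication
#' mapping: the fused model's trailing exons are lifted back into the first
#' copy to complete gene A, and its leading exons are lifted forward into
#' the second copy to complete gene B.
#'
#' @param fused a [gene_model()] of the fused locus.
#' @param matches result of [self_similarity_scan()] on `fused$sequence`.
#' @return object of class `duplicate_proposal`: list with `gene_a`,
#'   `gene_b` (each: `span`, `exons` data frame, `exon_count`) and
#'   `intergenic_span`.
#' @export
propose_duplicate_structure <- function(fused, matches) {
  stopifnot(inherits(fused, "gene_model"))
  if (is.null(matches) || nrow(matches) == 0L) {
    stop("no duplicate structure detectable: no internal duplication match")
  }
  m <- matches[which.max(matches$length), ]
  ex <- fused$exons
  # attribute each exon to the copy holding the majority of its span
  # (seed coverage can start a few bases inside a terminal exon)
  frac_in <- function(lo, hi) {
    pmax(0, pmin(ex$end, hi) - pmax(ex$start, lo) + 1L) / (ex$end - ex$start + 1L)
  }
  in_a <- frac_in(m$start_a, m$end_a) > 0.5
  in_b <- frac_in(m$start_b, m$end_b) > 0.5
  if (!any(in_a) || !any(in_b)) {
    stop("no duplicate structure detectable: duplication does not cover the exon complement")
  }
  cmap <- build_coordinate_map(
    substring(fused$sequence, m$start_a, m$end_a),
    substring(fused$sequence, m$start_b, m$end_b)
  )
  # project with nearest-non-gap fallback
  proj <- function(pos, from, to, base_from, base_to) {
    rel <- pos - base_from + 1L
    hit <- to[match(rel, from)]
    if (is.na(hit)) {
      ok <- which(!is.na(from) & !is.na(to))
      nearest <- ok[which.min(abs(from[ok] - rel))]
      hit <- to[nearest] + (rel - from[nearest])
    }
    hit + base_to - 1L
  }
  a_to_b <- function(pos) proj(pos, cmap$pos_a, cmap$pos_b, m$start_a, m$start_b)
  b_to_a <- function(pos) proj(pos, cmap$pos_b, cmap$pos_a, m$start_b, m$start_a)

  exons_a <- ex[in_a, ]
  exons_b <- ex[in_b, ]
  # complete gene A with the projection of the B-side exons
  add_a <- data.frame(
    index = exons_b$index,
    start = vapply(exons_b$start, b_to_a, numeric(1)),
    end = vapply(exons_b$end, b_to_a, numeric(1))
  )
  gene_a_exons <- rbind(exons_a, add_a)
  gene_a_exons <- gene_a_exons[order(gene_a_exons$start), ]
  gene_a_exons$index <- seq_len(nrow(gene_a_exons))
  # complete gene B with the projection of the A-side exons
  add_b <- data.frame(
    index = exons_a$index,
    start = vapply(exons_a$start, a_to_b, numeric(1)),
    end = vapply(exons_a$end, a_to_b, numeric(1))
  )
  gene_b_exons <- rbind(add_b, exons_b)
  gene_b_exons <- gene_b_exons[order(gene_b_exons$start), ]
  gene_b_exons$index <- seq_len(nrow(gene_b_exons))

  span_a <- c(min(gene_a_exons$start), max(gene_a_exons$end))
  span_b <- c(min(gene_b_exons$start), max(gene_b_exons$end))
  if (span_a[2] >= span_b[1]) stop("proposed genes overlap; duplication mapping inconsistent")
  structure(
    list(
      gene_a = list(span = span_a, exons = gene_a_exons, exon_count = nrow(gene_a_exons)),
      gene_b = list(span = span_b, exons = gene_b_exons, exon_count = nrow(gene_b_exons)),
      intergenic_span = c(span_a[2] + 1L, span_b[1] - 1L),
      match = m
    ),
    class = "duplicate_proposal"
  )
}

#' Per-exon identity table between two paralogs
#'
#' Each exon pair is globally aligned with the package's fixed scoring and
#' its identity reported as `floor(100 * matches / alignment_columns)` —
#' integer truncation, the convention under which a single mismatch over
#' 179 bases reads 99 and two mismatches over 142 read 98.
#'
#' @param gene_a,gene_b [gene_model()]s with equal exon counts.
#' @return data frame with columns `exon`, `len_a`, `len_b`,
#'   `identity_pct` (integer). Invariant to argument order.
#' @export
exon_identity_table <- function(gene_a, gene_b) {
  stopifnot(inherits(gene_a, "gene_model"), inherits(gene_b, "gene_model"))
  if (nrow(gene_a$exons) != nrow(gene_b$exons)) {
    stop("exon count mismatch: ", nrow(gene_a$exons), " vs ", nrow(gene_b$exons))
  }
  k <- nrow(gene_a$exons)
  res <- data.frame(
    exon = seq_len(k),
    len_a = gene_a$exons$end - gene_a$exons$start + 1L,
    len_b = gene_b$exons$end - gene_b$exons$start + 1L,
    identity_pct = NA_integer_
  )
  for (i in seq_len(k)) {
    ea <- substring(gene_a$sequence, gene_a$exons$start[i], gene_a$exons$end[i])
    eb <- substring(gene_b$sequence, gene_b$exons$start[i], gene_b$exons$end[i])
    idn <- alignment_identity(ea, eb)
    res$identity_pct[i] <- floor(idn$identity)
  }
  res
}

#' Pairwise gene-level identity matrix for a family
#'
#' Aligns every pair of gene-local sequences (ATG to stop; the modeled
#' sequences carry no UTRs) and reports identity rounded half-up to one
#' decimal place.
#'
#' @param models list of [gene_model()]s (length >= 2), or a
#'   `paralog_family`.
#' @return symmetric numeric matrix with 100.0 on the diagonal.
#' @export
gene_identity_matrix <- function(models) {
  if (inherits(models, "paralog_family")) models <- models$models
  stopifnot(length(models) >= 2L)
  nm <- vapply(models, function(m) m$name, character(1))
  n <- length(models)
  out <- matrix(100.0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      idn <- alignment_identity(models[[i]]$sequence, models[[j]]$sequence)
      out[i, j] <- out[j, i] <- round_half_up(idn$identity, 1)
    }
  }
  out
}
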