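#' @name synthetic_family
#' @title Seeded simulation of a paralogous CYP2D-like gene family
#'
#' @description
#' The generator emulates the structure of the equine CYP2D region: a family
#' of nine paralogous single-gene models derived from a common ancestor with
#' controlled pairwise identities, among them a focal tandem pair
#' (CYP2D50-1 / CYP2D50-2) that reproduces the published landmarks of the
#' locus — the nine exon lengths, the gene-local positions of the
#' paralog-diagnostic sites in the intron 7 / exon 8 / exon 9 region, the
#' retained acceptor site just upstream of the conversion tract, the 3-bp
#' exon-4 length difference, and the +59 coordinate offset between the two
#' paralogs downstream of their planted insertions. Intron lengths are free
#' parameters of the model and are chosen here to place all cited gene-local
#' positions consistently at desk scale.
NULL

# Exon lengths of the focal paralog CYP2D50-1 (CDS 1503 nt).
FOCAL_EXON_LENGTHS <- c(189L, 172L, 153L, 161L, 177L, 142L, 188L, 142L, 179L)

# Synthetic intron lengths for the acceptor paralog; chosen so that
# g.92 -> c.92 (exon 1), g.2605 -> c.805 (exon 5), g.3328 -> c.1127
# (exon 7), g.3688..g.3843 fall in intron 7, g.3857/g.3870 in exon 8,
# and g.4240 -> c.1471 (exon 9).
FOCAL_INTRON_LENGTHS <- c(600L, 500L, 400L, 300L, 200L, 201L, 469L, 99L)

# Donor paralog: 56 extra intron-1 bases plus a 3-bp in-frame insertion in
# exon 4 give the +59 offset observed between corresponding positions of
# the two paralogs downstream of exon 4.
DONOR_INTRON1_EXTRA <- 56L
DONOR_EXON4_EXTRA <- 3L

# Paralog-diagnostic differences planted between the focal pair in the
# intron 7 / exon 8 / exon 9 region: acceptor (ref) and donor bases at
# acceptor gene-local positions. The two exon-8 rows (g.3857, g.3870) and
# the exon-9 row (g.4240) are the three exonic differences of the pair.
CONVERSION_REGION_SITES <- data.frame(
  pos_a = c(
    3688L, 3689L, 3717L, 3725L, 3730L, 3733L, 3737L, 3755L, 3772L, 3786L,
    3787L, 3793L, 3803L, 3805L, 3806L, 3807L, 3810L, 3811L, 3814L, 3817L,
    3819L, 3822L, 3823L, 3826L, 3828L, 3835L, 3837L, 3843L, 3857L, 3870L,
    4240L
  ),
  ref = c(
    "T", "C", "C", "T", "G", "G", "T", "G", "T", "T",
    "G", "C", "T", "C", "A", "G", "A", "G", "A", "T",
    "C", "C", "A", "C", "C", "T", "C", "A", "C", "C",
    "T"
  ),
  donor = c(
    "C", "G", "T", "C", "T", "T", "A", "T", "G", "C",
    "A", "G", "G", "T", "G", "A", "G", "T", "C", "C",
    "G", "T", "G", "T", "T", "C", "G", "G", "G", "A",
    "G"
  ),
  stringsAsFactors = FALSE
)

# Acceptor-retained diagnostic site upstream of the conversion tract: the
# last inter-paralog difference that is never converted in hybrid alleles,
# bounding the switching interval from below. Planted as a reconstruction:
# its existence is implied by the published breakpoint interval, not listed
# in any table.
RETAINED_SITE <- data.frame(pos_a = 3625L, ref = "G", donor = "A", stringsAsFactors = FALSE)

# Codons of the acceptor CDS fixed by the generator so that the canonical
# cohort substitutions produce their published amino-acid changes
# (e.g. codon 31 = CGC so G>A at c.92 reads R31H; codon 491 = TCT so T>G at
# c.1471 reads S491A). Codons 396 and 400 carry the exon-8 diagnostic
# differences; codon 501 is the stop.
FOCAL_FIXED_CODONS <- c(
  "1" = "ATG", "31" = "CGC", "45" = "GGA", "269" = "CAA", "376" = "GGC",
  "396" = "ACA", "400" = "TTC", "475" = "CAG", "486" = "ACC", "487" = "CTG",
  "489" = "TCC", "491" = "TCT", "496" = "TGT", "501" = "TAA"
)

# Intronic positions whose reference base is pinned (cohort variant
# landmarks outside exons).
FOCAL_FIXED_INTRONIC <- c("1096" = "T")

# The donor paralog's own cohort polymorphism: T>C at donor position
# g.3864 (equal to acceptor g.3805 + 59), fixed (homozygous) in the donor
# population. It confounds the corresponding diagnostic site.
donor_fixed_variants <- function() {
  data.frame(
    gene = "CYP2D50-2", g_pos = 3864L, ref = "T", alt = "C",
    frequency_pct = 100, stringsAsFactors = FALSE
  )
}

#' Default family guide tree and identity targets
#'
#' The default pairwise identity targets are derived from a fixed guide
#' tree whose cophenetic distances put every pair in the 78-95 percent
#' band typical of the CYP2D region, with the focal tandem pair at 93.7.
#' Being tree-additive by construction, the targets are exactly realizable
#' by branch-wise substitution placement.
#'
#' @return symmetric matrix of percent identities with locus names.
#' @export
default_family_identity <- function() {
  tr <- ape::read.tree(text = paste0(
    "(((CYP2D50-1:2.0,CYP2D50-2:4.3):3.0,CYP2D14-LOC100070895:4.0):4.5,",
    "(CYP2D86:2.5,CYP2D82:2.6):6.0,",
    "((CYP2D14-LOC100070905:5.0,CYP2D88:5.2):1.5,",
    "(CYP2D84:5.1,CYP2D89:5.3):1.6):2.0);"
  ))
  d <- ape::cophenetic.phylo(tr)
  m <- 100 - d
  diag(m) <- 100
  m[order(rownames(m)), order(colnames(m))]
}

#' Configuration for the synthetic gene family
#'
#' @param target_identity symmetric matrix of pairwise percent identities
#'   in (50, 100], with locus names on both dimensions. Defaults to
#'   [default_family_identity()].
#' @param focal_pair names of the two focal paralogs (acceptor, donor).
#' @param focal_constraints plant the focal landmarks (diagnostic sites,
#'   exon-4 indel, fixed codons)? Disable for free-form small families.
#' @param tolerance maximum allowed deviation (percentage points) between
#'   realizable and requested identities before the matrix is declared
#'   infeasible.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return a `family_config` list.
#' @export
family_config <- function(target_identity = default_family_identity(),
                          focal_pair = c("CYP2D50-1", "CYP2D50-2"),
                          focal_constraints = TRUE,
                          tolerance = 1.0,
                          seed = 1L) {
  target_identity <- as.matrix(target_identity)
  if (is.null(rownames(target_identity))) {
    stop("target_identity must carry locus names")
  }
  if (!isTRUE(all.equal(target_identity, t(target_identity)))) {
    stop("target_identity must be symmetric")
  }
  off <- target_identity[upper.tri(target_identity)]
  if (any(off <= 50) || any(off > 100)) {
    stop("identity targets must lie in (50, 100]")
  }
  if (focal_constraints && !all(focal_pair %in% rownames(target_identity))) {
    stop("focal pair absent from target_identity")
  }
  structure(
    list(
      target_identity = target_identity,
      n_loci = nrow(target_identity),
      focal_pair = focal_pair,
      focal_constraints = isTRUE(focal_constraints),
      tolerance = tolerance,
      seed = as.integer(seed)
    ),
    class = "family_config"
  )
}

# --- internal scaffolding -------------------------------------------------

focal_scaffold <- function() {
  exons <- exon_table(FOCAL_EXON_LENGTHS, FOCAL_INTRON_LENGTHS)
  gene_len <- exons$end[nrow(exons)]
  g_pos <- unlist(mapply(seq.int, exons$start, exons$end, SIMPLIFY = FALSE))
  smap <- data.frame(
    g_pos = g_pos, c_pos = seq_along(g_pos),
    exon = rep(exons$index, exons$end - exons$start + 1L)
  )
  list(exons = exons, gene_len = gene_len, smap = smap)
}

# positions that must never receive random substitutions
protected_positions <- function(sc) {
  prot <- integer(0)
  # start and stop codons
  prot <- c(prot, sc$smap$g_pos[sc$smap$c_pos %in% c(1:3, (max(sc$smap$c_pos) - 2):max(sc$smap$c_pos))])
  # splice dinucleotides GT..AG of every intron
  for (i in seq_len(nrow(sc$exons) - 1L)) {
    prot <- c(
      prot,
      sc$exons$end[i] + 1:2,
      sc$exons$start[i + 1L] - (2:1)
    )
  }
  # fixed codons and pinned intronic bases
  fixed_c <- as.integer(names(FOCAL_FIXED_CODONS))
  prot <- c(prot, sc$smap$g_pos[ceiling(sc$smap$c_pos / 3) %in% fixed_c])
  prot <- c(prot, as.integer(names(FOCAL_FIXED_INTRONIC)))
  # diagnostic landmarks
  prot <- c(prot, CONVERSION_REGION_SITES$pos_a, RETAINED_SITE$pos_a)
  sort(unique(prot))
}

# build the ancestral sequence on the focal scaffold: random bases, valid
# splice dinucleotides, no internal stop codon, fixed codons applied
build_root_sequence <- function(sc) {
  bases <- c("A", "C", "G", "T")
  n_cds <- max(sc$smap$c_pos)
  n_codon <- n_cds %/% 3L
  non_stop <- setdiff(
    apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
    STOP_CODONS
  )
  codons <- sample(non_stop, n_codon, replace = TRUE)
  fixed_idx <- as.integer(names(FOCAL_FIXED_CODONS))
  codons[fixed_idx] <- unname(FOCAL_FIXED_CODONS)
  cds <- seq_chars(paste(codons, collapse = ""))
  seq <- character(sc$gene_len)
  seq[sc$smap$g_pos] <- cds[sc$smap$c_pos]
  intronic <- setdiff(seq_len(sc$gene_len), sc$smap$g_pos)
  seq[intronic] <- sample(bases, length(intronic), replace = TRUE)
  for (i in seq_len(nrow(sc$exons) - 1L)) {
    seq[sc$exons$end[i] + 1:2] <- c("G", "T")
    seq[sc$exons$start[i + 1L] - (2:1)] <- c("A", "G")
  }
  for (p in names(FOCAL_FIXED_INTRONIC)) seq[as.integer(p)] <- FOCAL_FIXED_INTRONIC[[p]]
  seq[CONVERSION_REGION_SITES$pos_a] <- CONVERSION_REGION_SITES$ref
  seq[RETAINED_SITE$pos_a] <- RETAINED_SITE$ref
  seq
}

# mutate `seq` (character vector) at `positions` to random non-matching
# bases, refusing exonic substitutions that would create a stop codon
mutate_positions <- function(seq, positions, sc, forced_base = NULL) {
  bases <- c("A", "C", "G", "T")
  c_of <- function(g) {
    i <- match(g, sc$smap$g_pos)
    if (is.na(i)) NA_integer_ else sc$smap$c_pos[i]
  }
  for (k in seq_along(positions)) {
    p <- positions[k]
    cur <- seq[p]
    if (!is.null(forced_base)) {
      seq[p] <- forced_base[k]
      next
    }
    alts <- setdiff(bases, cur)
    cp <- c_of(p)
    if (!is.na(cp)) {
      codon_start_c <- 3L * ((cp - 1L) %/% 3L) + 1L
      codon_g <- sc$smap$g_pos[match(codon_start_c + 0:2, sc$smap$c_pos)]
      off <- which(codon_g == p)
      safe <- alts[vapply(alts, function(b) {
        cod <- seq[codon_g]
        cod[off] <- b
        !(chars_seq(cod) %in% STOP_CODONS)
      }, logical(1))]
      if (length(safe) == 0L) next # cannot mutate safely; leave untouched
      alts <- safe
    }
    seq[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
  }
  seq
}

# --- generator ------------------------------------------------------------

#' Simulate a paralogous gene family with calibrated identities
#'
#' Sequences are evolved along a neighbor-joining guide tree fitted to the
#' requested identity matrix, with an exact substitution count per branch
#' and every substituted position used on at most one branch, so realized
#' pairwise divergences equal path sums exactly. Exonic substitutions never
#' create stop codons and splice dinucleotides are preserved. When focal
#' constraints are on, the focal pair additionally differs at the planted
#' diagnostic sites (two exonic differences in exon 8, one in exon 9) and
#' the donor paralog carries the 3-bp exon-4 and 56-bp intron-1 insertions.
#'
#' @param cfg a [family_config()].
#' @return object of class `paralog_family`: list with `models` (named list
#'   of [gene_model()]), `truth` (planted branch substitutions, diagnostic
#'   sites, indels, guide tree) and `config`.
#' @export
simulate_family <- function(cfg = family_config()) {
  stopifnot(inherits(cfg, "family_config"))
  set.seed(cfg$seed)
  sc <- focal_scaffold()
  loci <- rownames(cfg$target_identity)
  acceptor <- cfg$focal_pair[1]
  donor <- cfg$focal_pair[2]
  has_donor <- cfg$focal_constraints
  L <- sc$gene_len
  gap_extra <- DONOR_INTRON1_EXTRA + DONOR_EXON4_EXTRA

  # convert identity targets to substitution-count targets; pairs with the
  # indel-bearing donor have extra gap columns in their alignments
  n <- length(loci)
  subs_target <- matrix(0, n, n, dimnames = list(loci, loci))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      gap <- if (has_donor && xor(loci[i] == donor, loci[j] == donor)) gap_extra else 0L
      cols <- L + gap
      subs_target[i, j] <- cols * (1 - cfg$target_identity[i, j] / 100) - gap
    }
  }
  if (any(subs_target[upper.tri(subs_target)] < 0)) {
    stop("infeasible identity matrix: targets too close to 100 for the planted indels")
  }

  n_special <- nrow(CONVERSION_REGION_SITES) + nrow(RETAINED_SITE)

  # fit integer branch lengths on a guide tree
  if (n == 2L) {
    edges <- data.frame(parent = c(3L, 3L), child = c(1L, 2L))
    half <- subs_target[1, 2] / 2
    edge_len <- c(ceiling(half), floor(half))
    tip_labels <- loci
    tree <- NULL
  } else {
    tree <- ape::nj(stats::as.dist(subs_target))
    tree <- phangorn::nnls.tree(stats::as.dist(subs_target), tree, method = "unrooted")
    tree$edge.length <- pmax(0, round(tree$edge.length))
    realized <- ape::cophenetic.phylo(tree)[loci, loci]
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        gap <- if (has_donor && xor(loci[i] == donor, loci[j] == donor)) gap_extra else 0L
        cols <- L + gap
        ident <- 100 * (cols - gap - realized[i, j]) / cols
        if (abs(ident - cfg$target_identity[i, j]) > cfg$tolerance) {
          stop(
            "infeasible identity matrix: pair ", loci[i], "/", loci[j],
            " realizable only at ", format(ident, digits = 4),
            " vs target ", cfg$target_identity[i, j]
          )
        }
      }
    }
    edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])
    edge_len <- tree$edge.length
    tip_labels <- tree$tip.label
  }

  # allocate substitution positions: focal tip branches draw from a
  # restricted region (sparing exon 2, the conversion-region suffix,
  # exon 8, intron 8 and exon 9); all positions globally unique
  prot <- protected_positions(sc)
  pool_all <- setdiff(seq_len(L), prot)
  suffix_start <- RETAINED_SITE$pos_a + 1L
  exon2 <- seq.int(sc$exons$start[2], sc$exons$end[2])
  pool_focal <- setdiff(pool_all, c(exon2, seq.int(suffix_start, L)))

  tip_edge <- function(label) which(edges$child == match(label, tip_labels))
  acc_edge <- if (acceptor %in% tip_labels) tip_edge(acceptor) else integer(0)
  don_edge <- if (donor %in% tip_labels) tip_edge(donor) else integer(0)

  if (has_donor) {
    if (length(don_edge) != 1L || edge_len[don_edge] < n_special) {
      stop(
        "infeasible identity matrix: donor branch shorter than the ",
        n_special, " planted diagnostic sites"
      )
    }
  }
  total_needed <- sum(edge_len) - if (has_donor) n_special else 0L
  if (total_needed > length(pool_all)) {
    stop("infeasible identity matrix: requires more substitutions than available positions")
  }

  take <- function(pool, k) {
    if (k > length(pool)) stop("infeasible identity matrix: focal region exhausted")
    if (k == 0L) integer(0) else sample(pool, k)
  }

  used <- integer(0)
  edge_sites <- vector("list", nrow(edges))
  special_pos <- c(RETAINED_SITE$pos_a, CONVERSION_REGION_SITES$pos_a)
  special_base <- c(RETAINED_SITE$donor, CONVERSION_REGION_SITES$donor)
  focal_first <- c(don_edge, acc_edge)
  for (e in c(focal_first, setdiff(seq_len(nrow(edges)), focal_first))) {
    k <- edge_len[e]
    if (has_donor && length(don_edge) && e == don_edge) {
      rnd <- take(setdiff(pool_focal, used), k - n_special)
      edge_sites[[e]] <- list(pos = c(special_pos, rnd), forced = special_base)
      used <- c(used, rnd)
    } else if (has_donor && length(acc_edge) && e == acc_edge) {
      rnd <- take(setdiff(pool_focal, used), k)
      edge_sites[[e]] <- list(pos = rnd, forced = NULL)
      used <- c(used, rnd)
    } else {
      rnd <- take(setdiff(pool_all, used), k)
      edge_sites[[e]] <- list(pos = rnd, forced = NULL)
      used <- c(used, rnd)
    }
  }

  # walk the tree from the (arbitrary) root node, mutating along each edge
  root_seq <- build_root_sequence(sc)
  root_node <- if (n == 2L) 3L else length(tip_labels) + 1L
  node_seq <- list()
  node_seq[[as.character(root_node)]] <- root_seq
  remaining <- seq_len(nrow(edges))
  frontier <- root_node
  while (length(remaining)) {
    nxt <- integer(0)
    for (e in remaining) {
      if (edges$parent[e] %in% frontier) {
        parent_seq <- node_seq[[as.character(edges$parent[e])]]
        es <- edge_sites[[e]]
        child_seq <- parent_seq
        if (length(es$forced)) {
          nf <- length(es$forced)
          child_seq <- mutate_positions(child_seq, es$pos[seq_len(nf)], sc, forced_base = es$forced)
          child_seq <- mutate_positions(child_seq, es$pos[-seq_len(nf)], sc)
        } else {
          child_seq <- mutate_positions(child_seq, es$pos, sc)
        }
        node_seq[[as.character(edges$child[e])]] <- child_seq
        nxt <- c(nxt, edges$child[e])
      }
    }
    done <- edges$parent[remaining] %in% frontier
    remaining <- remaining[!done]
    frontier <- nxt
    if (length(frontier) == 0L && length(remaining)) stop("internal error: disconnected guide tree")
  }

  models <- list()
  for (i in seq_along(loci)) {
    s <- node_seq[[as.character(match(loci[i], tip_labels))]]
    if (has_donor && loci[i] == donor) {
      models[[loci[i]]] <- build_donor_model(donor, s, sc)
    } else {
      models[[loci[i]]] <- gene_model(loci[i], chars_seq(s), sc$exons)
    }
  }

  structure(
    list(
      models = models,
      truth = list(
        guide_tree = tree,
        edge_substitutions = edge_sites,
        diagnostic_sites = CONVERSION_REGION_SITES,
        retained_site = RETAINED_SITE,
        donor_offset = if (has_donor) gap_extra else 0L,
        donor_variants = if (has_donor) donor_fixed_variants() else NULL
      ),
      config = cfg
    ),
    class = "paralog_family"
  )
}

# apply the donor paralog's planted insertions: 56 bp into intron 1 and an
# in-frame GCT codon into exon 4, shifting downstream coordinates by +59
build_donor_model <- function(name, seq_chars_acc, sc) {
  intron1_at <- sc$exons$end[1] + 260L # inside intron 1, clear of GT/AG
  # insertion point at a codon boundary inside exon 4 (after c.600)
  exon4_at <- sc$smap$g_pos[match(600L, sc$smap$c_pos)]
  ins1 <- sample(c("A", "C", "G", "T"), DONOR_INTRON1_EXTRA, replace = TRUE)
  s <- append(seq_chars_acc, ins1, after = intron1_at)
  s <- append(s, c("G", "C", "T"), after = exon4_at + DONOR_INTRON1_EXTRA)
  exon_lengths <- FOCAL_EXON_LENGTHS
  exon_lengths[4] <- exon_lengths[4] + DONOR_EXON4_EXTRA
  intron_lengths <- FOCAL_INTRON_LENGTHS
  intron_lengths[1] <- intron_lengths[1] + DONOR_INTRON1_EXTRA
  gene_model(name, chars_seq(s), exon_table(exon_lengths, intron_lengths))
}

#' Assemble the fused single-gene annotation of the tandem locus
#'
#' Reproduces the mis-annotation the structure-discovery stage must
#' dissect: one locus sequence consisting of the acceptor gene, an
#' intergenic spacer, and the donor gene, annotated as a single 9-exon
#' gene whose exons 1-7 come from the first copy and exons 8-9 from the
#' second.
#'
#' @param family a [simulate_family()] result with focal constraints.
#' @param intergenic_length spacer length between the two copies
#'   (the real locus has a roughly 13 kb intergenic region).
#' @param seed seed for the spacer sequence.
#' @return list with `locus` (a fused [gene_model()]) and `truth`
#'   (true spans of the two genes and the intergenic region).
#' @export
simulate_fused_locus <- function(family, intergenic_length = 13000L, seed = 1L) {
  stopifnot(inherits(family, "paralog_family"))
  acc <- family$models[[family$config$focal_pair[1]]]
  don <- family$models[[family$config$focal_pair[2]]]
  if (is.null(acc) || is.null(don)) stop("family lacks the focal pair")
  set.seed(seed)
  spacer <- paste(sample(c("A", "C", "G", "T"), intergenic_length, replace = TRUE), collapse = "")
  seq <- paste0(acc$sequence, spacer, don$sequence)
  off <- nchar(acc$sequence) + intergenic_length
  ex_a <- acc$exons[1:7, ]
  ex_b <- don$exons[8:9, ]
  ex_b$start <- ex_b$start + off
  ex_b$end <- ex_b$end + off
  exons <- rbind(ex_a, ex_b)
  exons$index <- seq_len(nrow(exons))
  locus <- gene_model("CYP2D50-fused", seq, exons)
  list(
    locus = locus,
    truth = list(
      geneA_span = c(1L, nchar(acc$sequence)),
      geneB_span = c(off + 1L, off + nchar(don$sequence)),
      intergenic_span = c(nchar(acc$sequence) + 1L, off)
    )
  )
}
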