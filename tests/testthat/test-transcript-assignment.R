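test_that("identical consensus and reference give an empty pattern", {
  expect_equal(nrow(genotype_pattern("ACGTAC", "ACGTAC")), 0)
})

test_that("patterns decode IUPAC heterozygotes and homozygous alternates", {
  p <- genotype_pattern("AMGTAC", "ACGTAC")
  expect_equal(p$c_pos, 2L)
  expect_equal(p$label, "HET")
  expect_setequal(c(p$allele1, p$allele2), c("A", "C"))
  p2 <- genotype_pattern("AGGTAC", "ACGTAC")
  expect_equal(p2$label, "MUT")
  expect_error(genotype_pattern("ACG", "ACGT"), "length mismatch")
})

test_that("all four printed transcript patterns assign uniquely to CYP2D50-1", {
  res <- assign_printed_transcripts()
  expect_length(res, 4)
  for (h in names(res)) {
    expect_equal(res[[h]]$verdict, "assigned", info = paste("horse", h))
    expect_equal(res[[h]]$gene, "CYP2D50-1", info = paste("horse", h))
  }
})

test_that("the fused structure fails at the discriminating positions", {
  res <- assign_printed_transcripts()
  # horse 1: the fused annotation disagrees at c.1185 and c.1198
  mm1 <- res[["1"]]$mismatches[["CYP2D50-NCBI"]]
  expect_setequal(mm1$c_pos, c(1185L, 1198L))
  # horse 2: it disagrees at c.1471 (homozygous T/T against the het T/G transcript)
  mm2 <- res[["2"]]$mismatches[["CYP2D50-NCBI"]]
  expect_equal(mm2$c_pos, 1471L)
  # the second paralog is excluded for every horse
  for (h in names(res)) {
    expect_gt(nrow(res[[h]]$mismatches[["CYP2D50-2"]]), 0)
  }
})

test_that("an empty pattern against identical candidates is ambiguous", {
  tp <- genotype_pattern("ACGT", "ACGT")
  res <- assign_transcript(tp, list(g1 = tp, g2 = tp))
  expect_equal(res$verdict, "ambiguous")
  expect_setequal(res$gene, c("g1", "g2"))
})

test_that("synthetic transcripts assign to their source locus when distinguishable", {
  fam <- shared_family()
  candidates <- lapply(fam$models, function(m) {
    list(cds = splice_cds(m)$cds, genotype = paralocus:::empty_pattern())
  })
  withr::local_seed(41)
  some <- sample(names(fam$models), 4)
  for (locus in some) {
    tx <- splice_cds(fam$models[[locus]])$cds
    res <- assign_transcript_seq(tx, candidates)
    expect_equal(res$verdict, "assigned", info = locus)
    expect_equal(res$gene, locus, info = locus)
  }
})

test_that("indistinguishable candidates yield an ambiguous verdict", {
  tgt <- matrix(100, 2, 2, dimnames = list(c("L1", "L2"), c("L1", "L2")))
  fam <- simulate_family(family_config(target_identity = tgt, focal_constraints = FALSE, seed = 8))
  candidates <- lapply(fam$models, function(m) {
    list(cds = splice_cds(m)$cds, genotype = paralocus:::empty_pattern())
  })
  tx <- splice_cds(fam$models[["L1"]])$cds
  res <- assign_transcript_seq(tx, candidates)
  expect_equal(res$verdict, "ambiguous")
})

test_that("assignment is invariant to candidate order", {
  res <- assign_printed_transcripts()
  g <- read_transcript_genotypes()
  rows <- g[g$horse == 1, ]
  tp <- paralocus:::pattern_from_entries(rows, "transcript")
  cands <- list(
    "CYP2D50-NCBI" = paralocus:::pattern_from_entries(rows, "ncbi"),
    "CYP2D50-2" = paralocus:::pattern_from_entries(rows, "cyp2d50_2"),
    "CYP2D50-1" = paralocus:::pattern_from_entries(rows, "cyp2d50_1")
  )
  r2 <- assign_transcript(tp, cands)
  expect_equal(r2$verdict, res[["1"]]$verdict)
  expect_equal(r2$gene, res[["1"]]$gene)
})

test_that("expressed-locus inference applies the indirect non-expression argument", {
  assignments <- data.frame(
    transcript = c("t1", "t2"),
    verdict = "assigned",
    gene = "CYP2D50-1",
    assay = "panA",
    stringsAsFactors = FALSE
  )
  assays <- list(
    panA = c("CYP2D50-1", "LOC100070895", "LOC100070962"),
    panB = c("CYP2D89")
  )
  st <- detect_expressed_loci(assignments, assays)
  expect_equal(st$status[st$locus == "CYP2D50-1"], "detected")
  expect_equal(st$status[st$locus == "LOC100070895"], "not_detected")
  expect_equal(st$status[st$locus == "LOC100070962"], "not_detected")
  # an assay never used leaves its loci untested
  expect_equal(st$status[st$locus == "CYP2D89"], "untested")
})

test_that("an assignment outside every assay's amplifiable set errors", {
  assignments <- data.frame(
    transcript = "t1", verdict = "assigned", gene = "GHOST", assay = "panA"
  )
  expect_error(
    detect_expressed_loci(assignments, list(panA = "CYP2D50-1")),
    "consistency error"
  )
})

test_that("six expressed loci of nine are detected on the synthetic family", {
  fam <- shared_family()
  six <- c(
    "CYP2D50-1", "CYP2D50-2", "CYP2D84", "CYP2D86", "CYP2D82",
    "CYP2D14-LOC100070905"
  )
  tx <- simulate_transcripts(fam, six)
  candidates <- lapply(fam$models, function(m) {
    list(cds = splice_cds(m)$cds, genotype = paralocus:::empty_pattern())
  })
  assays <- list(panfamily = names(fam$models))
  assignments <- do.call(rbind, lapply(names(tx), function(id) {
    a <- assign_transcript_seq(tx[[id]], candidates)
    data.frame(
      transcript = id, verdict = a$verdict,
      gene = if (length(a$gene) == 1) a$gene else NA_character_,
      assay = "panfamily", stringsAsFactors = FALSE
    )
  }))
  st <- detect_expressed_loci(assignments, assays)
  expect_equal(sum(st$status == "detected"), 6)
  expect_equal(sum(st$status == "not_detected"), 3)
  expect_setequal(st$locus[st$status == "detected"], six)
})
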