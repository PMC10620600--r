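test_that("a consensus equal to the reference yields no calls", {
  acc <- shared_family()$models[["CYP2D50-1"]]
  calls <- call_variants(acc$sequence, acc)
  expect_equal(nrow(calls), 0)
})

test_that("an R code at a G reference decodes to a heterozygous G>A call", {
  acc <- shared_family()$models[["CYP2D50-1"]]
  cons <- acc$sequence
  substr(cons, 92, 92) <- "R" # A/G over reference G
  calls <- call_variants(cons, acc)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$g_pos, 92L)
  expect_equal(calls$ref, "G")
  expect_equal(calls$alt, "A")
  expect_equal(calls$zygosity, "HET")
  expect_equal(annotate_effect(calls[1, ], acc), "R31H")
})

test_that("cohort calling recovers the generator truth table exactly", {
  fam <- shared_family()
  co <- shared_cohort()
  acc <- fam$models[["CYP2D50-1"]]
  cons <- co$consensus[["CYP2D50-1"]]
  calls <- do.call(rbind, lapply(names(cons), function(s) {
    call_variants(cons[[s]], acc, sample = s, merge_mnv = FALSE)
  }))
  truth <- co$truth$calls
  called_keys <- sort(paste(calls$sample, calls$g_pos, calls$alt, calls$zygosity))
  truth_keys <- sort(paste(truth$sample, truth$g_pos, truth$alt, truth$zygosity))
  # precision = recall = 1
  expect_identical(called_keys, truth_keys)
})

test_that("calling stays exact across seeds on small cohorts", {
  fam <- shared_family()
  acc <- fam$models[["CYP2D50-1"]]
  panel <- default_cohort_variants(acc)
  panel$allele_count <- pmin(panel$allele_count, 4L)
  for (seed in c(31, 32, 33)) {
    co <- simulate_cohort(fam, cohort_spec(
      n_samples = 12, hybrid_allele_count = 5, seed = seed, variants = panel
    ))
    cons <- co$consensus[["CYP2D50-1"]]
    calls <- do.call(rbind, lapply(names(cons), function(s) {
      call_variants(cons[[s]], acc, sample = s, merge_mnv = FALSE)
    }))
    truth <- co$truth$calls
    expect_identical(
      sort(paste(calls$sample, calls$g_pos, calls$alt, calls$zygosity)),
      sort(paste(truth$sample, truth$g_pos, truth$alt, truth$zygosity))
    )
  }
})

test_that("invalid consensus symbols and length mismatches are rejected", {
  acc <- shared_family()$models[["CYP2D50-1"]]
  cons <- acc$sequence
  substr(cons, 10, 10) <- "N"
  expect_error(call_variants(cons, acc), "invalid IUPAC")
  expect_error(call_variants(substr(acc$sequence, 1, 100), acc), "length")
})

test_that("regions classify into the correct exon or intron", {
  acc <- shared_family()$models[["CYP2D50-1"]]
  expect_equal(classify_region(92, acc), list(type = "exon", index = 1L))
  expect_equal(classify_region(1, acc), list(type = "exon", index = 1L))
  expect_equal(classify_region(3688, acc), list(type = "intron", index = 7L))
  expect_equal(classify_region(1096, acc), list(type = "intron", index = 2L))
  expect_equal(classify_region(4240, acc), list(type = "exon", index = 9L))
})

test_that("effect annotation reproduces the canonical substitutions", {
  acc <- shared_family()$models[["CYP2D50-1"]]
  sub <- function(pos, alt) list(g_pos = pos, g_end = pos, ref = substring(acc$sequence, pos, pos), alt = alt, type = "snv")
  expect_equal(annotate_effect(sub(92, "A"), acc), "R31H")
  expect_equal(annotate_effect(sub(134, "A"), acc), "G45E")
  expect_equal(annotate_effect(sub(2605, "A"), acc), "Q269K")
  expect_equal(annotate_effect(sub(3328, "C"), acc), "G376A")
  expect_equal(annotate_effect(sub(4226, "T"), acc), "T486I")
  expect_equal(annotate_effect(sub(4240, "G"), acc), "S491A")
  expect_equal(annotate_effect(sub(4255, "A"), acc), "C496S")
  expect_equal(annotate_effect(sub(1096, "C"), acc), "intronic")
  expect_equal(ceiling(1471 / 3), 491)
})

test_that("effect annotation agrees with a whole-CDS translation oracle", {
  acc <- shared_family()$models[["CYP2D50-1"]]
  sp <- splice_cds(acc)
  withr::local_seed(21)
  probes <- sample(sp$map$g_pos, 60)
  for (g in probes) {
    ref_base <- substring(acc$sequence, g, g)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    eff <- annotate_effect(list(g_pos = g, g_end = g, ref = ref_base, alt = alt, type = "snv"), acc)
    # oracle: mutate the full CDS string, translate both, diff
    cpos <- sp$map$c_pos[match(g, sp$map$g_pos)]
    mut <- sp$cds
    substr(mut, cpos, cpos) <- alt
    aa_ref <- translate_cds(sp$cds)
    aa_mut <- translate_cds(mut)
    changed <- which(aa_ref != aa_mut)
    if (length(changed) == 0) {
      expect_equal(eff, "synonymous", info = paste("g.", g))
    } else {
      expect_equal(
        eff, sprintf("%s%d%s", aa_ref[changed], changed, aa_mut[changed]),
        info = paste("g.", g)
      )
    }
  }
})

test_that("a fully substituted codon merges into one MNV translated as a unit", {
  g82 <- shared_cyp2d82()
  cons <- g82$sequence
  # AAG>GGA at codon 248 in heterozygosity: R,R,R over positions 2673-2675
  substr(cons, 2673, 2675) <- "RRR"
  calls <- call_variants(cons, g82)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "mnv")
  expect_equal(calls$ref, "AAG")
  expect_equal(calls$alt, "GGA")
  expect_equal(annotate_effect(calls[1, ], g82), "K248G")
})

test_that("an 11-bp exonic deletion annotates as a frameshift at codon 378", {
  g82 <- shared_cyp2d82()
  expect_equal(substring(g82$sequence, 3474, 3484), "CCACATGACAT")
  del <- list(g_pos = 3474L, g_end = 3484L, ref = "CCACATGACAT", alt = "del", type = "del")
  expect_equal(annotate_effect(del, g82), "378 fs")
  # an in-frame deletion is not a frameshift
  del3 <- list(g_pos = 3474L, g_end = 3476L, ref = "CCA", alt = "del", type = "del")
  expect_equal(annotate_effect(del3, g82), "inframe_del")
})

test_that("allele frequencies follow the half-up two-decimal convention", {
  expect_equal(allele_frequency(1, 0, 72), 0.69)
  expect_equal(allele_frequency(25, 18, 72), 42.36)
  expect_equal(allele_frequency(0, 0, 72), 0)
  expect_equal(allele_frequency(11, 0, 72), 7.64)
  expect_equal(allele_frequency(0, 72, 72), 100)
  expect_error(allele_frequency(1, 0, 0), "zero genotyped")
})

test_that("planted allele counts reproduce their frequencies through the table", {
  fam <- shared_family()
  co <- shared_cohort()
  acc <- fam$models[["CYP2D50-1"]]
  cons <- co$consensus[["CYP2D50-1"]]
  calls <- do.call(rbind, lapply(names(cons), function(s) call_variants(cons[[s]], acc, sample = s)))
  tab <- cohort_variant_table(calls, 72)
  planted <- co$truth$planted_variants
  for (i in seq_len(nrow(planted))) {
    v <- planted[i, ]
    if (v$g_pos == 4240) next # shared with hybrid haplotypes, checked elsewhere
    row <- tab[tab$g_pos == v$g_pos & tab$alt == v$alt, ]
    expect_equal(row$frequency_pct, round_half_up(100 * v$allele_count / 144, 2),
      info = paste("g.", v$g_pos)
    )
  }
  expect_equal(tab$frequency_pct[tab$g_pos == 4240], 42.36)
})

test_that("missing genotypes reduce the frequency denominator", {
  expect_equal(allele_frequency(1, 0, 71), round_half_up(100 / 142, 2))
})

test_that("novelty annotation distinguishes known from novel variants", {
  known <- read_known_variants()
  v <- data.frame(
    gene = "CYP2D50-1",
    g_pos = c(2605L, 92L),
    ref = c("C", "G"),
    alt = c("A", "A")
  )
  out <- annotate_novelty(v, known)
  expect_equal(out$rs_id, c("rs1148503187", "novel"))
  all_novel <- annotate_novelty(v, known[0, ])
  expect_true(all(all_novel$rs_id == "novel"))
})

test_that("the canonical missense panel contains exactly six novel substitutions", {
  scores <- read_effect_scores()
  d501 <- scores[scores$gene == "CYP2D50-1", ]
  novel_missense <- d501[d501$rs_id == "novel", ]
  expect_equal(nrow(novel_missense), 6)
  expect_setequal(
    novel_missense$aa_change,
    c("R31H", "G45E", "G376A", "T486I", "L487V", "S489F")
  )
})
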