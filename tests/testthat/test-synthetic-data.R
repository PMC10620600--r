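test_that("generators are pure functions of config and seed", {
  f1 <- simulate_family(family_config(seed = 42))
  f2 <- simulate_family(family_config(seed = 42))
  expect_identical(
    lapply(f1$models, function(m) m$sequence),
    lapply(f2$models, function(m) m$sequence)
  )
  c1 <- simulate_cohort(f1, cohort_spec(seed = 9, sampling_mode = "binomial"))
  c2 <- simulate_cohort(f2, cohort_spec(seed = 9, sampling_mode = "binomial"))
  expect_identical(c1$consensus, c2$consensus)
  q1 <- simulate_qpcr(qpcr_spec(seed = 5, ct_noise_sd = 0.3))
  q2 <- simulate_qpcr(qpcr_spec(seed = 5, ct_noise_sd = 0.3))
  expect_identical(q1$samples, q2$samples)
})

test_that("a two-locus family at target identity 100 yields identical sequences", {
  tgt <- matrix(100, 2, 2, dimnames = list(c("L1", "L2"), c("L1", "L2")))
  fam <- simulate_family(family_config(
    target_identity = tgt, focal_constraints = FALSE, seed = 3
  ))
  expect_identical(fam$models[["L1"]]$sequence, fam$models[["L2"]]$sequence)
})

test_that("the focal pair differs by exactly three exonic bases in exons 8 and 9", {
  fam <- shared_family()
  acc <- fam$models[["CYP2D50-1"]]
  don <- fam$models[["CYP2D50-2"]]
  ex_diffs <- function(i) {
    a <- substring(acc$sequence, acc$exons$start[i], acc$exons$end[i])
    b <- substring(don$sequence, don$exons$start[i], don$exons$end[i])
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  expect_equal(ex_diffs(8), 2)
  expect_equal(ex_diffs(9), 1)
})

test_that("realized family identities stay within one point of their targets", {
  fam <- shared_family()
  realized <- gene_identity_matrix(fam)
  target <- fam$config$target_identity
  expect_true(all(abs(realized - target[rownames(realized), colnames(realized)]) <= 1.0))
  expect_gte(realized["CYP2D50-1", "CYP2D50-2"], 92.7)
  expect_lte(realized["CYP2D50-1", "CYP2D50-2"], 94.7)
})

test_that("wild-type spliced CDSs translate without internal stops", {
  fam <- shared_family()
  for (m in fam$models) {
    aa <- translate_cds(splice_cds(m)$cds)
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("an infeasible identity matrix is rejected", {
  # targets so close to 100 that the focal pair cannot carry its planted sites
  tgt <- default_family_identity()
  tgt[] <- 99.9
  diag(tgt) <- 100
  expect_error(
    simulate_family(family_config(target_identity = tgt, seed = 1)),
    "infeasible"
  )
})

test_that("exact-count planting realizes allele counts exactly", {
  fam <- shared_family()
  co <- shared_cohort()
  truth <- co$truth$calls
  planted <- co$truth$planted_variants
  for (i in seq_len(nrow(planted))) {
    v <- planted[i, ]
    if (v$alt == "del") next
    rows <- truth[truth$gene == v$gene & truth$g_pos == v$g_pos &
      truth$alt == substr(v$alt, 1, 1), ]
    n_alleles <- sum(rows$zygosity == "HET") + 2 * sum(rows$zygosity == "MUT")
    expected <- v$allele_count
    # hybrid haplotypes also carry the donor base at diagnostic positions
    if (v$g_pos == 4240) expected <- expected + sum(co$truth$hybrids$n_hybrid_alleles)
    expect_equal(n_alleles, expected, info = paste("g.", v$g_pos))
  }
})

test_that("a single planted allele among 72 samples appears as one heterozygote", {
  co <- shared_cohort()
  truth <- co$truth$calls
  g45e <- truth[truth$g_pos == 134, ]
  expect_equal(nrow(g45e), 1)
  expect_equal(g45e$zygosity, "HET")
})

test_that("42 hybrid alleles are planted across 144 haplotypes", {
  co <- shared_cohort()
  expect_equal(sum(co$truth$hybrids$n_hybrid_alleles), 42)
  expect_equal(nrow(co$truth$hybrids), 72)
})

test_that("the Sanger consensus uses IUPAC codes at heterozygous positions", {
  expect_equal(simulate_sanger_consensus("ACGT", "ACGT"), "ACGT")
  expect_equal(simulate_sanger_consensus("ACCT", "ATCT"), "AYCT")
  expect_error(simulate_sanger_consensus("ACG", "ACGT"), "length")
})

test_that("transcript simulation respects the expressed set and copy counts", {
  fam <- shared_family()
  expect_length(simulate_transcripts(fam, character(0)), 0)
  six <- c(
    "CYP2D50-1", "CYP2D50-2", "CYP2D84", "CYP2D86", "CYP2D82",
    "CYP2D14-LOC100070905"
  )
  tx <- simulate_transcripts(fam, six, copy_counts = c(2, 1, 1, 1, 1, 1))
  expect_length(tx, 7)
  expect_equal(length(unique(sub("\\|.*", "", names(tx)))), 6)
  expect_error(simulate_transcripts(fam, "NOPE"), "unknown locus")
})

test_that("qPCR standard curves have the analytic slope at full efficiency", {
  q <- simulate_qpcr(qpcr_spec(efficiency = 1, ct_noise_sd = 0, seed = 1))
  st <- q$standards[q$standards$assay == "ACTB", ]
  fitc <- fit_standard_curve(st)
  expect_equal(abs(fitc$slope), 1 / log10(2), tolerance = 1e-9)
  expect_equal(fitc$efficiency, 1, tolerance = 1e-9)
})

test_that("noisy qPCR simulations recover the planted ratio on average", {
  ratios <- vapply(1:100, function(s) {
    q <- simulate_qpcr(qpcr_spec(ct_noise_sd = 0.2, seed = s))
    quantify_relative_expression(q)$fold_change
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 7.5) / 7.5, 0.05)
})
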