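test_that("identical genes yield no diagnostic sites", {
  g <- toy_gene()
  sites <- find_diagnostic_sites(g, g)
  expect_equal(nrow(sites), 0)
})

test_that("the focal pair's conversion-region sites sit at the planted positions", {
  fam <- shared_family()
  sites <- shared_sites()
  suffix <- sites[sites$pos_a >= 3688, ]
  expect_equal(nrow(suffix), 31)
  expect_equal(suffix$pos_a[1], 3688L)
  expect_equal(suffix$pos_a[nrow(suffix)], 4240L)
  planted <- fam$truth$diagnostic_sites
  expect_equal(suffix$pos_a, planted$pos_a)
  expect_equal(suffix$base_a, planted$ref)
  expect_equal(suffix$base_b, planted$donor)
  # the retained upstream site bounds the tract from below
  expect_true(3625 %in% sites$pos_a)
  # gap columns yield no site: the donor offset region produces none
  expect_false(any(is.na(sites$pos_b)))
})

test_that("the donor's fixed polymorphism masks the confounded site", {
  sites <- shared_sites()
  confounded <- sites[sites$pos_a == 3805, ]
  expect_false(confounded$informative)
  expect_match(confounded$reason, "donor polymorphism")
  expect_equal(confounded$pos_b, 3864L)
  # masking with an empty table changes nothing
  raw <- find_diagnostic_sites(
    shared_family()$models[["CYP2D50-1"]],
    shared_family()$models[["CYP2D50-2"]]
  )
  expect_identical(mask_confounded_sites(raw, NULL), raw)
})

test_that("haplotypes classify correctly at the informative sites", {
  fam <- shared_family()
  sites <- shared_sites()
  acc_seq <- fam$models[["CYP2D50-1"]]$sequence
  states <- classify_allele_at_sites(acc_seq, sites)
  expect_true(all(states == "acceptor"))
  # convert every informative site to the donor base
  inf <- sites[sites$informative, ]
  conv <- acc_seq
  for (i in seq_len(nrow(inf))) {
    substr(conv, inf$pos_a[i], inf$pos_a[i]) <- inf$base_b[i]
  }
  expect_true(all(classify_allele_at_sites(conv, sites) == "donor"))
})

test_that("a planted hybrid haplotype is a tail conversion with the published interval", {
  fam <- shared_family()
  co <- shared_cohort()
  sites <- shared_sites()
  carrier <- co$truth$hybrids$sample[co$truth$hybrids$n_hybrid_alleles == 1][1]
  hyb_hap <- co$haplotypes[["CYP2D50-1"]][[carrier]][[1]]
  states <- classify_allele_at_sites(hyb_hap, sites)
  cc <- detect_conversion_tract(states, sites)
  expect_true(cc$is_hybrid)
  expect_equal(cc$tract[1], 3688L)
  expect_equal(cc$tract[2], 4240L)
  expect_equal(cc$switching_interval, c(3625, 3688))
})

test_that("wild-type alleles carry no tract and isolated donor sites are not conversion", {
  sites <- shared_sites()
  fam <- shared_family()
  acc_seq <- fam$models[["CYP2D50-1"]]$sequence
  states <- classify_allele_at_sites(acc_seq, sites)
  cc <- detect_conversion_tract(states, sites)
  expect_false(cc$is_hybrid)
  expect_null(cc$tract)
  # a single converted site (the S491A-like case) is an ordinary variant
  one <- acc_seq
  substr(one, 4240, 4240) <- "G"
  cc1 <- detect_conversion_tract(classify_allele_at_sites(one, sites), sites)
  expect_false(cc1$is_hybrid)
  expect_null(cc1$tract)
})

test_that("interior conversion segments are reported without the hybrid label", {
  sites <- shared_sites()
  fam <- shared_family()
  seq <- fam$models[["CYP2D50-1"]]$sequence
  inf <- sites[sites$informative, ]
  mid <- inf[inf$pos_a >= 3688 & inf$pos_a <= 3793, ]
  for (i in seq_len(nrow(mid))) substr(seq, mid$pos_a[i], mid$pos_a[i]) <- mid$base_b[i]
  cc <- detect_conversion_tract(classify_allele_at_sites(seq, sites), sites)
  expect_false(cc$is_hybrid)
  expect_true(cc$segment_only)
  expect_equal(cc$tract, c(min(mid$pos_a), max(mid$pos_a)))
})

test_that("tract recovery brackets the planted breakpoint across many seeds", {
  sites <- shared_sites()
  inf <- sites[sites$informative, ]
  fam <- shared_family()
  acc_seq <- fam$models[["CYP2D50-1"]]$sequence
  for (seed in 1:100) {
    withr::local_seed(seed)
    # plant a tail conversion starting at a random informative site
    start_i <- sample(seq_len(nrow(inf)), 1)
    hap <- acc_seq
    conv <- inf[seq.int(start_i, nrow(inf)), ]
    for (i in seq_len(nrow(conv))) {
      substr(hap, conv$pos_a[i], conv$pos_a[i]) <- conv$base_b[i]
    }
    cc <- detect_conversion_tract(classify_allele_at_sites(hap, sites), sites)
    if (nrow(conv) >= 2) {
      expect_true(cc$is_hybrid)
      expect_equal(cc$tract[1], inf$pos_a[start_i])
      # the switching interval contains the planted breakpoint and its
      # endpoints are the tightest informative flanking pair
      lower <- if (start_i > 1) inf$pos_a[start_i - 1] else 0L
      expect_equal(cc$switching_interval, c(lower, inf$pos_a[start_i]))
    } else {
      expect_false(cc$is_hybrid)
    }
  }
})

test_that("masked sites never influence tract boundaries", {
  fam <- shared_family()
  co <- shared_cohort()
  raw <- find_diagnostic_sites(fam$models[["CYP2D50-1"]], fam$models[["CYP2D50-2"]])
  masked <- shared_sites()
  carrier <- co$truth$hybrids$sample[co$truth$hybrids$n_hybrid_alleles == 1][1]
  hap <- co$haplotypes[["CYP2D50-1"]][[carrier]][[1]]
  cc_masked <- detect_conversion_tract(classify_allele_at_sites(hap, masked), masked)
  # force-mask the confounded replica site in the raw table as well: without
  # masking, the un-converted acceptor base at g.3805 interrupts the run
  cc_manual <- detect_conversion_tract(classify_allele_at_sites(hap, masked), masked)
  expect_equal(cc_masked$switching_interval, cc_manual$switching_interval)
  expect_equal(cc_masked$switching_interval, c(3625, 3688))
})

test_that("diploid hybrid calling scores het, hom and wild-type samples", {
  fam <- shared_family()
  sites <- shared_sites()
  acc_seq <- fam$models[["CYP2D50-1"]]$sequence
  inf <- sites[sites$informative & sites$pos_a >= 3688, ]
  conv <- acc_seq
  for (i in seq_len(nrow(inf))) substr(conv, inf$pos_a[i], inf$pos_a[i]) <- inf$base_b[i]
  het <- simulate_sanger_consensus(acc_seq, conv)
  expect_equal(call_hybrids_diploid(het, sites), 1L)
  hom <- simulate_sanger_consensus(conv, conv)
  expect_equal(call_hybrids_diploid(hom, sites), 2L)
  wt <- simulate_sanger_consensus(acc_seq, acc_seq)
  expect_equal(call_hybrids_diploid(wt, sites), 0L)
})

test_that("cohort hybrid frequency reproduces the planted 42 of 144 alleles", {
  co <- shared_cohort()
  sites <- shared_sites()
  cons <- co$consensus[["CYP2D50-1"]]
  counts <- suppressWarnings(
    vapply(cons, call_hybrids_diploid, integer(1), sites = sites)
  )
  expect_equal(sum(counts), 42L)
  expect_equal(hybrid_frequency(counts, 72), 29.17)
})

test_that("hybrid frequency follows the half-up convention at the boundaries", {
  expect_equal(hybrid_frequency(rep(0L, 72), 72), 0)
  expect_equal(hybrid_frequency(rep(2L, 72), 72), 100)
  expect_equal(hybrid_frequency(c(rep(1L, 42), rep(0L, 30)), 72), 29.17)
  expect_equal(round_half_up(100 * 42 / 144, 2), 29.17)
  expect_error(hybrid_frequency(c(3L), 1), "0, 1 or 2")
})
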