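test_that("threshold classification reproduces the canonical verdicts", {
  rows <- data.frame(
    aa_change = c("R31H", "R126G", "T486I"),
    provean = c(-3.134, -2.807, 2.112),
    sift = c(0.05, 0.20, 0.36)
  )
  out <- classify_deleterious(rows)
  expect_equal(out$category, c("deleterious_both", "provean_only", "tolerated"))
})

test_that("the SIFT boundary is inclusive and the PROVEAN boundary strict", {
  rows <- data.frame(provean = c(-2.5, -2.501, -2.428), sift = c(0.05, 0.06, 0.04))
  out <- classify_deleterious(rows)
  expect_equal(out$provean_deleterious, c(FALSE, TRUE, FALSE))
  expect_equal(out$sift_deleterious, c(TRUE, FALSE, TRUE))
})

test_that("classification reproduces the published flag partition row for row", {
  scores <- read_effect_scores()
  scored <- scores[!is.na(scores$provean), ]
  expect_equal(nrow(scored), 33) # 10 + 24 rows minus the unscored frameshift
  out <- classify_deleterious(scored)
  expect_equal(out$provean_deleterious, scored$provean_flagged)
  expect_equal(out$sift_deleterious, scored$sift_flagged)
})

test_that("novel clearly-deleterious counts are 2 and 1 for the two genes", {
  scores <- read_effect_scores()
  novel_501 <- scores[scores$gene == "CYP2D50-1" & scores$rs_id == "novel", ]
  out1 <- classify_deleterious(novel_501)
  expect_equal(count_novel_deleterious(out1), 2L)
  expect_setequal(
    out1$aa_change[out1$category == "deleterious_both"],
    c("R31H", "G45E")
  )
  # the six single-substitution novel rows of the second gene
  novel_82 <- scores[scores$gene == "CYP2D82" & scores$rs_id == "novel" &
    scores$aa_change %in% c("R126G", "Y127S", "L233F", "V239L", "A240V", "L258V"), ]
  out2 <- classify_deleterious(novel_82)
  expect_equal(count_novel_deleterious(out2), 1L)
  expect_equal(out2$aa_change[out2$category == "deleterious_both"], "L233F")
  expect_equal(count_novel_deleterious(classify_deleterious(scores[0, ])), 0L)
})

test_that("rows without scores are skipped with a warning", {
  scores <- read_effect_scores()
  expect_warning(out <- classify_deleterious(scores), "skipped")
  expect_equal(nrow(out), 33)
})

test_that("standard-curve fits recover slope, efficiency and the exact 2-point line", {
  # ct = 38 + slope * log10(q) with slope = -1/log10(2)
  slope <- -1 / log10(2)
  pts <- data.frame(quantity = 10^(5:0), ct = 38 + slope * (5:0))
  fitc <- fit_standard_curve(pts)
  expect_equal(fitc$slope, slope, tolerance = 1e-4)
  expect_equal(fitc$efficiency, 1, tolerance = 1e-6)
  expect_equal(fitc$r_squared, 1, tolerance = 1e-12)
  two <- fit_standard_curve(data.frame(quantity = c(10, 1000), ct = c(30, 24)))
  expect_equal(two$slope, -3)
  expect_equal(two$intercept, 33)
  expect_error(fit_standard_curve(data.frame(quantity = c(5, 5), ct = c(1, 2))), "degenerate")
  expect_error(fit_standard_curve(data.frame(quantity = c(-1, 5), ct = c(1, 2))), "positive")
})

test_that("a noise-free plate with planted efficiency 0.9 is recovered exactly", {
  q <- simulate_qpcr(qpcr_spec(efficiency = 0.9, ct_noise_sd = 0, seed = 2))
  st <- q$standards[q$standards$assay == "CYP2D50-1", ]
  fitc <- fit_standard_curve(st)
  expect_equal(fitc$efficiency, 0.9, tolerance = 1e-6)
})

test_that("the noise-free pipeline recovers the planted 7.5-fold ratio", {
  q <- simulate_qpcr(qpcr_spec(true_ratio = 7.5, ct_noise_sd = 0, seed = 1))
  res <- quantify_relative_expression(q)
  expect_equal(res$fold_change, 7.5, tolerance = 1e-9)
})

test_that("identical groups give fold change 1 and the ratio is scale invariant", {
  q <- simulate_qpcr(qpcr_spec(true_ratio = 1, ct_noise_sd = 0, seed = 4))
  expect_equal(quantify_relative_expression(q)$fold_change, 1, tolerance = 1e-9)
  # rescaling all standard quantities by a constant leaves the ratio unchanged
  q2 <- simulate_qpcr(qpcr_spec(true_ratio = 7.5, ct_noise_sd = 0, seed = 4))
  q3 <- q2
  q3$standards$quantity <- q3$standards$quantity * 1000
  expect_equal(
    quantify_relative_expression(q3)$fold_change,
    quantify_relative_expression(q2)$fold_change,
    tolerance = 1e-9
  )
})

test_that("normalization rescaling cancels in the fold change", {
  withr::local_seed(6)
  t1 <- runif(4, 1, 10)
  t2 <- runif(4, 1, 10)
  ref <- runif(4, 1, 10)
  fc <- fold_change(normalized_expression(t1, ref), normalized_expression(t2, ref))
  fc_scaled <- fold_change(
    normalized_expression(t1, ref * 7), normalized_expression(t2, ref * 7)
  )
  expect_equal(fc, fc_scaled)
})

test_that("the Welch test matches the closed-form hand computation", {
  w <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  # hand computation: means 2 and 3, variances 1 and 1, n = 3
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (2 - 3) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)
  expect_equal(w$p, 2 * pt(t_hand, df_hand))
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
})

test_that("the Welch test agrees with the reference implementation on random inputs", {
  withr::local_seed(7)
  for (rep in 1:25) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    w <- welch_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance groups follow the stated conventions", {
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t_test(c(3, 3), c(2, 2))$p, 0)
})
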