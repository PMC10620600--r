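#' Classify variant effects from SIFT and PROVEAN scores
#'
#' Scores are inputs (the prediction tools themselves are never run here);
#' only the threshold rules are applied. SIFT calls a substitution
#' deleterious at scores less than or equal to the cutoff — the boundary is
#' inclusive because published classifications flag substitutions scoring
#' exactly 0.05 — while PROVEAN uses a strict less-than at its default
#' -2.5 (scores of -2.428 or -2.281 are not flagged). A variant is
#' "clearly deleterious" when both tools agree.
#'
#' @param rows data frame with columns `provean` and `sift` (plus any
#'   identifying columns, carried through). Rows with a missing score are
#'   skipped with a warning.
#' @param sift_cutoff inclusive SIFT threshold (default 0.05).
#' @param provean_cutoff exclusive PROVEAN threshold (default -2.5).
#' @return input with added logical columns `sift_deleterious`,
#'   `provean_deleterious` and a `category` column over
#'   `deleterious_both` / `provean_only` / `sift_only` / `tolerated`.
#' @export
classify_deleterious <- function(rows, sift_cutoff = 0.05, provean_cutoff = -2.5) {
  keep <- !is.na(rows$provean) & !is.na(rows$sift)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) without scores skipped")
    rows <- rows[keep, , drop = FALSE]
  }
  if (any(rows$sift < 0 | rows$sift > 1)) stop("SIFT scores must lie in [0, 1]")
  s <- rows$sift <= sift_cutoff
  p <- rows$provean < provean_cutoff
  rows$sift_deleterious <- s
  rows$provean_deleterious <- p
  rows$category <- ifelse(s & p, "deleterious_both",
    ifelse(p, "provean_only", ifelse(s, "sift_only", "tolerated"))
  )
  rows
}

#' Count novel variants deleterious under both tools
#'
#' @param rows output of [classify_deleterious()] with an `rs_id` column
#'   (`"novel"` or empty marking unannotated variants).
#' @return integer count of novel `deleterious_both` rows.
#' @export
count_novel_deleterious <- function(rows) {
  if (nrow(rows) == 0L) {
    return(0L)
  }
  novel <- is.na(rows$rs_id) | rows$rs_id %in% c("", "novel")
  sum(novel & rows$category == "deleterious_both")
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = intercept + slope * log10(quantity)`;
#' amplification efficiency is `10^(-1/slope) - 1` (a perfectly efficient
#' assay doubles per cycle: slope -3.3219, efficiency 1).
#'
#' @param points data frame with columns `quantity` (positive) and `ct`.
#' @return list with `slope`, `intercept`, `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(points) {
  if (any(points$quantity <= 0)) stop("standard-curve quantities must be positive")
  if (length(unique(points$quantity)) < 2L) {
    stop("degenerate fit: need at least 2 distinct quantities")
  }
  x <- log10(points$quantity)
  fit <- stats::lm(ct ~ x, data = data.frame(ct = points$ct, x = x))
  co <- stats::coef(fit)
  ss_tot <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(
    slope = unname(co[2]), intercept = unname(co[1]),
    r_squared = r2, efficiency = 10^(-1 / unname(co[2])) - 1
  )
}

#' Interpolate a template quantity from a Ct value
#'
#' @param ct observed threshold cycle(s).
#' @param curve a [fit_standard_curve()] result.
#' @param warn_extrapolate warn when `ct` falls outside the fitted range
#'   implied by the curve points (supply `range_ct` to enable).
#' @param range_ct optional numeric range of standard-curve Cts.
#' @return quantity `10^((ct - intercept) / slope)`.
#' @export
relative_quantity <- function(ct, curve, warn_extrapolate = TRUE, range_ct = NULL) {
  if (curve$slope == 0) stop("zero slope: cannot invert standard curve")
  if (warn_extrapolate && !is.null(range_ct) &&
    any(ct < min(range_ct) - 1 | ct > max(range_ct) + 1)) {
    warning("Ct outside standard-curve range; extrapolating")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Reference-normalized expression and fold change
#'
#' `normalized_expression` divides each sample's target quantity by its
#' reference-gene quantity; `fold_change` is the ratio of group means of
#' normalized quantities (ratio of means, not mean of ratios — the stable
#' choice at n = 4).
#'
#' @param target_quantity,reference_quantity per-sample interpolated
#'   quantities.
#' @return numeric vector of normalized expressions.
#' @export
normalized_expression <- function(target_quantity, reference_quantity) {
  if (any(reference_quantity <= 0)) stop("non-positive reference quantity")
  target_quantity / reference_quantity
}

#' @rdname normalized_expression
#' @param group_a,group_b normalized expression vectors of the two targets.
#' @return `fold_change`: `mean(group_a) / mean(group_b)`.
#' @export
fold_change <- function(group_a, group_b) {
  mean(group_a) / mean(group_b)
}

#' Welch's unequal-variance t test
#'
#' The Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p value. Implemented from the closed form so it can be
#' cross-checked against an independent reference implementation.
#'
#' @param group_a,group_b numeric vectors (length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("need at least 2 values per group")
  va <- stats::var(group_a) / na
  vb <- stats::var(group_b) / nb
  if (va + vb == 0) {
    d <- mean(group_a) - mean(group_b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = na + nb - 2, p = if (d == 0) 1 else 0))
  }
  t <- (mean(group_a) - mean(group_b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Relative standard curve quantification of two targets
#'
#' Full workflow over simulated or imported plates: fit one standard curve
#' per assay, interpolate per-sample quantities, normalize both targets by
#' the reference gene, and report the fold change of target 1 over
#' target 2 with Welch's t test on the normalized groups.
#'
#' @param plates list with `standards` (assay, quantity, ct) and `samples`
#'   (sample, assay, ct), as from [simulate_qpcr()].
#' @param target1,target2,reference assay names.
#' @return list with `fold_change`, `welch` (t/df/p), `curves`,
#'   `normalized` (per-sample normalized quantities per target).
#' @export
quantify_relative_expression <- function(plates,
                                         target1 = "CYP2D50-1",
                                         target2 = "CYP2D50-2",
                                         reference = "ACTB") {
  st <- plates$standards
  sm <- plates$samples
  curves <- lapply(
    stats::setNames(c(target1, target2, reference), c(target1, target2, reference)),
    function(a) fit_standard_curve(st[st$assay == a, , drop = FALSE])
  )
  qty <- function(a) {
    rows <- sm[sm$assay == a, , drop = FALSE]
    stats::setNames(
      relative_quantity(rows$ct, curves[[a]], warn_extrapolate = FALSE),
      rows$sample
    )
  }
  q1 <- qty(target1)
  q2 <- qty(target2)
  qr <- qty(reference)
  samples <- names(qr)
  n1 <- normalized_expression(q1[samples], qr[samples])
  n2 <- normalized_expression(q2[samples], qr[samples])
  list(
    fold_change = fold_change(n1, n2),
    welch = welch_t_test(n1, n2),
    curves = curves,
    normalized = data.frame(
      sample = samples, target1 = unname(n1), target2 = unname(n2)
    )
  )
}
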