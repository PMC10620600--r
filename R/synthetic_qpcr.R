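#' Specification for the qPCR plate simulator
#'
#' Emulates a relative-standard-curve experiment: per-assay 10-fold
#' dilution series plus per-sample Ct values for two target transcripts and
#' a reference gene (actin), constructed so that the reference-normalized
#' ratio of target means equals a planted value.
#'
#' @param true_ratio fold difference between target 1 and target 2 after
#'   reference-gene normalization (the published result is 7.5).
#' @param dilution_points number of standard-curve points per assay.
#' @param dilution_step fold dilution between successive points.
#' @param efficiency amplification efficiency in (0, 1]; 1 doubles the
#'   template every cycle, giving a standard-curve slope of
#'   -1/log10(2) = -3.3219. Scalar or named per-assay vector.
#' @param ct_noise_sd standard deviation of additive Gaussian Ct noise.
#' @param n_samples number of biological samples per target (default 4).
#' @param seed integer seed.
#' @return a `qpcr_spec` list.
#' @export
qpcr_spec <- function(true_ratio = 7.5, dilution_points = 6L, dilution_step = 10,
                      efficiency = 1.0, ct_noise_sd = 0, n_samples = 4L, seed = 1L) {
  if (any(efficiency <= 0) || any(efficiency > 1)) stop("efficiency must lie in (0, 1]")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be non-negative")
  if (true_ratio <= 0) stop("true_ratio must be positive")
  if (dilution_points < 2L) stop("need at least 2 standard-curve points")
  structure(
    list(
      true_ratio = true_ratio,
      dilution_points = as.integer(dilution_points),
      dilution_step = dilution_step,
      efficiency = efficiency,
      ct_noise_sd = ct_noise_sd,
      n_samples = as.integer(n_samples),
      seed = as.integer(seed)
    ),
    class = "qpcr_spec"
  )
}

QPCR_ASSAYS <- c(target1 = "CYP2D50-1", target2 = "CYP2D50-2", reference = "ACTB")

#' Simulate relative-standard-curve qPCR plates
#'
#' Ct values follow the standard-curve model
#' `Ct = intercept + slope * log10(quantity)` with
#' `slope = -1 / log10(1 + efficiency)`, plus optional Gaussian noise.
#' Per-sample template quantities are drawn so that the actin-normalized
#' ratio of target-1 to target-2 group means equals `true_ratio` exactly in
#' the noise-free construction.
#'
#' @param spec a [qpcr_spec()].
#' @return list with `standards` (assay, quantity, ct), `samples`
#'   (sample, assay, ct) and `truth` (planted quantities, curve parameters,
#'   ratio).
#' @export
simulate_qpcr <- function(spec = qpcr_spec()) {
  stopifnot(inherits(spec, "qpcr_spec"))
  set.seed(spec$seed)
  assays <- unname(QPCR_ASSAYS)
  eff <- spec$efficiency
  if (length(eff) == 1L) eff <- stats::setNames(rep(eff, 3L), assays)
  if (is.null(names(eff))) names(eff) <- assays
  slope <- -1 / log10(1 + eff[assays])
  intercept <- stats::setNames(c(38, 38, 34), assays)

  quantities <- spec$dilution_step^((spec$dilution_points - 1L):0) * 10
  standards <- do.call(rbind, lapply(assays, function(a) {
    data.frame(
      assay = a, quantity = quantities,
      ct = intercept[a] + slope[a] * log10(quantities) +
        stats::rnorm(length(quantities), 0, spec$ct_noise_sd),
      stringsAsFactors = FALSE
    )
  }))
  rownames(standards) <- NULL

  n <- spec$n_samples
  ref_q <- stats::runif(n, 20, 200)
  t2_q <- stats::runif(n, 5, 50) * ref_q / stats::median(ref_q)
  t1_q <- spec$true_ratio * t2_q
  q <- rbind(t1_q, t2_q, ref_q)
  rownames(q) <- assays
  samples <- do.call(rbind, lapply(seq_len(n), function(s) {
    data.frame(
      sample = sprintf("H%d", s),
      assay = assays,
      ct = intercept[assays] + slope[assays] * log10(q[, s]) +
        stats::rnorm(3L, 0, spec$ct_noise_sd),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL

  list(
    standards = standards,
    samples = samples,
    truth = list(
      quantities = q,
      slope = slope,
      intercept = intercept,
      true_ratio = spec$true_ratio,
      spec = spec
    )
  )
}
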