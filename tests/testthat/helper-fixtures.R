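# Shared heavyweight fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

shared_family <- function() {
  if (is.null(.fixtures$family)) {
    .fixtures$family <- simulate_family(family_config(seed = 101))
  }
  .fixtures$family
}

shared_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(shared_family(), cohort_spec(seed = 202))
  }
  .fixtures$cohort
}

shared_sites <- function() {
  if (is.null(.fixtures$sites)) {
    fam <- shared_family()
    s <- find_diagnostic_sites(
      fam$models[["CYP2D50-1"]], fam$models[["CYP2D50-2"]]
    )
    .fixtures$sites <- mask_confounded_sites(s, fam$truth$donor_variants)
  }
  .fixtures$sites
}

shared_cyp2d82 <- function() {
  if (is.null(.fixtures$g82)) .fixtures$g82 <- simulate_cyp2d82_model(seed = 55)
  .fixtures$g82
}

# a minimal single-exon gene: ATG + payload codons + stop
toy_gene <- function(payload = "AAACCC", name = "TOY") {
  seq <- paste0("ATG", payload, "TAA")
  gene_model(name, seq, data.frame(index = 1L, start = 1L, end = nchar(seq)))
}
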