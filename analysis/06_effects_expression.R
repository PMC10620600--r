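#!/usr/bin/env Rscript
# Classify variant effects from the published SIFT/PROVEAN scores and
# quantify relative expression of the two focal transcripts by the
# relative standard curve method with Welch's t test.

suppressPackageStartupMessages(library(paralocus))
seed <- 101L
out <- "results"
dir.create(out, showWarnings = FALSE)

scores <- read_effect_scores()
verdicts <- suppressWarnings(classify_deleterious(scores))
write.table(verdicts, file.path(out, "effect_verdicts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("effect classification over", nrow(verdicts), "scored substitutions:\n")
print(table(verdicts$gene, verdicts$category))

novel_501 <- verdicts[verdicts$gene == "CYP2D50-1" & verdicts$rs_id == "novel", ]
six_82 <- c("R126G", "Y127S", "L233F", "V239L", "A240V", "L258V")
novel_82 <- verdicts[verdicts$gene == "CYP2D82" & verdicts$rs_id == "novel" &
                       verdicts$aa_change %in% six_82, ]
cat(
  "novel clearly-deleterious (both tools): CYP2D50-1 =",
  count_novel_deleterious(novel_501),
  paste0("(", paste(novel_501$aa_change[novel_501$category == "deleterious_both"], collapse = ", "), ");"),
  "CYP2D82 =", count_novel_deleterious(novel_82),
  paste0("(", paste(novel_82$aa_change[novel_82$category == "deleterious_both"], collapse = ", "), ")\n")
)

# expression: noise-free recovery plus a noisy replicate at realistic Ct noise
plates <- simulate_qpcr(qpcr_spec(true_ratio = 7.5, ct_noise_sd = 0, seed = seed))
clean <- quantify_relative_expression(plates)
noisy <- quantify_relative_expression(
  simulate_qpcr(qpcr_spec(true_ratio = 7.5, ct_noise_sd = 0.2, seed = seed))
)
cat(sprintf(
  "fold change (noise-free): %.4f; with Ct noise sd 0.2: %.3f (Welch p = %.4f)\n",
  clean$fold_change, noisy$fold_change, noisy$welch$p
))
write.table(
  data.frame(
    condition = c("noise_free", "ct_noise_0.2"),
    fold_change = c(clean$fold_change, noisy$fold_change),
    welch_t = c(clean$welch$t, noisy$welch$t),
    welch_df = c(clean$welch$df, noisy$welch$df),
    welch_p = c(clean$welch$p, noisy$welch$p)
  ),
  file.path(out, "expression_summary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
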