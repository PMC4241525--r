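#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the three data sets the downstream stages consume: a
# 148-condition expression compendium with 30 planted RBP regulons
# (variance-damped, plus an undamped contrast), and a paired wild-type /
# deletion-strain experiment with expression-biased decay. Everything is
# seeded; rerunning reproduces the files byte for byte.

suppressPackageStartupMessages(library(rbpregulon))

seed <- 1
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

co <- planted_coexpression_fixture(coexpression_scenario(seed = seed))
write_expression_matrix(co$expression, file.path(out, "compendium_expression.tsv"))
write_target_map(co$targets, file.path(out, "compendium_targets.tsv"))
write.table(co$truth, file.path(out, "compendium_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

co0 <- planted_coexpression_fixture(
  coexpression_scenario(damping_strength = 0, seed = seed))
write_expression_matrix(co0$expression, file.path(out, "undamped_expression.tsv"))
write_target_map(co0$targets, file.path(out, "undamped_targets.tsv"))
write.table(co0$truth, file.path(out, "undamped_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ko <- planted_knockout_fixture(knockout_scenario(seed = seed))
ids <- ko$pair$gene_ids
write_expression_matrix(
  expression_matrix(matrix(ko$pair$wt_expr, ncol = 1, dimnames = list(ids, "WT"))),
  file.path(out, "knockout_wt.tsv"))
write_expression_matrix(
  expression_matrix(matrix(ko$pair$ko_expr, ncol = 1, dimnames = list(ids, "KO"))),
  file.path(out, "knockout_ko.tsv"))
writeLines(ko$pair$target_ids, file.path(out, "knockout_targets.txt"))
write.table(ko$truth, file.path(out, "knockout_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("compendium: %d genes x %d conditions, %d regulons of %d targets\n",
            nrow(co$expression$values), ncol(co$expression$values),
            nrow(co$truth), co$scenario$n_targets_per_rbp))
cat(sprintf("knockout: %d genes, %d targets, mean planted efficiency %.2f\n",
            length(ids), length(ko$pair$target_ids), mean(ko$truth$efficiency)))
cat("fixtures written to", out, "\n")
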