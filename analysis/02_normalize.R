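#!/usr/bin/env Rscript
# Step 2: filter and normalize the expression table.
#
# Keeps protein-coding genes detected (FPKM > 0) in every sample, selects
# the target-free housekeeping normalization set H, and median-matches all
# samples in log2 space so that each sample's median over H equals a
# common value.  Writes the normalized matrix, the normalization report
# and the H gene list under results/.

suppressPackageStartupMessages(library(mirderep))

indir <- "results/simulated"
expr <- read_expression(file.path(indir, "expression.tsv"),
                        file.path(indir, "samples.tsv"))
ann <- read_target_annotation(file.path(indir, "target_pairs.tsv"),
                              file.path(indir, "housekeeping.txt"),
                              file.path(indir, "biotype.tsv"))

filtered <- filter_genes(expr, ann)
message(sprintf("filter: %d of %d genes are protein-coding and detected in all samples",
                nrow(filtered$values), nrow(expr$values)))

H <- select_normalization_genes(ann, filtered)
message(sprintf("normalization set: %d target-free housekeeping genes", length(H)))

nm <- normalize_expression(filtered, H)
message(sprintf("median matching: common value %.3f log2; offsets %s",
                nm$common_value,
                paste(sprintf("%+.2f", nm$offsets), collapse = " ")))

write_normalized(nm, "results/normalized_expression.tsv",
                 "results/normalization_report.tsv")
writeLines(H, "results/normalization_genes.txt")
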