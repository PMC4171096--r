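#!/usr/bin/env Rscript
# Step 1: generate the synthetic knockout-versus-control study.
#
# The generator emulates a bulk RNA-seq comparison of miRNA-pathway
# knockout and control germ-cell libraries (3 + 3 replicates, ~5,000
# detected protein-coding genes): miRNA targets are derepressed in the
# knockout in proportion to the summed mean-relative abundance of their
# targeting miRNAs (coefficient 0.3 log2 units), replicate noise is 0.25
# log2 units, and each library carries its own multiplicative size factor.
# Writes all pipeline inputs plus the ground truth to results/simulated/.

suppressPackageStartupMessages(library(mirderep))

seed <- 101
outdir <- "results/simulated"

sim <- simulate_transcriptome(simulation_config(seed = seed))
write_simulation(sim, outdir)

message(sprintf("simulated %d genes x %d samples into %s",
                nrow(sim$expression$values), ncol(sim$expression$values),
                outdir))
message(sprintf("  %d genes carry predicted target sites; %d target-free housekeeping genes",
                sum(lengths(sim$truth$targets) > 0),
                length(sim$truth$normalization_genes)))
message(sprintf("  true derepression: median %.3f log2 among targeted genes, max %.2f",
                median(sim$truth$delta_true[sim$truth$delta_true > 0]),
                max(sim$truth$delta_true)))
message(sprintf("  library factors span %.2fx-%.2fx",
                min(sim$truth$library_factors),
                max(sim$truth$library_factors)))
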