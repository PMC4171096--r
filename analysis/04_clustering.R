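#!/usr/bin/env Rscript
# Step 4: sample clustering on Spearman correlation distance.
#
# Pairwise sample distance is 1 - rho (Spearman over gene expression
# vectors); the dendrogram uses Ward linkage.  Replicates of the same
# condition should pair up, so the two-cluster cut is expected to separate
# knockout from control libraries.  Writes the distance matrix, the merge
# table and a Newick dendrogram under results/.

suppressPackageStartupMessages(library(mirderep))

nm <- read_normalized("results/normalized_expression.tsv",
                      "results/simulated/samples.tsv",
                      "results/normalization_genes.txt")
d <- sample_distances(nm)
wc <- ward_cluster(d)
purity <- cut_purity(wc, nm$samples)

message(sprintf("sample distances (1 - rho) span %.4f-%.4f",
                min(d[upper.tri(d)]), max(d[upper.tri(d)])))
message(sprintf("2-cluster cut condition purity: %.0f%%", 100 * purity))

write_clustering(wc, d, "results/sample_distances.tsv",
                 "results/ward_merges.tsv", "results/dendrogram.nwk")
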