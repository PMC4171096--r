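Package: mirderep
Title: miRNA Target Derepression Analysis for Knockout Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome-wide derepression of
    microRNA targets after genetic ablation of the miRNA pathway (e.g.
    Dicer1 knockout in pachytene spermatocytes). Normalizes FPKM expression
    tables against a set of target-free housekeeping genes by median
    matching in log2 space, computes per-gene derepression summaries and
    the associated rank statistics (paired Wilcoxon signed-rank global
    shift, Spearman correlation of expression change with predicted target
    counts, stratified Mann-Whitney comparison of targets of highly versus
    lowly expressed miRNAs), clusters samples on Spearman correlation
    distance with Ward linkage, performs hypergeometric gene-set
    overrepresentation of upregulated genes, and quantifies qPCR assays by
    the 2^-ddCt method. Includes a synthetic transcriptome generator with
    known ground truth so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ape
Config/testthat/edition: 3
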