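# Housekeeping median-matching normalization.
#
# The normalization anchor is the set H of housekeeping genes without
# predicted miRNA target sites: the genes least likely to change when the
# miRNA pathway is ablated.  Each sample's log2 FPKM column is shifted by
# a constant so that the median over H equals a common value c, which
# removes multiplicative library-size distortion exactly while preserving
# within-sample expression differences.

#' Filter to protein-coding genes detected in all samples
#'
#' Retains genes whose biotype is `protein_coding` and whose FPKM exceeds
#' `detection_threshold` in every sample; gene order is preserved.
#' "Detected" defaults to strictly positive FPKM.
#'
#' @param x An [expression_matrix()].
#' @param annotation A [gene_annotation()].
#' @param detection_threshold FPKM strictly above this counts as detected
#'   (default 0).
#' @return A filtered `expr_matrix`.
#' @export
filter_genes <- function(x, annotation, detection_threshold = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  ann <- annotation_for(annotation, rownames(x$values))
  keep <- ann$biotype == "protein_coding" &
    apply(x$values > detection_threshold, 1L, all)
  if (!any(keep))
    stop("no genes pass the protein-coding + detected-in-all-samples filter",
         call. = FALSE)
  expression_matrix(x$values[keep, , drop = FALSE], x$samples)
}

#' Select the normalization gene set H
#'
#' H is the set of genes in the (already filtered) matrix that are flagged
#' housekeeping and have no predicted miRNA target sites.  A median over a
#' tiny set is unstable, so fewer than `min_norm_genes` is an error.
#'
#' @param annotation A [gene_annotation()].
#' @param x The filtered [expression_matrix()].
#' @param min_norm_genes Minimum acceptable |H| (default 20).
#' @return Character vector of gene ids (in matrix order).
#' @export
select_normalization_genes <- function(annotation, x, min_norm_genes = 20) {
  stopifnot(inherits(x, "expr_matrix"))
  ann <- annotation_for(annotation, rownames(x$values))
  H <- ann$gene_id[ann$housekeeping & ann$n_targets == 0L]
  if (length(H) < min_norm_genes)
    stop("only ", length(H), " target-free housekeeping genes available; ",
         "need at least ", min_norm_genes, call. = FALSE)
  H
}

#' Median-match samples in log2 space against the normalization set
#'
#' Computes `raw_log2 = log2(FPKM)` and per-sample offsets
#' `o_s = c - median(raw_log2[H, s])` so that after
#' `normalized = raw_log2 + o_s` every sample's median over H equals the
#' common value `c`.  By default `c` is the mean over samples of the
#' per-sample H-medians, which keeps the output on the data's own scale;
#' a fixed constant can be supplied instead.
#'
#' @param x An [expression_matrix()]; genes in `H` must be strictly
#'   positive in every sample (guaranteed after [filter_genes()]).
#' @param norm_genes Character vector H of normalization gene ids, a
#'   subset of the matrix genes.
#' @param common_value Numeric scalar `c`, or `NULL` (default) for the
#'   mean of per-sample H-medians.
#' @return An object of class `norm_matrix`: list with `values` (log2
#'   matrix), `samples`, `norm_genes`, `offsets` (named per-sample
#'   vector), `common_value`.
#' @export
normalize_expression <- function(x, norm_genes, common_value = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(norm_genes) == 0) stop("empty normalization set", call. = FALSE)
  missing <- setdiff(norm_genes, rownames(x$values))
  if (length(missing))
    stop("normalization genes absent from matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  if (any(x$values[norm_genes, ] <= 0))
    stop("zero FPKM inside the normalization set; log2 undefined",
         call. = FALSE)
  raw_log2 <- log2(x$values)
  med <- apply(raw_log2[norm_genes, , drop = FALSE], 2L, stats::median)
  cc <- if (is.null(common_value)) mean(med) else common_value
  offsets <- cc - med
  values <- sweep(raw_log2, 2L, offsets, `+`)
  structure(list(values = values, samples = x$samples,
                 norm_genes = norm_genes, offsets = offsets,
                 common_value = cc),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf(
    "norm_matrix: %d genes x %d samples; |H| = %d, common value = %.4g\n",
    nrow(x$values), ncol(x$values), length(x$norm_genes), x$common_value))
  cat("offsets:", paste(sprintf("%s %+.3f", names(x$offsets), x$offsets),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Read a normalized log2 matrix written by [write_normalized()]
#'
#' Reconstructs a `norm_matrix` from its TSV files.  The stored values
#' are already median-matched, so the offsets of the reconstructed
#' object are zero and the common value is recomputed as the (equal)
#' per-sample medians over the normalization set.
#'
#' @param path TSV of log2 values (`gene_id` first column).
#' @param sample_sheet_path Sample sheet TSV.
#' @param norm_genes Character vector of normalization gene ids, or the
#'   path of a text file with one id per line.
#' @return A `norm_matrix`.
#' @export
read_normalized <- function(path, sample_sheet_path, norm_genes) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$gene_id)
  samples <- validate_sample_sheet(read_tsv(sample_sheet_path))
  samples <- samples[match(colnames(m), samples$sample_id), ]
  if (length(norm_genes) == 1 && file.exists(norm_genes)) {
    lines <- readLines(norm_genes, warn = FALSE)
    norm_genes <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  }
  med <- apply(m[norm_genes, , drop = FALSE], 2L, stats::median)
  structure(list(values = m, samples = samples, norm_genes = norm_genes,
                 offsets = stats::setNames(numeric(ncol(m)), colnames(m)),
                 common_value = mean(med)),
            class = "norm_matrix")
}

#' Write a normalized matrix and its normalization report
#'
#' @param x A `norm_matrix`.
#' @param path Output TSV for the log2 matrix (`gene_id` first column).
#' @param report_path Optional TSV reporting |H|, the common value and the
#'   per-sample offsets.
#' @export
write_normalized <- function(x, path, report_path = NULL) {
  stopifnot(inherits(x, "norm_matrix"))
  write_tsv(data.frame(gene_id = rownames(x$values), x$values,
                       check.names = FALSE), path)
  if (!is.null(report_path))
    write_tsv(data.frame(sample_id = names(x$offsets),
                         offset = unname(x$offsets),
                         n_norm_genes = length(x$norm_genes),
                         common_value = x$common_value), report_path)
  invisible(x)
}
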