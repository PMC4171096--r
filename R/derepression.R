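# Per-gene derepression summaries and the three headline statistics:
# the global expression shift in the knockout (paired Wilcoxon), the
# correlation of expression change with the number of targeting miRNAs
# among the most expressed ones (Spearman), and the stratified comparison
# of targets of highly versus lowly expressed miRNAs (Mann-Whitney).

#' Summarize normalized expression per gene and condition
#'
#' For each gene: the median normalized log2 FPKM across replicates of
#' each condition (`expr_ko`, `expr_ctrl`), their mean (`combined`), and
#' the expression change `delta = expr_ko - expr_ctrl` in log2 units.
#' If an annotation and a top-miRNA set are supplied, also counts each
#' gene's targeting miRNAs (`n_targets`), those within the top set
#' (`n_targets_top`), and flags genes targeted exclusively by miRNAs
#' outside the top set (`targeted_by_low_only`).  `in_H` flags genes used
#' for normalization, which downstream tests exclude to avoid circularity.
#'
#' @param norm A `norm_matrix` from [normalize_expression()].
#' @param annotation Optional [gene_annotation()].
#' @param top_mirnas Optional character vector of top-expressed miRNA ids
#'   (see [top_expressed_mirnas()]).
#' @return Data frame with one row per gene, class `gene_summary`.
#' @export
summarize_genes <- function(norm, annotation = NULL, top_mirnas = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  cond <- norm$samples$condition
  for (cn in VALID_CONDITIONS)
    if (!any(cond == cn)) stop("no samples with condition '", cn, "'",
                               call. = FALSE)
  med_by <- function(cn)
    apply(norm$values[, cond == cn, drop = FALSE], 1L, stats::median)
  expr_ko <- med_by("knockout")
  expr_ctrl <- med_by("control")
  out <- data.frame(gene_id = rownames(norm$values),
                    expr_ko = unname(expr_ko),
                    expr_ctrl = unname(expr_ctrl),
                    combined = unname((expr_ko + expr_ctrl) / 2),
                    delta = unname(expr_ko - expr_ctrl),
                    in_H = rownames(norm$values) %in% norm$norm_genes,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    ann <- annotation_for(annotation, out$gene_id)
    tg <- attr(ann, "targets")
    out$n_targets <- ann$n_targets
    if (!is.null(top_mirnas)) {
      out$n_targets_top <- vapply(tg, function(m)
        sum(m %in% top_mirnas), 0L)
      out$targeted_by_low_only <- out$n_targets > 0L &
        out$n_targets_top == 0L
    }
  }
  class(out) <- c("gene_summary", "data.frame")
  out
}

#' Global expression shift between knockout and control
#'
#' Paired two-sided Wilcoxon signed-rank test of per-gene condition
#' medians (`expr_ko` vs `expr_ctrl`), plus both medians.  Genes with
#' zero change carry no sign information and are dropped by the test.
#'
#' @param summary A `gene_summary`.
#' @param exact_limit Passed to [wilcoxon_signed_rank()].
#' @return List with `median_ko`, `median_ctrl`, `p_value`, `n_nonzero`.
#' @export
global_shift_test <- function(summary, exact_limit = 25) {
  n_nonzero <- sum(summary$delta != 0)
  if (n_nonzero > 0 && n_nonzero < 6)
    stop("need at least 6 genes with non-zero change (got ", n_nonzero,
         ")", call. = FALSE)
  wt <- wilcoxon_signed_rank(summary$expr_ko, summary$expr_ctrl,
                             exact_limit = exact_limit)
  list(median_ko = stats::median(summary$expr_ko),
       median_ctrl = stats::median(summary$expr_ctrl),
       p_value = wt$p_value, n_nonzero = wt$n)
}

#' The n most expressed miRNAs
#'
#' Ranks by expression, highest first; ties at the cutoff boundary are
#' broken by lexicographic miRNA id so the set is deterministic.
#'
#' @param mirna_table Data frame with columns `mirna_id`, `expression`.
#' @param n Size of the top set (default 100).
#' @return Character vector of `n` miRNA ids.
#' @export
top_expressed_mirnas <- function(mirna_table, n = 100) {
  stopifnot(nrow(mirna_table) >= 1, n >= 1)
  if (n > nrow(mirna_table)) {
    warning("n = ", n, " exceeds table size ", nrow(mirna_table),
            "; returning all miRNAs")
    n <- nrow(mirna_table)
  }
  ord <- order(-mirna_table$expression, mirna_table$mirna_id)
  mirna_table$mirna_id[ord[seq_len(n)]]
}

#' Correlation of expression change with top-miRNA target count
#'
#' Spearman correlation between `n_targets_top` and `delta` over all
#' genes except those used for normalization (excluded to avoid
#' circularity: their changes were forced toward zero by construction).
#' Untargeted genes are included with a target count of zero.
#'
#' @param summary A `gene_summary` with target columns (see
#'   [summarize_genes()]).
#' @param exact_limit Passed to [spearman_rho_test()].
#' @return List with `rho`, `p_value`, `n`.
#' @export
target_count_correlation <- function(summary, exact_limit = 10) {
  if (is.null(summary$n_targets_top))
    stop("summary lacks n_targets_top; rerun summarize_genes() with an ",
         "annotation and a top-miRNA set", call. = FALSE)
  s <- summary[!summary$in_H, , drop = FALSE]
  if (nrow(s) < 3)
    stop("fewer than 3 genes after excluding normalization genes",
         call. = FALSE)
  st <- spearman_rho_test(s$n_targets_top, s$delta,
                          exact_limit = exact_limit)
  list(rho = st$rho, p_value = st$p_value, n = st$n)
}

#' Compare targets of highly vs lowly expressed miRNAs
#'
#' Splits targeted genes (normalization genes excluded) into stratum HI
#' (at least one targeting miRNA in the top-expressed set) and stratum
#' LOW (targeted, but only by miRNAs outside that set); untargeted genes
#' belong to neither.  Reports each stratum's median expression change
#' and the two-sided Mann-Whitney p-value on `delta`.
#'
#' @param summary A `gene_summary` with target columns.
#' @param exact_limit Passed to [mann_whitney_u()].
#' @return List with `median_change_hi`, `median_change_low`, `n_hi`,
#'   `n_low`, `p_value`.
#' @export
stratified_target_test <- function(summary, exact_limit = 10) {
  if (is.null(summary$n_targets_top))
    stop("summary lacks n_targets_top; rerun summarize_genes() with an ",
         "annotation and a top-miRNA set", call. = FALSE)
  s <- summary[!summary$in_H & summary$n_targets > 0L, , drop = FALSE]
  hi <- s$delta[s$n_targets_top > 0L]
  lo <- s$delta[s$n_targets_top == 0L]
  if (length(hi) == 0) stop("stratum HI is empty", call. = FALSE)
  if (length(lo) == 0) stop("stratum LOW is empty", call. = FALSE)
  mw <- mann_whitney_u(hi, lo, exact_limit = exact_limit)
  list(median_change_hi = stats::median(hi),
       median_change_low = stats::median(lo),
       n_hi = length(hi), n_low = length(lo), p_value = mw$p_value)
}

#' Assign genes to equally sized expression bins
#'
#' Sorts genes by combined expression (ties keep stable input order) and
#' splits them into `n_bins` contiguous groups whose sizes differ by at
#' most one; when the count does not divide evenly the larger bins sit at
#' the low-expression end.  Bin 1 is the lowest-expression bin.
#'
#' @param summary A `gene_summary`.
#' @param n_bins Number of bins (default 10).
#' @return The summary with a `bin` column added.
#' @export
bin_by_expression <- function(summary, n_bins = 10) {
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  n <- nrow(summary)
  if (n < n_bins)
    stop("need at least ", n_bins, " genes for ", n_bins, " bins",
         call. = FALSE)
  ord <- order(summary$combined)          # stable for ties
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_sorted <- rep(seq_len(n_bins), sizes)
  summary$bin <- integer(n)
  summary$bin[ord] <- bin_sorted
  summary
}

#' Per-bin expression change summaries
#'
#' @param summary A binned `gene_summary` (see [bin_by_expression()]).
#' @return Data frame with columns `bin`, `n`, `delta_q1`,
#'   `delta_median`, `delta_q3`.
#' @export
bin_summary <- function(summary) {
  if (is.null(summary$bin))
    stop("summary has no bins; call bin_by_expression() first",
         call. = FALSE)
  sp <- split(summary$delta, summary$bin)
  data.frame(bin = as.integer(names(sp)),
             n = lengths(sp),
             delta_q1 = vapply(sp, stats::quantile, 0, probs = 0.25,
                               names = FALSE),
             delta_median = vapply(sp, stats::median, 0),
             delta_q3 = vapply(sp, stats::quantile, 0, probs = 0.75,
                               names = FALSE),
             row.names = NULL)
}

#' Full derepression report
#'
#' Runs [global_shift_test()], [target_count_correlation()],
#' [stratified_target_test()] and [bin_summary()] on a summary and
#' collects the results.
#'
#' @param summary A `gene_summary` with target columns and bins.
#' @return List of class `derep_report` with elements `global`,
#'   `correlation`, `stratified`, `bins`.
#' @export
derepression_report <- function(summary) {
  structure(list(global = global_shift_test(summary),
                 correlation = target_count_correlation(summary),
                 stratified = stratified_target_test(summary),
                 bins = bin_summary(summary)),
            class = "derep_report")
}

#' @export
print.derep_report <- function(x, ...) {
  g <- x$global; r <- x$correlation; s <- x$stratified
  cat(sprintf("Global shift: median log2 expression %.3f (knockout) vs %.3f (control), Wilcoxon p = %.3g\n",
              g$median_ko, g$median_ctrl, g$p_value))
  cat(sprintf("Target-count correlation: Spearman rho = %.3f (n = %d), p = %.3g\n",
              r$rho, r$n, r$p_value))
  cat(sprintf("Stratified targets: median change %.3f (top-miRNA targets, n = %d) vs %.3f (other targets, n = %d), Mann-Whitney p = %.3g\n",
              s$median_change_hi, s$n_hi, s$median_change_low, s$n_low,
              s$p_value))
  invisible(x)
}

#' Write a derepression report as TSV
#'
#' @param report A `derep_report`.
#' @param stats_path TSV path for the scalar statistics (key/value).
#' @param bins_path Optional TSV path for the per-bin table.
#' @export
write_derepression_report <- function(report, stats_path,
                                      bins_path = NULL) {
  stopifnot(inherits(report, "derep_report"))
  g <- report$global; r <- report$correlation; s <- report$stratified
  df <- data.frame(
    statistic = c("median_ko", "median_ctrl", "wilcoxon_p",
                  "spearman_rho", "spearman_p", "median_change_hi",
                  "median_change_low", "n_hi", "n_low", "mannwhitney_p"),
    value = c(g$median_ko, g$median_ctrl, g$p_value, r$rho, r$p_value,
              s$median_change_hi, s$median_change_low, s$n_hi, s$n_low,
              s$p_value))
  write_tsv(df, stats_path)
  if (!is.null(bins_path)) write_tsv(report$bins, bins_path)
  invisible(report)
}
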