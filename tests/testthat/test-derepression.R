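# small normalized matrix with chosen values; H empty unless given
toy_norm <- function(values, n_genes, n_ko, n_ctrl, norm_genes = character()) {
  sheet <- toy_sheet(n_ko, n_ctrl)
  m <- matrix(values, nrow = n_genes,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sheet$sample_id))
  structure(list(values = m, samples = sheet, norm_genes = norm_genes,
                 offsets = stats::setNames(numeric(n_ko + n_ctrl),
                                           sheet$sample_id),
                 common_value = 0), class = "norm_matrix")
}

test_that("per-gene summaries use condition medians and their mean", {
  # gene g1: ko replicates {1,2,10} -> median 2; ctrl {0,0,0} -> 0
  nm <- toy_norm(c(1, 3, 2, 3, 10, 3, 0, 1, 0, 1, 0, 1), 2, 3, 3)
  s <- summarize_genes(nm)
  expect_equal(s$expr_ko, c(2, 3))
  expect_equal(s$expr_ctrl, c(0, 1))
  expect_equal(s$delta, c(2, 2))
  expect_equal(s$combined, c(1, 2))
  nm1 <- toy_norm(c(3, 1), 1, 1, 1)
  expect_error(summarize_genes(
    structure(list(values = nm1$values[, 1, drop = FALSE],
                   samples = nm1$samples[1, ], norm_genes = character()),
              class = "norm_matrix")), "control")
})

test_that("global shift test handles identity, small-n guard and direction", {
  vals <- matrix(rep(1:8, 2), 8)
  nm <- toy_norm(as.vector(vals), 8, 1, 1)
  s <- summarize_genes(nm)
  expect_warning(g <- global_shift_test(s), "zero")
  expect_equal(g$p_value, 1)
  # 3 genes changed is below the 6-gene minimum
  nm2 <- toy_norm(c(2:9, 1:8), 8, 1, 1)
  s2 <- summarize_genes(nm2)
  nm3 <- nm2; nm3$values[4:8, 1] <- nm3$values[4:8, 2]
  expect_error(global_shift_test(summarize_genes(nm3)), "at least 6")
  g2 <- global_shift_test(s2)
  expect_equal(g2$p_value, 1 / 128)   # 8 positive shifts, exact
  expect_equal(g2$median_ko - g2$median_ctrl, 1)
})

test_that("top-expressed miRNA selection is deterministic under boundary ties", {
  tab <- data.frame(mirna_id = c("m5", "m4", "m3", "m2", "m1"),
                    expression = c(10, 8, 6, 4, 2))
  expect_identical(top_expressed_mirnas(tab, 2), c("m5", "m4"))
  expect_warning(all_m <- top_expressed_mirnas(tab, 9), "exceeds")
  expect_identical(sort(all_m), sort(tab$mirna_id))
  # tie spanning the cutoff: lexicographic id among the tied block
  tie <- data.frame(mirna_id = c("mB", "mA", "mC", "mD"),
                    expression = c(5, 5, 5, 9))
  expect_identical(top_expressed_mirnas(tie, 2), c("mD", "mA"))
  expect_identical(top_expressed_mirnas(tie, 2),
                   top_expressed_mirnas(tie[c(3, 1, 4, 2), ], 2))
})

test_that("target-count correlation excludes normalization genes", {
  nm <- toy_norm(c(1:6, rep(0, 6)), 6, 1, 1, norm_genes = c("g1", "g2"))
  ann <- gene_annotation(
    targets = list(g3 = "mA", g4 = c("mA", "mB"),
                   g5 = c("mA", "mB", "mC"),
                   g6 = c("mA", "mB", "mC", "mD")),
    biotype = stats::setNames(rep("protein_coding", 6),
                              sprintf("g%d", 1:6)))
  s <- summarize_genes(nm, ann, top_mirnas = c("mA", "mB", "mC", "mD"))
  res <- target_count_correlation(s)
  expect_equal(res$n, 4)      # g1, g2 excluded
  expect_equal(res$rho, 1)    # delta and top-target count both increase
  expect_error(target_count_correlation(s[s$in_H | s$gene_id == "g3", ]),
               "fewer than 3")
  expect_error(target_count_correlation(summarize_genes(nm)),
               "n_targets_top")
})

test_that("stratified test splits targeted genes by top-miRNA membership", {
  nm <- toy_norm(c(3, 4, 1, 2, 5, rep(0, 5)), 5, 1, 1)
  ann <- gene_annotation(targets = list(
    g1 = "hi1", g2 = c("hi1", "lo1"),   # HI stratum, deltas {3, 4}
    g3 = "lo1", g4 = "lo2"))            # LOW stratum, deltas {1, 2}
  s <- summarize_genes(nm, ann, top_mirnas = "hi1")   # g5 untargeted
  res <- stratified_target_test(s)
  expect_equal(res$median_change_hi, 3.5)
  expect_equal(res$median_change_low, 1.5)
  expect_equal(res$n_hi, 2); expect_equal(res$n_low, 2)
  expect_equal(res$p_value, 1 / 3)
  # identical delta multisets across strata -> p = 1
  nm2 <- toy_norm(c(1, 2, 1, 2, rep(0, 4)), 4, 1, 1)
  s2 <- summarize_genes(nm2, gene_annotation(targets = list(
    g1 = "hi1", g2 = "hi1", g3 = "lo1", g4 = "lo1")), top_mirnas = "hi1")
  expect_equal(stratified_target_test(s2)$p_value, 1)
  # empty stratum is named
  s3 <- summarize_genes(nm2, gene_annotation(targets = list(
    g1 = "hi1", g2 = "hi1")), top_mirnas = "hi1")
  expect_error(stratified_target_test(s3), "LOW")
})

test_that("expression binning is equal-sized, low-end-heavy and tie-stable", {
  nm <- toy_norm(c(10:1, rep(0, 10)), 10, 1, 1)
  s <- bin_by_expression(summarize_genes(nm), 10)
  expect_equal(s$bin, 10:1)   # one gene per bin, ordered by combined
  # 25 genes in 10 bins: sizes 3x5 then 2x5, larger bins at the low end
  nm25 <- toy_norm(c(1:25, rep(0, 25)), 25, 1, 1)
  s25 <- bin_by_expression(summarize_genes(nm25), 10)
  expect_equal(as.vector(table(s25$bin)),
               c(3, 3, 3, 3, 3, 2, 2, 2, 2, 2))
  expect_true(all(diff(s25$bin[order(s25$combined)]) >= 0))
  # all-tied combined values: assignment follows stable input order
  nmt <- toy_norm(rep(1, 12), 6, 1, 1)
  st <- bin_by_expression(summarize_genes(nmt), 3)
  expect_equal(st$bin, rep(1:3, each = 2))
  expect_error(bin_by_expression(summarize_genes(nmt), 0), "n_bins")
  bs <- bin_summary(st)
  expect_equal(bs$n, rep(2L, 3))
  expect_true(all(bs$delta_median == 0))
})

test_that("derepression report combines all statistics and writes TSV", {
  sim <- simulate_transcriptome(
    simulation_config(n_genes = 600, n_mirnas = 60, seed = 17,
                      derepression_coefficient = 0.5))
  fem <- filter_genes(sim$expression, sim$annotation)
  H <- select_normalization_genes(sim$annotation, fem)
  nm <- normalize_expression(fem, H)
  top <- top_expressed_mirnas(sim$mirna_expression, 20)
  s <- bin_by_expression(summarize_genes(nm, sim$annotation, top))
  rep <- derepression_report(s)
  expect_gt(rep$correlation$rho, 0)
  expect_gt(rep$stratified$median_change_hi,
            rep$stratified$median_change_low)
  expect_true(rep$global$p_value > 0 && rep$global$p_value <= 1)
  dir <- withr::local_tempdir()
  write_derepression_report(rep, file.path(dir, "stats.tsv"),
                            file.path(dir, "bins.tsv"))
  stats_tab <- read.delim(file.path(dir, "stats.tsv"))
  expect_equal(stats_tab$value[stats_tab$statistic == "spearman_rho"],
               rep$correlation$rho, tolerance = 1e-6)
  expect_equal(nrow(read.delim(file.path(dir, "bins.tsv"))), 10)
})
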