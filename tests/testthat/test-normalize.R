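make_annotation <- function(gene_ids, biotype = "protein_coding",
                            housekeeping = character(),
                            targets = list()) {
  gene_annotation(targets, housekeeping,
                  stats::setNames(rep(biotype, length.out =
                                        length(gene_ids)), gene_ids))
}

test_that("filter keeps protein-coding genes detected in all samples", {
  em <- toy_matrix(c(1, 2, 0.5, 0,   3, 1, 2, 4), 4, 1, 1)
  ann <- make_annotation(rownames(em$values))
  out <- filter_genes(em, ann)
  expect_identical(rownames(out$values), c("g1", "g2", "g3")) # g4 has a 0
  # all positive, all coding: unchanged
  em2 <- toy_matrix(1:6, 3, 1, 1)
  expect_equal(filter_genes(em2, make_annotation(c("g1", "g2", "g3")))$values,
               em2$values)
})

test_that("filter enumerates biotype and detection exclusions correctly", {
  # 5 genes: 2 non-coding, 1 undetected -> 2 remain
  em <- toy_matrix(c(1, 2, 3, 4, 0,  1, 1, 1, 1, 1), 5, 1, 1)
  bt <- c(g1 = "protein_coding", g2 = "lincRNA", g3 = "pseudogene",
          g4 = "protein_coding", g5 = "protein_coding")
  ann <- gene_annotation(biotype = bt)
  out <- filter_genes(em, ann)
  expect_identical(rownames(out$values), c("g1", "g4"))
  expect_error(filter_genes(toy_matrix(c(0, 0), 1, 1, 1),
                            make_annotation("g1")), "no genes")
})

test_that("normalization-set selection enforces the minimum size", {
  em <- toy_matrix(rep(1, 10), 5, 1, 1)
  ids <- rownames(em$values)
  # 2 housekeeping genes, one of which is targeted -> |H| = 1
  ann <- make_annotation(ids, housekeeping = c("g1", "g2"),
                         targets = list(g1 = "mirA"))
  expect_error(select_normalization_genes(ann, em), "1 ")
  expect_identical(select_normalization_genes(ann, em,
                                              min_norm_genes = 1), "g2")
  expect_error(select_normalization_genes(make_annotation(ids), em),
               "housekeeping")
})

test_that("median matching reproduces the hand-computed offsets", {
  # H log2 values {1,2,3} and {2,3,4}: medians 2 and 3, c = 2.5,
  # offsets +0.5 and -0.5
  em <- toy_matrix(2^c(1, 2, 3, 2, 3, 4), 3, 1, 1)
  nm <- normalize_expression(em, c("g1", "g2", "g3"))
  expect_equal(nm$common_value, 2.5)
  expect_equal(unname(nm$offsets), c(0.5, -0.5))
  expect_equal(unname(nm$values[, 1]), c(1.5, 2.5, 3.5))
  expect_equal(unname(nm$values[, 2]), c(1.5, 2.5, 3.5))
})

test_that("already-matched samples get zero offsets and a fixed common value is honored", {
  em <- toy_matrix(2^c(1, 2, 3, 3, 2, 1), 3, 1, 1)
  nm <- normalize_expression(em, c("g1", "g2", "g3"))
  expect_equal(unname(nm$offsets), c(0, 0))
  expect_equal(nm$values, log2(em$values))
  nm5 <- normalize_expression(em, c("g1", "g2", "g3"), common_value = 5)
  expect_equal(unname(apply(nm5$values[1:3, ], 2, median)), c(5, 5))
})

test_that("normalization cancels per-sample multiplicative rescaling exactly", {
  set.seed(71)
  for (i in 1:5) {
    vals <- 2^matrix(rnorm(60, 2, 1.5), 10)
    sheet <- toy_sheet(3, 3)
    dimnames(vals) <- list(sprintf("g%d", 1:10), sheet$sample_id)
    em <- expression_matrix(vals, sheet)
    H <- c("g1", "g3", "g5", "g7")
    scale <- runif(6, 0.05, 20)
    em2 <- expression_matrix(sweep(vals, 2, scale, `*`), sheet)
    # with a fixed common value the cancellation is exact
    nf1 <- normalize_expression(em, H, common_value = 3)
    nf2 <- normalize_expression(em2, H, common_value = 3)
    expect_equal(nf2$values, nf1$values, tolerance = 1e-9)
    # the default (data-scale) rule cancels scaling up to one global
    # additive constant, so every contrast is scale-invariant
    nm <- normalize_expression(em, H)
    nm2 <- normalize_expression(em2, H)
    shift <- nm2$values - nm$values
    expect_lt(diff(range(shift)), 1e-9)
    expect_equal(summarize_genes(nm2)$delta, summarize_genes(nm)$delta,
                 tolerance = 1e-9)
    # median-matching invariant
    expect_equal(unname(apply(nm$values[H, ], 2, median)),
                 rep(nm$common_value, 6), tolerance = 1e-9)
    # within-sample gene differences preserved
    expect_equal(nm$values[2, ] - nm$values[4, ],
                 log2(vals[2, ]) - log2(vals[4, ]))
  }
})

test_that("normalization contract errors fire", {
  em <- toy_matrix(c(1, 2, 3, 4), 2, 1, 1)
  expect_error(normalize_expression(em, character()), "empty")
  expect_error(normalize_expression(em, c("g1", "gX")), "absent")
  em0 <- toy_matrix(c(0, 2, 3, 4), 2, 1, 1)
  expect_error(normalize_expression(em0, "g1"), "zero FPKM")
})

test_that("shifting knockout samples is absorbed by the offsets, leaving delta fixed", {
  sim <- simulate_transcriptome(
    simulation_config(n_genes = 400, n_mirnas = 50, seed = 31))
  fem <- filter_genes(sim$expression, sim$annotation)
  H <- select_normalization_genes(sim$annotation, fem)
  nm1 <- normalize_expression(fem, H)
  k <- 1.7   # log2 shift applied multiplicatively to every knockout sample
  v2 <- fem$values
  ko <- fem$samples$condition == "knockout"
  v2[, ko] <- v2[, ko] * 2^k
  nm2 <- normalize_expression(expression_matrix(v2, fem$samples), H)
  # the common value follows the knockout medians by k * n_ko / n, so the
  # knockout offsets absorb the remaining k * (1 - n_ko / n)
  expect_equal(unname(nm1$offsets[ko] - nm2$offsets[ko]),
               rep(k * (1 - mean(ko)), sum(ko)))
  # delta shifts by the constant minus the induced offset change: zero
  s1 <- summarize_genes(nm1); s2 <- summarize_genes(nm2)
  expect_equal(s2$delta, s1$delta)
})
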