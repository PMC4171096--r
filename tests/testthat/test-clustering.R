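norm_like <- function(values) {
  list(values = values,
       samples = data.frame(sample_id = colnames(values),
                            condition = "control",
                            replicate = seq_len(ncol(values))))
}

test_that("Spearman distances hit the defining special cases", {
  v <- matrix(c(1, 5, 2, 9, 4), 5, 1)
  m <- cbind(a = v[, 1], b = v[, 1], c = max(v) + 1 - v[, 1], d = exp(v[, 1]))
  rownames(m) <- sprintf("g%d", 1:5)
  d <- sample_distances(norm_like(m))
  expect_equal(d["a", "b"], 0)          # duplicated sample
  expect_equal(d["a", "c"], 2)          # strictly decreasing transform
  expect_equal(d["a", "d"], 0)          # strictly increasing transform
  expect_equal(unclass(d), t(unclass(d)))
  expect_equal(diag(unclass(d)), setNames(rep(0, 4), colnames(m)))
})

test_that("Spearman distances match the rank-then-Pearson oracle", {
  set.seed(19)
  m <- matrix(sample.int(4, 15, replace = TRUE), 5, 3,
              dimnames = list(sprintf("g%d", 1:5), c("s1", "s2", "s3")))
  m <- m + matrix(runif(15, 0, 0.01), 5)   # break full-column ties
  d <- sample_distances(norm_like(m))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d[i, j], 1 - oracle_spearman_rho(m[, i], m[, j]))
})

test_that("constant sample vectors are rejected by name", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(7, 7, 7))
  rownames(m) <- sprintf("g%d", 1:3)
  expect_error(sample_distances(norm_like(m)), "s2")
})

test_that("Ward clustering handles the two-sample base case", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  wc <- ward_cluster(d)
  expect_equal(nrow(wc$merge), 1)
  expect_equal(wc$merge[1, ], c(-2L, -1L))
  expect_equal(wc$height, 0.4)   # sqrt of the squared two-point distance
})

test_that("two tight pairs merge before the final join", {
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.1
  d["b1", "b2"] <- d["b2", "b1"] <- 0.1
  wc <- ward_cluster(d)
  expect_equal(wc$merge[1, ], c(-2L, -1L))
  expect_equal(wc$merge[2, ], c(-4L, -3L))
  expect_equal(wc$merge[3, ], c(1L, 2L))
  expect_true(all(diff(wc$height) >= 0))
})

test_that("Ward merges match the from-scratch ESS oracle on small matrices", {
  set.seed(29)
  for (n in 3:5) {
    for (rep in 1:4) {
      p <- matrix(rnorm(n * 2), n)
      d <- as.matrix(dist(p))
      dimnames(d) <- list(letters[1:n], letters[1:n])
      wc <- ward_cluster(d)
      orc <- oracle_ward_merges(d)
      expect_equal(wc$merge, orc$merge, info = sprintf("n=%d", n))
      expect_equal(wc$height, orc$height, tolerance = 1e-10)
    }
  }
})

test_that("Ward clustering agrees with hclust ward.D2 and is order-invariant", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 7
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    wc <- ward_cluster(d)
    hc <- hclust(as.dist(d), method = "ward.D2")
    expect_equal(sort(wc$height), sort(hc$height), tolerance = 1e-10)
    cut_mine <- cutree(as.hclust(wc), k = 3)
    cut_ref <- cutree(hc, k = 3)[names(cut_mine)]
    expect_equal(length(unique(paste(cut_mine, cut_ref))), 3)
    # permuting the input samples relabels but does not reshape the tree
    perm <- sample(n)
    wc2 <- ward_cluster(d[perm, perm])
    expect_equal(sort(wc2$height), sort(wc$height), tolerance = 1e-10)
    cut2 <- cutree(as.hclust(wc2), k = 3)[names(cut_mine)]
    expect_equal(length(unique(paste(cut_mine, cut2))), 3)
  }
})

test_that("asymmetric or non-finite input is rejected", {
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_cluster(d), "symmetric")
  d2 <- matrix(c(0, NA, NA, 0), 2)
  expect_error(ward_cluster(d2), "symmetric|finite")
})

test_that("noise-free simulated conditions split perfectly at the 2-cluster cut", {
  sim <- simulate_transcriptome(
    simulation_config(n_genes = 500, n_mirnas = 60, noise_sd = 0.01,
                      derepression_coefficient = 0.5, seed = 23))
  fem <- filter_genes(sim$expression, sim$annotation)
  nm <- normalize_expression(
    fem, select_normalization_genes(sim$annotation, fem))
  wc <- ward_cluster(sample_distances(nm))
  expect_equal(cut_purity(wc, nm$samples), 1)
})

test_that("clustering outputs round-trip to TSV and Newick", {
  d <- structure(as.matrix(dist(matrix(rnorm(12, sd = 2), 4))),
                 class = c("dist_matrix", "matrix"))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  wc <- ward_cluster(d)
  dir <- withr::local_tempdir()
  write_clustering(wc, d, file.path(dir, "d.tsv"), file.path(dir, "m.tsv"),
                   file.path(dir, "t.nwk"))
  m <- read.delim(file.path(dir, "m.tsv"))
  expect_equal(m$height, wc$height)
  tree <- ape::read.tree(file.path(dir, "t.nwk"))
  expect_setequal(tree$tip.label, paste0("s", 1:4))
})
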