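# Sample-level hierarchical clustering on Spearman correlation distance.
#
# Replicate libraries of the same condition should be most similar, so
# the dendrogram of d = 1 - rho (Spearman, over gene expression vectors)
# under Ward linkage is the standard visual check that the knockout
# transcriptome separates from the control one.

#' Spearman correlation distance between samples
#'
#' `d_ij = 1 - rho_ij` where rho is the Spearman correlation (mid-rank
#' ties) of the two samples' gene expression vectors; range [0, 2].
#'
#' @param norm A `norm_matrix` (or any `expr_matrix`-like object with a
#'   `values` matrix); needs >= 2 samples and >= 3 genes.
#' @return Symmetric distance matrix with zero diagonal, class
#'   `dist_matrix`.
#' @export
sample_distances <- function(norm) {
  v <- norm$values
  stopifnot(is.matrix(v), ncol(v) >= 2, nrow(v) >= 3)
  const <- apply(v, 2L, function(x) stats::sd(x) == 0)
  if (any(const))
    stop("constant expression vector (Spearman undefined) in sample: ",
         paste(colnames(v)[const], collapse = ", "), call. = FALSE)
  d <- 1 - stats::cor(v, method = "spearman")
  diag(d) <- 0
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Agglomerative Ward clustering of a distance matrix
#'
#' Lance-Williams recursion for Ward linkage.  By default the input
#' distances are squared before the update and merge heights are the
#' square roots of the Ward values (the `hclust` `ward.D2` convention,
#' appropriate when the input is a plain dissimilarity such as
#' `1 - rho`); with `square_distances = FALSE` the input is treated as
#' already squared (`ward.D`).  Ties in the minimum merge cost are
#' broken deterministically toward the earliest-created cluster pair.
#'
#' @param d Symmetric numeric matrix with zero diagonal (e.g. from
#'   [sample_distances()]).
#' @param square_distances Square the input before the Ward update
#'   (default `TRUE`).
#' @return List of class `ward_clust` with `merge` (hclust-style, one
#'   row per agglomeration: negative entries are singletons, positive
#'   are prior merge steps), `height`, `sizes` (cluster size after each
#'   merge), `labels`.
#' @seealso [as.hclust.ward_clust()] to use `stats::cutree` and plotting.
#' @export
ward_cluster <- function(d, square_distances = TRUE) {
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
      any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  n <- nrow(d)
  labels <- colnames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- if (square_distances) d^2 else d

  active <- seq_len(n)          # slots still in play, in creation order
  code <- -seq_len(n)           # hclust codes: -singleton / +merge step
  sizes <- rep(1, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  out_sizes <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); best_v <- Inf
    for (a in seq_along(active)[-length(active)]) {
      i <- active[a]
      for (b in (a + 1L):length(active)) {
        j <- active[b]
        if (D[i, j] < best_v - 1e-12) {
          best_v <- D[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- if (square_distances) sqrt(best_v) else best_v
    # Lance-Williams Ward update into slot i
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      v <- ((ni + nk) * D[k, i] + (nj + nk) * D[k, j] - nk * best_v) /
        (ni + nj + nk)
      D[k, i] <- D[i, k] <- v
    }
    sizes[i] <- ni + nj
    out_sizes[step] <- sizes[i]
    code[i] <- step
    active <- active[active != j]
  }
  structure(list(merge = merge, height = height, sizes = out_sizes,
                 labels = labels), class = "ward_clust")
}

# leaf order for plotting / hclust conversion
tree_order <- function(merge, n) {
  leaves <- function(k)
    if (k < 0) -k else c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  leaves(n - 1L)
}

#' Convert a Ward clustering to an hclust object
#'
#' Enables `stats::cutree`, `plot` and `ape::as.phylo`.
#'
#' @param x A `ward_clust`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.ward_clust <- function(x, ...) {
  n <- nrow(x$merge) + 1L
  structure(list(merge = x$merge, height = x$height,
                 order = tree_order(x$merge, n), labels = x$labels,
                 method = "ward", call = match.call(),
                 dist.method = "1 - spearman rho"),
            class = "hclust")
}

#' @export
print.ward_clust <- function(x, ...) {
  cat(sprintf("ward_clust: %d leaves, %d merges; heights %.3g .. %.3g\n",
              nrow(x$merge) + 1L, nrow(x$merge), min(x$height),
              max(x$height)))
  invisible(x)
}

#' Write clustering outputs as TSV (and optionally Newick)
#'
#' @param wc A `ward_clust`.
#' @param d The `dist_matrix` it was built from.
#' @param dist_path TSV path for the distance matrix.
#' @param merge_path TSV path for the merge table (node_a, node_b,
#'   height, size).
#' @param newick_path Optional Newick export of the dendrogram (requires
#'   the `ape` package).
#' @export
write_clustering <- function(wc, d, dist_path, merge_path,
                             newick_path = NULL) {
  write_tsv(data.frame(sample_id = rownames(unclass(d)), unclass(d),
                       check.names = FALSE), dist_path)
  write_tsv(data.frame(node_a = wc$merge[, 1], node_b = wc$merge[, 2],
                       height = wc$height, size = wc$sizes), merge_path)
  if (!is.null(newick_path)) {
    if (!requireNamespace("ape", quietly = TRUE))
      stop("Newick export requires the 'ape' package", call. = FALSE)
    ape::write.tree(ape::as.phylo(as.hclust(wc)), file = newick_path)
  }
  invisible(wc)
}

#' Condition purity of the two-cluster cut
#'
#' Cuts the dendrogram into two clusters and reports the fraction of
#' samples on the majority-condition side of each cluster: 1 means the
#' cut separates knockout from control perfectly.
#'
#' @param wc A `ward_clust` over samples.
#' @param samples Sample sheet with `sample_id` and `condition`.
#' @return Purity in \[0.5, 1\].
#' @export
cut_purity <- function(wc, samples) {
  cl <- stats::cutree(as.hclust(wc), k = 2)
  cond <- samples$condition[match(names(cl), samples$sample_id)]
  sum(vapply(split(cond, cl), function(x) max(table(x)), 0)) / length(cl)
}
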