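# Gene-set overrepresentation of upregulated genes.
#
# A generic hypergeometric overrepresentation test: for each gene set,
# does it overlap the upregulated genes more than expected if the
# upregulated genes were drawn uniformly from the analyzed universe?
# The universe is the filtered (detected, protein-coding) gene list, not
# the genome, which guards against detection bias.

#' Genes upregulated beyond a log2 threshold
#'
#' @param summary A `gene_summary`.
#' @param delta_threshold Minimum expression change in log2 units
#'   (default 0.5, i.e. ~1.4-fold).
#' @return Character vector of gene ids with `delta >= delta_threshold`.
#' @export
upregulated_set <- function(summary, delta_threshold = 0.5) {
  stopifnot(is.finite(delta_threshold))
  summary$gene_id[summary$delta >= delta_threshold]
}

#' Read gene sets from a GMT file
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; the description is kept in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], ": need id, description and ",
         "at least one gene", call. = FALSE)
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set id: ", ids[duplicated(ids)][1], call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, "", 2L), ids)
  sets
}

#' Hypergeometric overrepresentation test
#'
#' For each gene set, the one-sided hypergeometric tail probability of
#' observing at least the seen overlap between the set (restricted to the
#' universe) and the upregulated genes, with Benjamini-Hochberg
#' adjustment across the tested sets.  Sets with fewer than
#' `min_set_size` genes inside the universe are skipped (reported with
#' `tested = FALSE` and `NA` p-values).
#'
#' @param upregulated Character vector of selected genes; must be a
#'   subset of `universe`.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: all analyzed genes.
#' @param min_set_size Minimum in-universe set size to test (default 5).
#' @return Data frame with one row per set: `set_id`, `set_size` (in
#'   universe), `overlap`, `expected`, `p_raw`, `p_adjusted`, `tested`,
#'   ordered by `p_raw`.
#' @export
overrepresentation <- function(upregulated, sets, universe,
                               min_set_size = 5) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stray <- setdiff(upregulated, universe)
  if (length(stray))
    stop("upregulated genes outside the universe: ",
         paste(utils::head(stray, 3), collapse = ", "), call. = FALSE)
  upregulated <- unique(upregulated)
  N <- length(universe)
  n_up <- length(upregulated)
  K <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(sets, function(s) length(intersect(s, upregulated)), 0L)
  tested <- K >= min_set_size
  # P(X >= k) for X ~ Hypergeometric(N, K, n_up)
  p_raw <- ifelse(tested,
                  stats::phyper(k - 1, K, N - K, n_up, lower.tail = FALSE),
                  NA_real_)
  p_adj <- rep(NA_real_, length(sets))
  p_adj[tested] <- stats::p.adjust(p_raw[tested], method = "BH")
  out <- data.frame(set_id = names(sets), set_size = K, overlap = k,
                    expected = n_up * K / N, p_raw = p_raw,
                    p_adjusted = p_adj, tested = tested,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(!out$tested, out$p_raw), ]
}
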