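# Tabular input/output with strict validation.
#
# All files are plain TSV: tab-delimited, UTF-8, no quoting; lines starting
# with '#' are comments and are ignored.  Every reader validates its input
# and names the offending row or column in its error message.

VALID_CONDITIONS <- c("knockout", "control")

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Construct a validated expression matrix
#'
#' Bundles a genes-by-samples matrix of FPKM values with its sample sheet.
#' FPKM (fragments per kilobase of transcript per million mapped reads) is a
#' length- and depth-normalized expression unit; values must be finite and
#' non-negative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`"knockout"` or `"control"`) and `replicate` (integer index), one row
#'   per column of `values`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     condition = c("knockout", "control"),
#'                     replicate = c(1L, 1L))
#' expression_matrix(m, sheet)
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names",
         call. = FALSE)
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite FPKM at gene '",
         rownames(values)[bad[1, 1]], "', sample '",
         colnames(values)[bad[1, 2]], "'", call. = FALSE)
  samples <- validate_sample_sheet(samples)
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing))
    stop("samples absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  samples <- samples[match(colnames(values), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "condition", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  bad <- setdiff(unique(samples$condition), VALID_CONDITIONS)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         " (expected knockout/control)", call. = FALSE)
  samples$replicate <- as.integer(samples$replicate)
  samples
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$samples$condition)),
                            table(x$samples$condition)), collapse = ", ")))
  invisible(x)
}

#' Read an FPKM expression table and its sample sheet
#'
#' The expression file has a header `gene_id<TAB>sample1<TAB>...` and one
#' row per gene; the sample sheet has columns `sample_id`, `condition`,
#' `replicate`.  Row order is preserved.
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, sample_sheet_path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id")
    stop("first column of ", path, " must be 'gene_id', got '",
         names(df)[1], "'", call. = FALSE)
  genes <- as.character(df$gene_id)
  vals <- df[, -1, drop = FALSE]
  for (col in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[col]]))
    nn <- which(is.na(v) & !is.na(vals[[col]]))
    if (length(nn))
      stop("non-numeric FPKM in column '", col, "', gene '",
           genes[nn[1]], "'", call. = FALSE)
    vals[[col]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  sheet <- read_tsv(sample_sheet_path)
  expression_matrix(m, sheet)
}

#' Write an expression matrix (and optionally its sample sheet) as TSV
#'
#' @param x An `expr_matrix` object.
#' @param path Output path for the expression TSV.
#' @param sample_sheet_path Optional output path for the sample sheet.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(sample_sheet_path)) write_tsv(x$samples, sample_sheet_path)
  invisible(x)
}

# Read a two-column TSV by hand so malformed lines can be reported with
# their line number (read.delim would silently recycle or fail obscurely).
read_pair_lines <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    stop("malformed ", what, " line ", idx[bad[1]], " in ", path,
         ": expected ", n_fields, " tab-separated fields", call. = FALSE)
  parts
}

#' Read gene annotation: miRNA target pairs, housekeeping list, biotypes
#'
#' @param pairs_path TSV of `gene_id<TAB>mirna_id` pairs (one predicted
#'   targeting interaction per line; duplicates collapse, set semantics).
#'   A header line `gene_id<TAB>mirna_id` is allowed and skipped.
#' @param housekeeping_path Text file with one housekeeping gene id per
#'   line, or `NULL` for none.
#' @param biotype_path TSV of `gene_id<TAB>biotype`, or `NULL`.  Genes
#'   absent from this file get biotype `"unknown"` when queried.
#' @return An object of class `gene_annotation` with elements `targets`
#'   (named list of character vectors), `housekeeping` (character vector)
#'   and `biotype` (named character vector).
#' @seealso [gene_annotation()] to build the object in code.
#' @export
read_target_annotation <- function(pairs_path, housekeeping_path = NULL,
                                   biotype_path = NULL) {
  parts <- read_pair_lines(pairs_path, 2L, "target-pair")
  if (length(parts) && identical(parts[[1]], c("gene_id", "mirna_id")))
    parts <- parts[-1]
  genes <- vapply(parts, `[`, "", 1L)
  mirnas <- vapply(parts, `[`, "", 2L)
  targets <- lapply(split(mirnas, genes), function(m) sort(unique(m)))
  hk <- character()
  if (!is.null(housekeeping_path)) {
    lines <- readLines(housekeeping_path, warn = FALSE)
    hk <- unique(trimws(lines[!grepl("^\\s*(#|$)", lines)]))
  }
  biotype <- character()
  if (!is.null(biotype_path)) {
    bparts <- read_pair_lines(biotype_path, 2L, "biotype")
    if (length(bparts) && identical(bparts[[1]], c("gene_id", "biotype")))
      bparts <- bparts[-1]
    bg <- vapply(bparts, `[`, "", 1L)
    if (anyDuplicated(bg))
      stop("duplicate gene id in biotype file: ", bg[duplicated(bg)][1],
           call. = FALSE)
    biotype <- stats::setNames(vapply(bparts, `[`, "", 2L), bg)
  }
  gene_annotation(targets, hk, biotype)
}

#' Construct a gene annotation object
#'
#' @param targets Named list: gene id -> character vector of targeting
#'   miRNA ids (set semantics; duplicates are collapsed).  Genes not named
#'   here have empty target sets.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param biotype Named character vector: gene id -> biotype.  Genes not
#'   named here have biotype `"unknown"`.
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(targets = list(), housekeeping = character(),
                            biotype = character()) {
  if (length(targets) && is.null(names(targets)))
    stop("'targets' must be a named list", call. = FALSE)
  if (anyDuplicated(names(targets)))
    stop("duplicate gene ids in 'targets'", call. = FALSE)
  targets <- lapply(targets, function(m) sort(unique(as.character(m))))
  structure(list(targets = targets,
                 housekeeping = unique(as.character(housekeeping)),
                 biotype = biotype),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "gene_annotation: %d genes with targets, %d housekeeping, %d biotyped\n",
    length(x$targets), length(x$housekeeping), length(x$biotype)))
  invisible(x)
}

#' Query a gene annotation for a set of genes
#'
#' Returns per-gene annotation aligned to `gene_ids`, applying the
#' defaults for unannotated genes (empty target set, biotype `"unknown"`,
#' not housekeeping).
#'
#' @param annotation A `gene_annotation` object.
#' @param gene_ids Character vector of gene ids.
#' @return Data frame with columns `gene_id`, `biotype`, `housekeeping`,
#'   `n_targets`, plus the target sets as a list in
#'   `attr(, "targets")`.
#' @export
annotation_for <- function(annotation, gene_ids) {
  stopifnot(inherits(annotation, "gene_annotation"))
  gene_ids <- as.character(gene_ids)
  tg <- annotation$targets[gene_ids]
  names(tg) <- gene_ids
  tg[vapply(tg, is.null, TRUE)] <- list(character())
  bt <- unname(annotation$biotype[gene_ids])
  bt[is.na(bt)] <- "unknown"
  out <- data.frame(gene_id = gene_ids, biotype = bt,
                    housekeeping = gene_ids %in% annotation$housekeeping,
                    n_targets = lengths(tg), stringsAsFactors = FALSE)
  attr(out, "targets") <- tg
  out
}

#' Read a miRNA expression table
#'
#' TSV with columns `mirna_id` and `expression` (non-negative reals, any
#' consistent unit, e.g. normalized read counts); used only for ranking.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `mirna_id`, `expression`.
#' @export
read_mirna_expression <- function(path) {
  df <- read_tsv(path)
  if (!all(c("mirna_id", "expression") %in% names(df)))
    stop("miRNA table needs columns mirna_id, expression", call. = FALSE)
  df$mirna_id <- as.character(df$mirna_id)
  df$expression <- as.numeric(df$expression)
  if (anyDuplicated(df$mirna_id))
    stop("duplicate miRNA id: ", df$mirna_id[duplicated(df$mirna_id)][1],
         call. = FALSE)
  if (any(!is.finite(df$expression) | df$expression < 0))
    stop("miRNA expression values must be finite and >= 0", call. = FALSE)
  df[, c("mirna_id", "expression")]
}

#' Write a miRNA expression table
#' @param x Data frame with columns `mirna_id`, `expression`.
#' @param path Output TSV path.
#' @export
write_mirna_expression <- function(x, path) {
  write_tsv(x[, c("mirna_id", "expression")], path)
  invisible(x)
}

#' Write a gene annotation as its three input files
#'
#' Inverse of [read_target_annotation()].
#'
#' @param annotation A `gene_annotation` object.
#' @param pairs_path,housekeeping_path,biotype_path Output paths; any may
#'   be `NULL` to skip that file.
#' @export
write_target_annotation <- function(annotation, pairs_path,
                                    housekeeping_path = NULL,
                                    biotype_path = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!is.null(pairs_path)) {
    g <- rep(names(annotation$targets), lengths(annotation$targets))
    df <- data.frame(gene_id = g,
                     mirna_id = unlist(annotation$targets, use.names = FALSE))
    write_tsv(df, pairs_path)
  }
  if (!is.null(housekeeping_path))
    writeLines(annotation$housekeeping, housekeeping_path)
  if (!is.null(biotype_path))
    write_tsv(data.frame(gene_id = names(annotation$biotype),
                         biotype = unname(annotation$biotype)),
              biotype_path)
  invisible(annotation)
}
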