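# Synthetic transcriptome generator with known miRNA-repression-loss
# structure.  Emulates a bulk RNA-seq comparison of miRNA-pathway knockout
# versus control germ-cell libraries at the FPKM level: log2-normal
# baseline expression, heavy-tailed miRNA abundances, Poisson-distributed
# predicted target counts, derepression in the knockout proportional to
# the summed relative abundance of a gene's targeting miRNAs, log-scale
# replicate noise and a per-sample multiplicative library-size factor.

#' Simulation configuration
#'
#' Parameters of the synthetic knockout-versus-control transcriptome.
#' Defaults describe a mid-sized mammalian germ-cell experiment: 5,000
#' detected protein-coding genes, 300 expressed miRNAs with a heavy-tailed
#' abundance spectrum, three replicates per condition.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_mirnas Number of miRNAs (>= 1).
#' @param n_replicates_per_condition Replicates per condition (default 3,
#'   matching a typical bulk RNA-seq design).
#' @param baseline_mean,baseline_sd Mean and sd of the per-gene control
#'   log2-FPKM baseline (defaults 2.2 and 2: median detected-gene
#'   expression a little above 4 FPKM with a several-log2 spread).
#' @param mirna_abundance_shape Pareto tail index of the miRNA abundance
#'   distribution (default 1.5; smaller = heavier tail, i.e. expression
#'   more concentrated in the top miRNAs).
#' @param target_density Mean number of targeting miRNAs per gene; target
#'   counts are Poisson(`target_density`) (default 2, leaving a
#'   substantial target-free gene pool as real TargetScan-style
#'   annotations do).
#' @param derepression_coefficient Derepression per unit of mean-relative
#'   targeting-miRNA abundance, in log2 units (delta).  A gene's true
#'   derepression is `delta * sum(a_m)` over its targeting miRNAs, where
#'   abundances `a_m` are scaled to mean 1 across miRNAs, so `delta` is
#'   the log2 upregulation conferred by one averagely-expressed miRNA.
#' @param target_affinity_exponent Exponent gamma weighting target
#'   assignment probability by `abundance^gamma` (default 0: targets
#'   chosen uniformly across miRNAs).
#' @param housekeeping_fraction Fraction of genes flagged housekeeping,
#'   drawn from the target-free pool (default 0.07, the order of the
#'   ~900/13,000 target-free housekeeping genes typical of mouse data).
#' @param noise_sd Replicate noise sd on the log2 scale (default 0.25).
#' @param library_factors Per-sample multiplicative library-size factors
#'   (length `2 * n_replicates_per_condition`, all > 0), or `NULL` to
#'   draw them as `2^Normal(0, 0.5)` (roughly 0.5x-2x depth distortion).
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 5000,
                              n_mirnas = 300,
                              n_replicates_per_condition = 3,
                              baseline_mean = 2.2,
                              baseline_sd = 2,
                              mirna_abundance_shape = 1.5,
                              target_density = 2,
                              derepression_coefficient = 0.3,
                              target_affinity_exponent = 0,
                              housekeeping_fraction = 0.07,
                              noise_sd = 0.25,
                              library_factors = NULL,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_replicates_per_condition =
                as.integer(n_replicates_per_condition),
              baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              mirna_abundance_shape = mirna_abundance_shape,
              target_density = target_density,
              derepression_coefficient = derepression_coefficient,
              target_affinity_exponent = target_affinity_exponent,
              housekeeping_fraction = housekeeping_fraction,
              noise_sd = noise_sd,
              library_factors = library_factors,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1, n_mirnas >= 1, n_replicates_per_condition >= 1,
              baseline_sd >= 0, noise_sd >= 0,
              mirna_abundance_shape > 0, target_density >= 0,
              derepression_coefficient >= 0,
              housekeeping_fraction >= 0, housekeeping_fraction <= 1)
  })
  if (!is.null(cfg$library_factors)) {
    n_s <- 2L * cfg$n_replicates_per_condition
    if (length(cfg$library_factors) != n_s)
      stop("library_factors must have length ", n_s, call. = FALSE)
    if (any(cfg$library_factors <= 0))
      stop("library_factors must be > 0", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a knockout-versus-control transcriptome with ground truth
#'
#' Generative model, all on the log2-FPKM scale.  Control baseline
#' `b_g ~ Normal(baseline_mean, baseline_sd)`.  miRNA abundances are
#' Pareto(`mirna_abundance_shape`) draws rescaled to mean 1; each gene
#' receives `Poisson(target_density)` distinct targeting miRNAs sampled
#' with probability proportional to `abundance^gamma`.  True derepression
#' `delta_true(g) = delta * sum(a_m, m in T(g))` is added to knockout
#' samples only, so genes without target sites are unaffected
#' (`delta_true = 0`).  Replicate values are
#' `2^(b_g + delta_true * is_ko + eps)` with `eps ~ Normal(0, noise_sd)`,
#' then multiplied by the sample's library factor.  A
#' `housekeeping_fraction` of genes is flagged housekeeping, drawn from
#' the target-free pool; every gene is biotyped `protein_coding`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `transcriptome_simulation` with elements
#'   `expression` ([expression_matrix()]), `annotation`
#'   ([gene_annotation()]), `mirna_expression` (data frame `mirna_id`,
#'   `expression`), and `truth` (list: `delta_true` named per-gene vector,
#'   `targets` named list, `library_factors` named per-sample vector,
#'   `normalization_genes` character vector of the housekeeping
#'   target-free genes).
#' @examples
#' sim <- simulate_transcriptome(simulation_config(n_genes = 100,
#'                                                 n_mirnas = 20, seed = 7))
#' sim$expression
#' head(sim$truth$delta_true)
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nm <- config$n_mirnas
  nr <- config$n_replicates_per_condition

  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  mirna_ids <- sprintf("mir-%03d", seq_len(nm))

  # Pareto(shape, x_m = 1) abundances, rescaled to mean 1 across miRNAs:
  # derepression_coefficient is per unit of this mean-relative abundance.
  abund_raw <- stats::runif(nm)^(-1 / config$mirna_abundance_shape)
  abund <- abund_raw / mean(abund_raw)
  names(abund) <- mirna_ids

  n_targets <- stats::rpois(ng, config$target_density)
  n_targets <- pmin(n_targets, nm)
  w <- abund^config$target_affinity_exponent
  targets <- lapply(n_targets, function(k) {
    if (k == 0) character() else sample(mirna_ids, k, prob = w)
  })
  names(targets) <- gene_ids

  delta_true <- config$derepression_coefficient *
    vapply(targets, function(m) sum(abund[m]), 0)

  target_free <- gene_ids[n_targets == 0L]
  n_hk <- floor(config$housekeeping_fraction * ng)
  if (n_hk > length(target_free))
    stop("housekeeping_fraction requires ", n_hk, " target-free genes but ",
         "only ", length(target_free), " exist (short by ",
         n_hk - length(target_free), ")", call. = FALSE)
  hk <- sort(sample(target_free, n_hk))

  sample_ids <- c(sprintf("ko_%d", seq_len(nr)),
                  sprintf("ctrl_%d", seq_len(nr)))
  condition <- rep(c("knockout", "control"), each = nr)
  lf <- config$library_factors
  if (is.null(lf)) lf <- 2^stats::rnorm(2L * nr, 0, 0.5)
  names(lf) <- sample_ids

  b <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  is_ko <- as.numeric(condition == "knockout")
  log2_mean <- outer(b, rep(1, 2L * nr)) + outer(delta_true, is_ko)
  eps <- matrix(stats::rnorm(ng * 2L * nr, 0, config$noise_sd), ng)
  fpkm <- 2^(log2_mean + eps) * rep(lf, each = ng)
  dimnames(fpkm) <- list(gene_ids, sample_ids)

  sheet <- data.frame(sample_id = sample_ids, condition = condition,
                      replicate = rep(seq_len(nr), 2L),
                      stringsAsFactors = FALSE)
  annotation <- gene_annotation(
    targets = targets[lengths(targets) > 0],
    housekeeping = hk,
    biotype = stats::setNames(rep("protein_coding", ng), gene_ids))
  structure(list(
    expression = expression_matrix(fpkm, sheet),
    annotation = annotation,
    mirna_expression = data.frame(mirna_id = mirna_ids,
                                  expression = unname(abund),
                                  stringsAsFactors = FALSE),
    truth = list(delta_true = stats::setNames(delta_true, gene_ids),
                 targets = targets,
                 library_factors = lf,
                 normalization_genes = hk),
    config = config), class = "transcriptome_simulation")
}

#' Write a simulation to TSV files
#'
#' Writes `expression.tsv`, `samples.tsv`, `target_pairs.tsv`,
#' `housekeeping.txt`, `biotype.tsv`, `mirna_expression.tsv` and
#' `truth.tsv` (gene_id, delta_true, n_targets) into `outdir`.
#'
#' @param sim A `transcriptome_simulation`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "transcriptome_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_expression(sim$expression, p("expression.tsv"), p("samples.tsv"))
  write_target_annotation(sim$annotation, p("target_pairs.tsv"),
                          p("housekeeping.txt"), p("biotype.tsv"))
  write_mirna_expression(sim$mirna_expression, p("mirna_expression.tsv"))
  write_tsv(data.frame(gene_id = names(sim$truth$delta_true),
                       delta_true = unname(sim$truth$delta_true),
                       n_targets = lengths(sim$truth$targets)),
            p("truth.tsv"))
  invisible(outdir)
}
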