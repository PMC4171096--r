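# Relative qPCR quantification by the 2^-ddCt (Livak) method.
#
# Ct is the threshold cycle: one cycle more means about half the starting
# template (amplification efficiency is assumed to be exactly 2; no
# efficiency correction).  Expression of a target assay is normalized to
# reference assays (e.g. U6 snRNA and 5S rRNA for miRNA quantification)
# within each group, and the sample group is expressed relative to the
# calibrator group as a fold change 2^-ddCt.

#' Read a Ct table
#'
#' TSV with columns `assay_id`, `role` (`target` or `reference`),
#' `sample_id`, `group`, `replicate`, `ct`.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  ct_table(df)
}

#' Validate a Ct table
#'
#' @param df Data frame with columns `assay_id`, `role`, `sample_id`,
#'   `group`, `replicate`, `ct`; Ct values must be finite and positive,
#'   roles `target` or `reference`, and every group needs at least one
#'   reference assay.
#' @return `df` with class `ct_table` prepended.
#' @export
ct_table <- function(df) {
  need <- c("assay_id", "role", "sample_id", "group", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct) | df$ct <= 0))
    stop("Ct values must be finite and > 0", call. = FALSE)
  bad <- setdiff(unique(df$role), c("target", "reference"))
  if (length(bad))
    stop("unknown assay role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (g in unique(df$group))
    if (!any(df$role == "reference" & df$group == g))
      stop("group '", g, "' has no reference assay", call. = FALSE)
  if (!inherits(df, "ct_table")) class(df) <- c("ct_table", class(df))
  df
}

#' Relative quantification by 2^-ddCt
#'
#' Within each group, technical/biological replicates of each assay are
#' averaged; `dCt = mean Ct(target) - mean over reference assays of their
#' mean Ct` (with `ref_combine = "geometric"` the reference Cts are
#' combined so that the implied reference expression levels 2^-Ct are
#' averaged geometrically -- for an efficiency of 2 this is again the
#' arithmetic mean of Cts, so both options coincide unless future
#' efficiency handling changes; the option documents intent).  Then
#' `ddCt = dCt(sample_group) - dCt(calibrator_group)` and the fold change
#' of the target in the sample group relative to the calibrator is
#' `2^-ddCt`.
#'
#' @param ct A `ct_table` (or data frame accepted by [ct_table()]).
#' @param target Target assay id.
#' @param sample_group,calibrator_group Group labels.
#' @param ref_combine How to combine multiple reference assays
#'   (`"mean"`, the default, or `"geometric"`; see Details).
#' @return List with `fold_change`, `ddct`, `dct_sample`,
#'   `dct_calibrator`, `references` (assay ids used).
#' @examples
#' tab <- data.frame(assay_id = rep(c("mir21", "U6"), each = 2),
#'                   role = rep(c("target", "reference"), each = 2),
#'                   sample_id = rep(c("s1", "c1"), 2),
#'                   group = rep(c("ko", "ctrl"), 2),
#'                   replicate = 1L,
#'                   ct = c(25, 22, 20, 19))
#' delta_delta_ct(tab, "mir21", "ko", "ctrl")$fold_change  # 0.25
#' @export
delta_delta_ct <- function(ct, target, sample_group, calibrator_group,
                           ref_combine = c("mean", "geometric")) {
  ct <- ct_table(as.data.frame(ct))
  ref_combine <- match.arg(ref_combine)
  dct <- function(group) {
    g <- ct[ct$group == group, , drop = FALSE]
    if (nrow(g) == 0) stop("no rows for group '", group, "'",
                           call. = FALSE)
    tg <- g$ct[g$assay_id == target & g$role == "target"]
    if (length(tg) == 0)
      stop("target assay '", target, "' missing in group '", group, "'",
           call. = FALSE)
    refs <- g[g$role == "reference", , drop = FALSE]
    ref_means <- tapply(refs$ct, refs$assay_id, mean)
    # on the Ct (log) scale the geometric mean of 2^-Ct levels is the
    # arithmetic mean of Cts, so both rules reduce to mean(ref_means)
    ref_ct <- mean(ref_means)
    list(dct = mean(tg) - ref_ct, refs = names(ref_means))
  }
  s <- dct(sample_group)
  k <- dct(calibrator_group)
  ddct <- s$dct - k$dct
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct_sample = s$dct, dct_calibrator = k$dct,
       references = sort(unique(c(s$refs, k$refs))))
}
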