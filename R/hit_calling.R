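# Hit calling: plate normalization against negative controls, per-replicate
# Z-scores on the normalized signal, replicate-mean aggregation and strict
# threshold classification into activators and inhibitors.

#' Normalize one plate's wells to its negative-control median
#'
#' @param rlu Named or unnamed positive raw values for the plate's wells.
#' @param control_rlu Raw values of the plate's negative-control wells.
#' @param min_controls Minimum controls required (default 3).
#' @return `rlu / median(control_rlu)`; the controls' normalized median is 1.
#' @export
normalize_plate <- function(rlu, control_rlu, min_controls = 3L) {
  if (length(control_rlu) < min_controls) {
    stop_degenerate("insufficient negative controls: ", length(control_rlu),
                    " < ", min_controls)
  }
  if (any(!is.finite(rlu)) || any(rlu <= 0)) {
    stop_validation("raw RLU must be positive and finite")
  }
  med <- stats::median(control_rlu)
  if (!is.finite(med) || med <= 0) {
    stop_degenerate("control median is not positive")
  }
  rlu / med
}

#' Normalize a whole screen plate by plate
#'
#' Every (plate, replicate) pair is scaled by the median raw signal of that
#' plate's negative-control wells, so any multiplicative plate effect cancels
#' and a null test well has expected normalized signal ~1.
#'
#' @param screen A `screen_dataset`.
#' @param min_controls Minimum negative-control wells per plate.
#' @return Data frame: plate_id, well, replicate, role, gene_id,
#'   norm_signal (fold of the plate control median).
#' @export
normalize_screen <- function(screen, min_controls = 3L) {
  if (!inherits(screen, "screen_dataset")) {
    stop_validation("screen must be a screen_dataset")
  }
  pm <- screen$platemap
  ms <- screen$measurements
  key <- paste(pm$plate_id, pm$well)
  idx <- match(paste(ms$plate_id, ms$well), key)
  out <- data.frame(plate_id = ms$plate_id, well = ms$well,
                    replicate = ms$replicate, role = pm$role[idx],
                    gene_id = pm$gene_id[idx], norm_signal = NA_real_,
                    stringsAsFactors = FALSE)
  grp <- paste(ms$plate_id, ms$replicate)
  for (g in unique(grp)) {
    sel <- grp == g
    ctrl <- ms$rlu[sel & out$role == "negative_control"]
    out$norm_signal[sel] <- normalize_plate(ms$rlu[sel], ctrl, min_controls)
  }
  out
}

#' Z-score a vector of normalized signals
#'
#' z_i = (x_i - mean(x)) / sd(x) with the sample (n-1) standard deviation.
#' The output has mean 0 and sample sd 1 by construction.
#'
#' @param values Normalized signals of one replicate's test wells.
#' @return Numeric vector of Z-scores.
#' @export
zscore <- function(values) {
  if (length(values) < 2L || length(unique(values)) < 2L) {
    stop_degenerate("zscore needs >= 2 distinct values")
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop_degenerate("zero standard deviation")
  (values - mean(values)) / s
}

#' Per-gene, per-replicate Z-scores of a normalized screen
#'
#' By default mu and sigma are computed over all test wells of one replicate
#' (plate effects are already removed by normalization), excluding control
#' wells. Alternatives — per-plate scoring and inclusion of control wells in
#' the reference population — are exposed as options.
#'
#' @param normalized Output of [normalize_screen()].
#' @param scope `"replicate"` (default) or `"plate"`: population over which
#'   mu and sigma are computed.
#' @param include_controls Include negative-control wells in mu/sigma.
#' @param log2_scale Z-score log2(normalized signal) instead of the natural
#'   scale (default off: the formula is applied to the signal data directly).
#' @return Data frame: gene_id, replicate, z.
#' @export
zscore_screen <- function(normalized, scope = c("replicate", "plate"),
                          include_controls = FALSE, log2_scale = FALSE) {
  scope <- match.arg(scope)
  x <- normalized
  x$value <- if (log2_scale) log2(x$norm_signal) else x$norm_signal
  pop <- if (include_controls) x$role != "empty" else x$role == "test"
  grp <- if (scope == "replicate") as.character(x$replicate) else {
    paste(x$replicate, x$plate_id)
  }
  x$z <- NA_real_
  for (g in unique(grp)) {
    ref <- which(grp == g & pop)
    if (length(ref) == 0) next  # plate with no population wells (all
                                # controls, empty or filtered): nothing to score
    zscore(x$value[ref])  # validates >= 2 distinct values, nonzero sd
    mu <- mean(x$value[ref])
    s <- stats::sd(x$value[ref])
    sel <- which(grp == g)
    x$z[sel] <- (x$value[sel] - mu) / s
  }
  out <- x[x$role == "test", c("gene_id", "replicate", "z")]
  rownames(out) <- NULL
  out
}

#' Aggregate per-replicate Z-scores to a per-gene mean
#'
#' @param gene_z Data frame gene_id, replicate, z from [zscore_screen()].
#' @param min_replicates Genes with fewer finite Z values are excluded with a
#'   counted warning, never imputed.
#' @return Gene Z table: gene_id, z_rep1..z_repR, mean_z, n_replicates_used.
#' @export
aggregate_replicates <- function(gene_z, min_replicates = 2L) {
  min_replicates <- check_count(min_replicates, "min_replicates", min = 1L)
  reps <- sort(unique(gene_z$replicate))
  wide <- stats::reshape(gene_z, idvar = "gene_id", timevar = "replicate",
                         direction = "wide")
  names(wide) <- sub("^z\\.", "z_rep", names(wide))
  zmat <- as.matrix(wide[, -1, drop = FALSE])
  n_used <- rowSums(is.finite(zmat))
  keep <- n_used >= min_replicates
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) excluded with fewer than ", min_replicates,
            " replicates", call. = FALSE)
  }
  out <- wide[keep, , drop = FALSE]
  out$mean_z <- rowMeans(zmat[keep, , drop = FALSE], na.rm = TRUE)
  out$n_replicates_used <- as.integer(n_used[keep])
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Classify genes as activators or inhibitors by strict Z threshold
#'
#' Silencing an activator of the readout lowers luminescence, so
#' `mean_z < -threshold` calls an activator and `mean_z > +threshold` an
#' inhibitor; both inequalities are strict, so a gene at exactly +/-
#' threshold is not a hit.
#'
#' @param gene_z_table Output of [aggregate_replicates()].
#' @param threshold Positive Z threshold (default 2 standard deviations).
#' @return The table with a `hit_class` column in
#'   `c("activator", "inhibitor", "none")`.
#' @export
call_hits <- function(gene_z_table, threshold = 2) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_validation("threshold must be a single positive number")
  }
  if (any(!is.finite(gene_z_table$mean_z))) {
    stop_validation("mean_z must be finite for all genes")
  }
  gene_z_table$hit_class <- ifelse(gene_z_table$mean_z < -threshold, "activator",
                            ifelse(gene_z_table$mean_z > threshold, "inhibitor",
                                   "none"))
  gene_z_table
}

#' Annotate hits with a viability flag
#'
#' Annotation only: a flagged gene keeps its hit class (viability effects are
#' reported alongside hits, not used to remove them).
#'
#' @param gene_z_table Gene Z table (any stage).
#' @param viability Data frame gene_id, ratio (silenced-gene viability over
#'   control, positive).
#' @param min_ratio Flag genes whose ratio falls below this (default 0.7).
#' @return Table with a logical `viability_flag` column (`NA` where the gene
#'   is absent from the viability table; absences are counted in a message).
#' @export
annotate_viability <- function(gene_z_table, viability, min_ratio = 0.7) {
  if (!all(c("gene_id", "ratio") %in% names(viability))) {
    stop_validation("viability table must have columns gene_id, ratio")
  }
  if (any(!is.finite(viability$ratio)) || any(viability$ratio <= 0)) {
    stop_validation("viability ratios must be positive")
  }
  min_ratio <- check_positive(min_ratio, "min_ratio")
  ratio <- viability$ratio[match(gene_z_table$gene_id, viability$gene_id)]
  missing_n <- sum(is.na(ratio))
  if (missing_n > 0) {
    log_stage("viability", missing_n, " gene(s) absent from viability table")
  }
  gene_z_table$viability_flag <- ratio < min_ratio
  gene_z_table
}

#' Summarize a called gene Z table
#' @param gene_z_table Output of [call_hits()].
#' @return Named list of totals per class.
#' @export
hit_summary <- function(gene_z_table) {
  list(
    genes_scored = nrow(gene_z_table),
    hits = sum(gene_z_table$hit_class != "none"),
    activators = sum(gene_z_table$hit_class == "activator"),
    inhibitors = sum(gene_z_table$hit_class == "inhibitor")
  )
}
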