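# TMT phosphosite differential regulation: decoy/contaminant/confidence
# filtering, median-centered log2 intensities, per-site two-sample t-test,
# and the dual significance threshold (p <= 0.05 and |difference| >= 0.2).

#' Filter a phosphosite table on identification confidence
#'
#' A site is retained iff it is not a reverse (decoy) hit, not a
#' contaminant, its score difference is strictly greater than 5 and its
#' localization probability strictly greater than 0.5. Sites exactly at a
#' boundary are removed. Exclusions are counted by the first failing reason
#' in the order reverse, contaminant, score difference, localization.
#'
#' @param table Wide phosphosite data frame (see [read_phospho_table()]).
#' @param min_score_diff,min_loc_prob Strict lower bounds (defaults 5, 0.5).
#' @return List with `retained` (filtered table) and `exclusions`
#'   (data frame reason, n).
#' @export
filter_sites <- function(table, min_score_diff = 5, min_loc_prob = 0.5) {
  need <- c("reverse", "contaminant", "score_diff", "localization_prob")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_validation("phosphosite table missing columns: ",
                    paste(miss, collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(table))
  reason[is.na(reason) & table$reverse] <- "reverse"
  reason[is.na(reason) & table$contaminant] <- "contaminant"
  reason[is.na(reason) & !(table$score_diff > min_score_diff)] <- "low_score_diff"
  reason[is.na(reason) & !(table$localization_prob > min_loc_prob)] <- "low_localization_prob"
  retained <- table[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  counts <- table(factor(reason, levels = c("reverse", "contaminant",
                                            "low_score_diff",
                                            "low_localization_prob")))
  exclusions <- data.frame(reason = names(counts), n = as.integer(counts),
                           stringsAsFactors = FALSE)
  log_stage("phospho_filter", nrow(retained), "/", nrow(table), " sites retained")
  list(retained = retained, exclusions = exclusions)
}

#' Log2-transform and median-center intensity columns
#'
#' Default order is log2 first, then subtraction of each sample column's
#' median, so every per-sample median is exactly 0 afterwards; the
#' operation is idempotent on centered data and invariant to per-sample
#' multiplicative scaling. The alternative order (center on the raw scale,
#' then log) is available as an option.
#'
#' @param table Phosphosite data frame.
#' @param sample_cols Names of the intensity columns.
#' @param order `"log-then-center"` (default) or `"center-then-log"`.
#' @return The table with `sample_cols` replaced by normalized log2 values.
#' @export
normalize_log <- function(table, sample_cols,
                          order = c("log-then-center", "center-then-log")) {
  order <- match.arg(order)
  miss <- setdiff(sample_cols, names(table))
  if (length(miss)) {
    stop_validation("missing intensity columns: ", paste(miss, collapse = ", "))
  }
  for (col in sample_cols) {
    v <- table[[col]]
    ok <- !is.na(v)
    if (any(v[ok] <= 0)) stop_validation("nonpositive intensity in column ", col)
    if (order == "log-then-center") {
      lv <- log2(v)
      table[[col]] <- lv - stats::median(lv, na.rm = TRUE)
    } else {
      table[[col]] <- log2(v / stats::median(v, na.rm = TRUE))
    }
  }
  table
}

# Dual-threshold significance rule: inclusive on both sides.
phospho_call <- function(difference, p, diff_threshold = 0.2, p_threshold = 0.05) {
  (p <= p_threshold) & (abs(difference) >= diff_threshold)
}

#' Per-site two-sample t-tests between conditions
#'
#' Tests each site's normalized log2 intensities, stimulated versus control,
#' with the pooled-variance Student t-test (Welch available as an option).
#' A site needs at least `min_per_group` finite values per group; others are
#' excluded and counted. Significance uses the dual threshold, inclusive on
#' both sides: `p <= p_threshold` and `|difference| >= diff_threshold`.
#' Degenerate sites with zero pooled variance get p = 1 when the group means
#' are equal, and the minimum representable p (logged) when they differ.
#'
#' @param table Normalized phosphosite data frame with `gene` and `position`
#'   columns.
#' @param group_a_cols,group_b_cols Intensity column names of the stimulated
#'   and control condition (an explicit channel-to-condition map; the
#'   difference is mean(A) - mean(B)).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @param diff_threshold,p_threshold Dual significance rule (defaults 0.2,
#'   0.05, both inclusive).
#' @param min_per_group Minimum finite values per group (default 2).
#' @return List with `results` (site_id, gene, position, residue if present,
#'   difference, t, df, p, p_adj (BH, informational), significant,
#'   direction) and `n_excluded` (sites with too few values).
#' @export
phospho_test <- function(table, group_a_cols, group_b_cols,
                         test = c("student", "welch"),
                         diff_threshold = 0.2, p_threshold = 0.05,
                         min_per_group = 2L) {
  test <- match.arg(test)
  miss <- setdiff(c(group_a_cols, group_b_cols), names(table))
  if (length(miss)) {
    stop_validation("missing intensity columns: ", paste(miss, collapse = ", "))
  }
  A <- as.matrix(table[, group_a_cols, drop = FALSE])
  B <- as.matrix(table[, group_b_cols, drop = FALSE])
  nA <- rowSums(is.finite(A))
  nB <- rowSums(is.finite(B))
  keep <- nA >= min_per_group & nB >= min_per_group
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    log_stage("phospho_test", n_excluded,
              " site(s) excluded with < ", min_per_group, " values per group")
  }
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  nA <- nA[keep]; nB <- nB[keep]
  mA <- rowMeans(A, na.rm = TRUE)
  mB <- rowMeans(B, na.rm = TRUE)
  vA <- apply(A, 1, stats::var, na.rm = TRUE)
  vB <- apply(B, 1, stats::var, na.rm = TRUE)
  diff <- mA - mB
  if (test == "student") {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  tstat <- diff / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero_var <- se == 0 | !is.finite(se)
  if (any(zero_var)) {
    eq <- zero_var & diff == 0
    p[eq] <- 1; tstat[eq] <- 0
    ne <- zero_var & diff != 0
    if (any(ne)) {
      log_stage("phospho_test", sum(ne),
                " site(s) with zero variance and unequal means; p set to minimum")
      p[ne] <- .Machine$double.xmin
      tstat[ne] <- sign(diff[ne]) * Inf
    }
  }
  kept <- table[keep, , drop = FALSE]
  results <- data.frame(
    site_id = sprintf("%s(%d)", kept$gene, kept$position),
    gene = kept$gene, position = kept$position,
    difference = diff, t = tstat, df = df, p = p,
    p_adj = bh_adjust(p),
    significant = phospho_call(diff, p, diff_threshold, p_threshold),
    direction = ifelse(diff >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  if ("residue" %in% names(kept)) results$residue <- kept$residue
  results <- results[order(results$site_id), ]
  rownames(results) <- NULL
  list(results = results, n_excluded = n_excluded)
}

#' Annotate site results with GO categories and known regulatory sites
#'
#' @param results Results data frame from [phospho_test()].
#' @param gobp_map Data frame gene, category (one row per membership);
#'   matched by uppercased gene symbol. May be empty.
#' @param regulatory_map Data frame gene, position of known regulatory
#'   sites; matched on both. May be empty.
#' @return Results with one logical column per GO category (spaces become
#'   underscores) and `known_regulatory`; unmatched sites get `FALSE`.
#' @export
annotate_sites <- function(results, gobp_map = NULL, regulatory_map = NULL) {
  if (!is.null(gobp_map) && nrow(gobp_map) > 0) {
    for (cat in sort(unique(gobp_map$category))) {
      genes <- toupper(gobp_map$gene[gobp_map$category == cat])
      col <- gsub("[^A-Za-z0-9]+", "_", tolower(cat))
      results[[col]] <- toupper(results$gene) %in% genes
    }
  }
  results$known_regulatory <- FALSE
  if (!is.null(regulatory_map) && nrow(regulatory_map) > 0) {
    key <- paste(toupper(regulatory_map$gene), regulatory_map$position)
    results$known_regulatory <-
      paste(toupper(results$gene), results$position) %in% key
  }
  results
}

#' Export a volcano-plot table
#'
#' @param results Annotated or plain results from [phospho_test()].
#' @return Data frame site_id, difference, neg_log10_p, significant,
#'   direction plus any annotation columns, ordered by site_id. No plotting
#'   is performed.
#' @export
volcano_table <- function(results) {
  base <- c("site_id", "difference", "p", "significant", "direction")
  extra <- setdiff(names(results),
                   c(base, "gene", "position", "residue", "t", "df", "p_adj"))
  if (nrow(results) == 0) {
    return(data.frame(site_id = character(0), difference = numeric(0),
                      neg_log10_p = numeric(0), significant = logical(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(site_id = results$site_id,
                    difference = results$difference,
                    neg_log10_p = -log10(results$p),
                    significant = results$significant,
                    direction = results$direction,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- results[[col]]
  out <- out[order(out$site_id), ]
  rownames(out) <- NULL
  out
}
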