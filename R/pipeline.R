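# End-to-end orchestration. Every run records its configuration hash and
# seed in a JSON sidecar; identical inputs and config reproduce identical
# output bytes (timings go to stderr, never into result files).

#' Run the screen analysis pipeline
#'
#' Stage order: expression filter (optional, when a count table is given) ->
#' restriction of the screened library to expressed genes -> plate
#' normalization -> per-replicate Z-scores -> replicate aggregation ->
#' strict threshold hit calling -> optional viability annotation. The
#' Z-score reference population contains only test wells of genes that
#' survived the expression filter.
#'
#' @param config Named list: `platemap`, `measurements` (paths; or `screen`,
#'   a `screen_dataset`), optional `counts` path, `min_median` (20),
#'   `z_threshold` (2), `min_replicates` (2), `log2_scale` (FALSE),
#'   `zscore_scope` ("replicate"), `include_controls` (FALSE), optional
#'   `viability` path + `min_viability_ratio` (0.7), `out_dir`, `seed`.
#' @return Invisibly, a list with `hits` (gene Z table) and `summary`;
#'   writes `hits.tsv` and `summary.json` under `out_dir` when given.
#' @export
run_screen_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  screen <- if (!is.null(config$screen)) config$screen else {
    read_screen(config$platemap, config$measurements)
  }
  screen_genes <- screen$platemap$gene_id[screen$platemap$role == "test"]
  log_stage("read_screen", length(screen_genes), " genes in library")

  kept <- screen_genes
  dropped <- character(0)
  if (!is.null(config$counts)) {
    counts <- if (is.character(config$counts)) read_counts(config$counts) else config$counts
    fe <- filter_expressed(counts, min_median = config$min_median %||% 20)
    r <- restrict_to_expressed(screen_genes, fe$expressed)
    kept <- r$kept
    dropped <- r$dropped
    stopifnot(length(kept) + length(dropped) == length(screen_genes))
    log_stage("expression_filter", length(kept), " kept / ",
              length(dropped), " dropped")
    if (length(kept) == 0) {
      stop_validation("no genes after expression filter")
    }
  }

  normalized <- normalize_screen(screen,
                                 min_controls = config$min_controls %||% 3L)
  # Filtered genes leave the Z reference population entirely.
  filtered_out <- normalized$role == "test" & !normalized$gene_id %in% kept
  normalized$role[filtered_out] <- "filtered"
  gene_z <- zscore_screen(normalized,
                          scope = config$zscore_scope %||% "replicate",
                          include_controls = isTRUE(config$include_controls),
                          log2_scale = isTRUE(config$log2_scale))
  tab <- aggregate_replicates(gene_z,
                              min_replicates = config$min_replicates %||% 2L)
  tab <- call_hits(tab, threshold = config$z_threshold %||% 2)
  if (!is.null(config$viability)) {
    viab <- if (is.character(config$viability)) read_tsv(config$viability) else config$viability
    tab <- annotate_viability(tab, viab,
                              min_ratio = config$min_viability_ratio %||% 0.7)
  }
  summ <- c(list(genes_in_library = length(screen_genes),
                 genes_expressed_kept = length(kept),
                 genes_dropped = length(dropped)),
            hit_summary(tab))
  log_stage("call_hits", summ$hits, " hits (", summ$activators, " activators, ",
            summ$inhibitors, " inhibitors) in ",
            round(proc.time()[["elapsed"]] - t0, 2), "s")
  if (!is.null(config$out_dir)) {
    meta <- list(stage = "screen_pipeline",
                 config = config[!vapply(config, is.object, logical(1))],
                 summary = summ)
    write_results(list(hits = tab), config$out_dir, metadata = meta)
    jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(hits = tab, summary = summ))
}

#' Run the enrichment stage
#'
#' @param config Named list: `query` (path or character vector), `gmt`
#'   (paths or a named library list), `universe` (path or vector), `alpha`
#'   (0.05), `n_permutations` (1000), `seed` (1), optional `out_dir`.
#' @return Invisibly, the enrichment result table; writes `enrichment.tsv`.
#' @export
run_enrichment <- function(config) {
  query <- if (is.character(config$query) && length(config$query) == 1 &&
               file.exists(config$query)) readLines(config$query) else config$query
  universe <- if (is.character(config$universe) && length(config$universe) == 1 &&
                  file.exists(config$universe)) readLines(config$universe) else config$universe
  library <- config$gmt
  if (is.character(library)) {
    libs <- lapply(library, read_gmt)
    if (length(libs) > 1) {
      stem <- sub("\\.gmt$", "", basename(library))
      libs <- lapply(seq_along(libs), function(i) {
        stats::setNames(libs[[i]], paste0(stem[i], ":", names(libs[[i]])))
      })
    }
    library <- do.call(c, libs)
  }
  res <- enrich(query, library, universe,
                alpha = config$alpha %||% 0.05,
                n_permutations = config$n_permutations %||% 1000L,
                seed = config$seed %||% 1L)
  log_stage("enrichment", sum(res$significant), "/", nrow(res),
            " terms significant")
  if (!is.null(config$out_dir)) {
    write_results(list(enrichment = res), config$out_dir,
                  metadata = list(stage = "enrichment",
                                  config = config[vapply(config, is.atomic, logical(1))]))
  }
  invisible(res)
}

#' Run the phosphoproteomics stage
#'
#' @param config Named list: `table` (path or data frame), `group_a_cols`,
#'   `group_b_cols` (character vectors; the explicit channel-to-condition
#'   map), `test` ("student"), `order` ("log-then-center"),
#'   `diff_threshold` (0.2), `p_threshold` (0.05), optional `gobp_map`,
#'   `regulatory_map` (paths or data frames), optional `out_dir`.
#' @return Invisibly, list with `results`, `exclusions`, `volcano`; writes
#'   `phospho_results.tsv`, `exclusions.tsv`, `volcano.tsv`.
#' @export
run_phospho_pipeline <- function(config) {
  tab <- if (is.character(config$table)) read_phospho_table(config$table) else config$table
  f <- filter_sites(tab)
  sample_cols <- c(config$group_a_cols, config$group_b_cols)
  norm <- normalize_log(f$retained, sample_cols,
                        order = config$order %||% "log-then-center")
  tt <- phospho_test(norm, config$group_a_cols, config$group_b_cols,
                     test = config$test %||% "student",
                     diff_threshold = config$diff_threshold %||% 0.2,
                     p_threshold = config$p_threshold %||% 0.05)
  res <- tt$results
  gobp <- if (is.character(config$gobp_map)) read_tsv(config$gobp_map) else config$gobp_map
  regm <- if (is.character(config$regulatory_map)) read_tsv(config$regulatory_map) else config$regulatory_map
  res <- annotate_sites(res, gobp_map = gobp, regulatory_map = regm)
  volcano <- volcano_table(res)
  exclusions <- rbind(f$exclusions,
                      data.frame(reason = "too_few_values", n = tt$n_excluded))
  log_stage("phospho", sum(res$significant), "/", nrow(res),
            " sites significant")
  if (!is.null(config$out_dir)) {
    write_results(list(phospho_results = res, exclusions = exclusions,
                       volcano = volcano),
                  config$out_dir,
                  metadata = list(stage = "phospho",
                                  config = config[vapply(config, is.atomic, logical(1))]))
  }
  invisible(list(results = res, exclusions = exclusions, volcano = volcano))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
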