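# Expression prefilter: restrict the screened library to genes actively
# transcribed in the assay cells, using a strict median read-count rule.

#' Flag expressed genes by median read count
#'
#' A gene is retained iff the median of its counts across samples is
#' strictly greater than `min_median`; a gene sitting exactly at the
#' boundary is excluded. With an even number of samples the median is the
#' mean of the two central values, so boundary behavior is well defined.
#'
#' @param counts Data frame with a `gene_id` column followed by sample
#'   columns of nonnegative counts (as from [read_counts()]), or a numeric
#'   matrix with gene rownames.
#' @param min_median Threshold (default 20 reads).
#' @return List with `expressed` (character vector, sorted) and `medians`
#'   (data frame gene_id, median_count, expressed).
#' @export
filter_expressed <- function(counts, min_median = 20) {
  if (is.matrix(counts)) {
    counts <- data.frame(gene_id = rownames(counts), counts,
                         stringsAsFactors = FALSE, row.names = NULL)
  }
  if (nrow(counts) == 0) {
    warning("empty count table: no genes pass the expression filter",
            call. = FALSE)
    return(list(expressed = character(0),
                medians = data.frame(gene_id = character(0),
                                     median_count = numeric(0),
                                     expressed = logical(0))))
  }
  mat <- as.matrix(counts[, -1, drop = FALSE])
  if (ncol(mat) < 1) stop_validation("count table needs >= 1 sample column")
  if (any(mat < 0)) stop_validation("counts must be nonnegative")
  med <- apply(mat, 1, stats::median)
  keep <- med > min_median  # strict: median == min_median is excluded
  medians <- data.frame(gene_id = counts$gene_id, median_count = med,
                        expressed = keep, stringsAsFactors = FALSE)
  medians <- medians[order(medians$gene_id), ]
  rownames(medians) <- NULL
  list(expressed = sort(counts$gene_id[keep]), medians = medians)
}

#' Intersect screened genes with the expressed set
#'
#' Matching is done after uppercasing both sides (gene-set and library
#' symbol conventions differ in case). The returned sets partition the
#' screen: `kept` and `dropped` are disjoint and their union is the input.
#'
#' @param screen_genes Character vector of genes in the screen library.
#' @param expressed Character vector of expressed genes.
#' @return List with `kept` and `dropped` character vectors (original
#'   spelling of `screen_genes`, input order preserved).
#' @export
restrict_to_expressed <- function(screen_genes, expressed) {
  hit <- toupper(screen_genes) %in% toupper(expressed)
  if (!any(hit) && length(screen_genes)) {
    warning("no screened gene is in the expressed set", call. = FALSE)
  }
  list(kept = screen_genes[hit], dropped = screen_genes[!hit])
}
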