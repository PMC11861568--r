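# Over-representation analysis: Fisher exact (hypergeometric upper tail) p,
# Benjamini-Hochberg adjustment, a permutation rank-deviation z and the
# combined score ln(p) * z, plus the gene ratio k / K.

#' Fisher exact over-representation test for one gene set
#'
#' Computes the hypergeometric upper tail P(X >= k) for drawing `k` term
#' genes in a query of size `n` from a universe of `N` genes of which `K`
#' belong to the term. Gene symbols are matched after uppercasing; query
#' genes outside the universe are dropped with a logged count.
#'
#' @param query Character vector of query genes.
#' @param term Character vector of gene-set members.
#' @param universe Character vector of background genes.
#' @return List with `k`, `K`, `n`, `N`, `p` and `overlap_genes`.
#' @export
fisher_enrich <- function(query, term, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop_validation("universe must be nonempty")
  query <- unique(toupper(query))
  outside <- sum(!query %in% universe)
  if (outside > 0) {
    log_stage("enrichment", outside, " query gene(s) outside universe dropped")
  }
  query <- intersect(query, universe)
  term <- intersect(unique(toupper(term)), universe)
  k <- length(intersect(query, term))
  K <- length(term)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p,
       overlap_genes = sort(intersect(query, term)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, clipped to 1, in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_validation("p must be numeric")
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)   # largest first for the running minimum
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Rank-deviation z for every term of a library
#'
#' Terms are ranked by Fisher p for the observed query; the same ranking is
#' repeated for `n_permutations` seeded-random queries of the same size, and
#' each term's z is its observed rank's deviation from the permutation mean
#' in permutation-sd units. A term ranked much better (smaller rank) than
#' expected by chance gets a negative z, so ln(p) * z is large and positive
#' for enriched terms.
#'
#' @param library Named list of gene sets.
#' @param query,universe Character vectors (matched after uppercasing).
#' @param n_permutations At least 100 (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return Named numeric vector of z values (0 with a warning where the
#'   permutation sd is degenerate).
#' @export
rank_z <- function(library, query, universe, n_permutations = 1000L, seed = 1L) {
  n_permutations <- check_count(n_permutations, "n_permutations", min = 100L)
  st <- enrich_stats(library, query, universe)
  obs_rank <- rank(st$p, ties.method = "average")
  null_ranks <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      qi <- sample.int(st$N, st$n)
      kb <- vapply(st$term_idx, function(ix) sum(ix %in% qi), integer(1))
      pb <- stats::phyper(kb - 1L, st$K, st$N - st$K, st$n, lower.tail = FALSE)
      rank(pb, ties.method = "average")
    }, numeric(length(st$term_idx)))
  })
  # single-term libraries: vapply simplifies to a vector
  null_ranks <- matrix(null_ranks, nrow = length(st$term_idx))
  mu <- rowMeans(null_ranks)
  sdv <- apply(null_ranks, 1, stats::sd)
  z <- (obs_rank - mu) / sdv
  bad <- !is.finite(z)
  if (any(bad)) {
    warning(sum(bad), " term(s) with degenerate permutation rank sd; z set to 0",
            call. = FALSE)
    z[bad] <- 0
  }
  stats::setNames(z, names(library))
}

# Shared bookkeeping: uppercase everything, restrict to universe, count
# overlaps for the observed query.
enrich_stats <- function(library, query, universe) {
  if (!length(library)) stop_validation("gene-set library must be nonempty")
  universe <- sort(unique(toupper(universe)))
  if (length(universe) == 0) stop_validation("universe must be nonempty")
  query <- unique(toupper(query))
  outside <- sum(!query %in% universe)
  if (outside > 0) {
    log_stage("enrichment", outside, " query gene(s) outside universe dropped")
  }
  query <- intersect(query, universe)
  term_idx <- lapply(library, function(g) {
    which(universe %in% unique(toupper(g)))
  })
  qidx <- which(universe %in% query)
  k <- vapply(term_idx, function(ix) sum(ix %in% qidx), integer(1))
  K <- lengths(term_idx)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(term_idx = term_idx, query = query, universe = universe,
       k = k, K = K, n = n, N = N, p = p)
}

#' Score a query gene list against a gene-set library
#'
#' One row per term: overlap `k`, query size `n`, term size within the
#' universe `K`, universe size `N`, Fisher p, BH-adjusted p, rank-deviation
#' z, combined score `ln(p) * z` (with `abs_combined_score` alongside),
#' gene ratio `k / K`, overlap genes, and a significance flag
#' `p_adj < alpha` (strict). Rows are sorted by combined score descending.
#'
#' @param query,universe Character vectors of gene symbols.
#' @param library Named list of gene sets (as from [read_gmt()]).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param n_permutations,seed Passed to the rank-deviation permutation.
#' @return Data frame of per-term results.
#' @export
enrich <- function(query, library, universe, alpha = 0.05,
                   n_permutations = 1000L, seed = 1L) {
  check_fraction(alpha, "alpha")
  st <- enrich_stats(library, query, universe)
  z <- rank_z(library, query, universe, n_permutations = n_permutations,
              seed = seed)
  combined <- log(st$p) * z
  p_adj <- bh_adjust(st$p)
  overlap <- vapply(st$term_idx, function(ix) {
    paste(st$universe[intersect(ix, which(st$universe %in% st$query))],
          collapse = ",")
  }, character(1))
  res <- data.frame(
    term = names(library),
    k = st$k, n = st$n, K = st$K, N = st$N,
    p = st$p, p_adj = p_adj, z_rank = unname(z),
    combined_score = unname(combined),
    abs_combined_score = abs(unname(combined)),
    gene_ratio = ifelse(st$K > 0, st$k / st$K, NA_real_),
    significant = p_adj < alpha,
    overlap_genes = unname(overlap),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$combined_score, res$p, res$term), ]
  rownames(res) <- NULL
  res
}
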