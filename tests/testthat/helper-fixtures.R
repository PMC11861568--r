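# Fixture builders shared across test files. Everything is generated in
# code; no binary or stored data.

# A minimal hand-built screen: `n_plates` plates of a tiny 2 x 3 format,
# `genes_per_plate` test wells and 3 controls per plate, constant RLU unless
# a `rlu` function(gene_id, replicate) is supplied.
toy_screen <- function(n_plates = 1L, n_replicates = 1L, genes_per_plate = 3L,
                       rlu_fun = function(gene, rep) 100) {
  stopifnot(genes_per_plate <= 3)
  wells <- c("A1", "A2", "A3", "B1", "B2", "B3")
  pm <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    gene <- c(sprintf("G%d_%d", p, seq_len(genes_per_plate)),
              rep(NA, 3 - genes_per_plate))
    data.frame(plate_id = sprintf("P%02d", p), well = wells,
               role = c(rep("test", genes_per_plate),
                        rep("empty", 3 - genes_per_plate),
                        rep("negative_control", 3)),
               gene_id = c(gene, rep(NA, 3)),
               control_type = c(rep(NA, 3), "GFP", "Scrambled", "AllStars"),
               stringsAsFactors = FALSE)
  }))
  measured <- pm[pm$role != "empty", ]
  ms <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(plate_id = measured$plate_id, well = measured$well,
               replicate = r,
               rlu = mapply(rlu_fun, measured$gene_id, r),
               stringsAsFactors = FALSE)
  }))
  rownames(ms) <- NULL
  new_screen_dataset(pm, ms, plate_rows = 2L, plate_cols = 3L)
}

# Independent hypergeometric upper-tail oracle: binomial-coefficient
# enumeration, no calls into stats::*hyper.
hyper_tail_oracle <- function(k, K, N, n) {
  xs <- k:min(n, K)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Six-site phosphosite fixture used by the filter tests: one reverse, one
# contaminant, one below the localization bound, three clean.
phospho_fixture <- function() {
  data.frame(
    gene = c("AAA1", "BBB2", "CCC3", "SHANK3", "MICAL3", "DDD4"),
    protein = sprintf("PR%02d", 1:6),
    position = c(10L, 20L, 30L, 40L, 120L, 60L),
    residue = c("S", "T", "S", "S", "Y", "S"),
    localization_prob = c(0.99, 0.9, 0.3, 0.95, 0.8, 0.97),
    score_diff = c(20, 30, 40, 25, 12, 50),
    reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    contaminant = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stim_1 = 2^c(10, 11, 12, 10.5, 11.5, 12.5),
    stim_2 = 2^c(10.1, 11.1, 12.1, 10.6, 11.6, 12.6),
    ctrl_1 = 2^c(10.0, 11.2, 12.0, 10.4, 11.4, 12.4),
    ctrl_2 = 2^c(10.2, 11.0, 12.2, 10.7, 11.3, 12.7),
    stringsAsFactors = FALSE
  )
}
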