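test_that("screen simulation is deterministic and conserves the design", {
  cfg <- screen_sim_config(n_genes = 200, n_plates_per_replicate = 2,
                           n_replicates = 2, n_controls_per_plate = 16,
                           activator_genes = 10, inhibitor_genes = 5,
                           seed = 11)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)

  # every gene occupies exactly one test well, measured once per replicate
  pm <- a$screen$platemap
  expect_identical(sort(pm$gene_id[pm$role == "test"]), sort(a$truth$gene_id))
  ms <- a$screen$measurements
  per_rep <- table(ms$replicate)
  expect_true(all(per_rep == sum(pm$role != "empty")))
  expect_identical(as.integer(table(factor(a$truth$class,
                                           c("activator", "inhibitor", "null")))),
                   c(10L, 5L, 185L))
  expect_true(all(ms$rlu > 0))

  # a different seed moves the layout
  c2 <- screen_sim_config(n_genes = 200, n_plates_per_replicate = 2,
                          n_replicates = 2, n_controls_per_plate = 16,
                          activator_genes = 10, inhibitor_genes = 5,
                          seed = 12)
  expect_false(identical(simulate_screen(c2)$screen$measurements$rlu,
                         a$screen$measurements$rlu))
})

test_that("screen simulation with no planted effects yields only null genes", {
  cfg <- screen_sim_config(n_genes = 50, n_plates_per_replicate = 1,
                           n_replicates = 1, n_controls_per_plate = 8, seed = 3)
  sim <- simulate_screen(cfg)
  expect_true(all(sim$truth$class == "null"))
  expect_true(all(sim$truth$fold == 1))
})

test_that("screen config rejects impossible designs", {
  expect_error(screen_sim_config(n_genes = 400, n_plates_per_replicate = 1,
                                 n_controls_per_plate = 0),
               "insufficient test wells", class = "lumiscreen_validation_error")
  expect_error(screen_sim_config(n_genes = 10, noise_cv = 0),
               "noise_cv", class = "lumiscreen_validation_error")
  expect_error(screen_sim_config(n_genes = 10, activator_effect = 1.2),
               class = "lumiscreen_validation_error")
  expect_error(screen_sim_config(n_genes = 10, inhibitor_effect = 0.9),
               class = "lumiscreen_validation_error")
})

test_that("planted activators land at their fold after normalization", {
  cfg <- screen_sim_config(n_genes = 3000, n_plates_per_replicate = 9,
                           n_replicates = 1, n_controls_per_plate = 32,
                           activator_genes = 150, activator_effect = 0.5,
                           noise_cv = 0.1, seed = 99)
  sim <- simulate_screen(cfg)
  norm <- normalize_screen(sim$screen)
  act <- sim$truth$gene_id[sim$truth$class == "activator"]
  m <- mean(norm$norm_signal[norm$gene_id %in% act])
  expect_gt(m, 0.47)
  expect_lt(m, 0.53)
})

test_that("count simulation separates expressed medians from the boundary", {
  one <- simulate_counts(60, expressed_fraction = 1, seed = 5)
  expect_identical(filter_expressed(one$counts)$expressed, one$expressed)
  none <- simulate_counts(60, expressed_fraction = 0, seed = 5)
  expect_length(filter_expressed(none$counts)$expressed, 0)

  mix <- simulate_counts(100, expressed_fraction = 0.4, seed = 17)
  expect_length(mix$expressed, 40)
  expect_identical(filter_expressed(mix$counts)$expressed, mix$expressed)
  expect_identical(simulate_counts(100, expressed_fraction = 0.4, seed = 17),
                   mix)
})

test_that("gmt simulation plants a detectably enriched term", {
  universe <- sprintf("G%04d", 1:1000)
  query <- sprintf("G%04d", 1:20)
  lib <- simulate_gmt(15, term_size_range = c(10, 10), universe = universe,
                      query = query, enriched_overlap = 8, seed = 21)
  expect_identical(lib$enriched_term, "PLANTED_TERM")
  expect_length(intersect(lib$library$PLANTED_TERM, toupper(query)), 8)

  # enumeration oracle on the planted configuration
  p_oracle <- hyper_tail_oracle(k = 8, K = 10, N = 1000, n = 20)
  expect_lt(p_oracle, 1e-6)
  fe <- fisher_enrich(query, lib$library$PLANTED_TERM, universe)
  expect_equal(fe$p, p_oracle, tolerance = 1e-12)

  # maximal enrichment: query identical to a term gives the library minimum p
  lib2 <- simulate_gmt(5, term_size_range = c(8, 12), universe = universe,
                       seed = 4)
  term <- lib2$library[[3]]
  ps <- vapply(lib2$library, function(g) fisher_enrich(term, g, universe)$p,
               numeric(1))
  expect_identical(unname(which.min(ps)), 3L)

  # identical file bytes under the same seed
  f1 <- tempfile(fileext = ".gmt"); f2 <- tempfile(fileext = ".gmt")
  simulate_gmt(6, c(5, 9), universe, seed = 9, path = f1)
  simulate_gmt(6, c(5, 9), universe, seed = 9, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_gmt(3, c(10, 2000), universe, seed = 1),
               "exceeds universe", class = "lumiscreen_validation_error")
})

test_that("phospho simulation honors flags, truth and replicate structure", {
  cfg <- phospho_sim_config(n_sites = 300, n_regulated = 50, seed = 8)
  a <- simulate_phospho(cfg)
  expect_identical(a, simulate_phospho(cfg))
  expect_identical(sum(a$truth$regulated), 50L)
  expect_true(all(!a$truth$reverse[a$truth$regulated]))
  expect_identical(ncol(a$table), 8L + 2L * 4L)
  expect_true(all(as.matrix(a$table[, 9:16]) > 0))

  allrev <- simulate_phospho(phospho_sim_config(n_sites = 40, frac_reverse = 1,
                                                frac_contaminant = 0, seed = 2))
  expect_identical(nrow(filter_sites(allrev$table)$retained), 0L)

  expect_error(phospho_sim_config(n_sites = 10, n_regulated = 11),
               class = "lumiscreen_validation_error")
  expect_error(phospho_sim_config(n_sites = 10, frac_reverse = 0.7,
                                  frac_contaminant = 0.7),
               class = "lumiscreen_validation_error")
})

test_that("planted phospho regulation is recovered with high power", {
  cfg <- phospho_sim_config(n_sites = 500, n_regulated = 150,
                            group_difference = 1.0, within_group_sd = 0.2,
                            seed = 31)
  sim <- simulate_phospho(cfg)
  f <- filter_sites(sim$table)
  cols <- c(sprintf("stim_%d", 1:4), sprintf("ctrl_%d", 1:4))
  norm <- normalize_log(f$retained, cols)
  res <- phospho_test(norm, sprintf("stim_%d", 1:4), sprintf("ctrl_%d", 1:4))$results
  m <- merge(res, sim$truth, by = "site_id")
  reg <- m[m$regulated, ]
  called <- reg$significant &
    sign(reg$difference) == sign(reg$log2_effect)
  expect_gte(mean(called), 0.95)
})
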