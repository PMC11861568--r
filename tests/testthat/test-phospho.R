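test_that("site filtering is strict at both confidence boundaries", {
  tab <- phospho_fixture()
  f <- filter_sites(tab)
  expect_identical(nrow(f$retained), 3L)  # 1 reverse, 1 contaminant, 1 low-prob
  expect_identical(sum(f$exclusions$n), 3L)
  expect_setequal(f$retained$gene, c("SHANK3", "MICAL3", "DDD4"))

  # exact boundaries are removed: loc prob 0.5 and score difference 5
  tab$reverse <- FALSE; tab$contaminant <- FALSE
  tab$localization_prob <- c(0.5, 0.51, 0.9, 0.9, 0.9, 0.9)
  tab$score_diff <- c(10, 10, 5, 5.01, 10, 10)
  f2 <- filter_sites(tab)
  expect_setequal(f2$retained$gene, c("BBB2", "SHANK3", "MICAL3", "DDD4"))
  expect_identical(f2$exclusions$n[f2$exclusions$reason == "low_score_diff"], 1L)
  expect_identical(
    f2$exclusions$n[f2$exclusions$reason == "low_localization_prob"], 1L)

  expect_error(filter_sites(tab[, setdiff(names(tab), "score_diff")]),
               "missing columns", class = "lumiscreen_validation_error")
})

test_that("normalize_log centers log2 intensities per sample", {
  tab <- data.frame(gene = c("A", "B", "C"), position = 1:3,
                    s1 = c(4, 8, 16))
  out <- normalize_log(tab, "s1")
  expect_equal(out$s1, c(-1, 0, 1))  # log2 {2,3,4} centered at 3

  # idempotent on centered data; invariant to per-sample scaling
  out2 <- normalize_log(transform(out, s1 = 2^s1), "s1")
  expect_equal(out2$s1, out$s1)
  scaled <- normalize_log(transform(tab, s1 = s1 * 8), "s1")
  expect_equal(scaled$s1, out$s1)

  expect_error(normalize_log(transform(tab, s1 = c(0, 1, 2)), "s1"),
               "nonpositive", class = "lumiscreen_validation_error")
  # alternative order: center on the raw scale, then log
  alt <- normalize_log(tab, "s1", order = "center-then-log")
  expect_equal(alt$s1, log2(c(4, 8, 16) / 8))
})

test_that("the site t-test matches the closed-form Student distribution", {
  A <- c(0.0, 0.1, -0.1, 0.0)
  B <- c(0.5, 0.6, 0.4, 0.5)
  tab <- data.frame(gene = "X", position = 1L,
                    a1 = A[1], a2 = A[2], a3 = A[3], a4 = A[4],
                    b1 = B[1], b2 = B[2], b3 = B[3], b4 = B[4])
  res <- phospho_test(tab, sprintf("a%d", 1:4), sprintf("b%d", 1:4))$results
  expect_equal(res$difference, -0.5)
  expect_identical(res$direction, "down")
  # closed-form oracle: pooled t with 6 df, computed from first principles
  sp2 <- (3 * stats::var(A) + 3 * stats::var(B)) / 6
  t_hand <- (mean(A) - mean(B)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * stats::pt(abs(t_hand), df = 6, lower.tail = FALSE)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  expect_identical(res$df, 6)
  # independent route: stats::t.test
  ref <- stats::t.test(A, B, var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_true(res$significant)

  welch <- phospho_test(tab, sprintf("a%d", 1:4), sprintf("b%d", 1:4),
                        test = "welch")$results
  ref_w <- stats::t.test(A, B)
  expect_equal(welch$p, ref_w$p.value, tolerance = 1e-12)
  expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-12)
})

test_that("the dual significance threshold is inclusive on both sides", {
  expect_true(lumiscreen:::phospho_call(difference = 0.2, p = 0.05))
  expect_true(lumiscreen:::phospho_call(difference = -0.2, p = 0.04))
  expect_false(lumiscreen:::phospho_call(difference = 0.1999, p = 0.001))
  expect_false(lumiscreen:::phospho_call(difference = 0.9, p = 0.0501))
})

test_that("degenerate variance cases follow the stated contracts", {
  tab <- data.frame(gene = c("EQ", "NE"), position = c(1L, 2L),
                    a1 = c(1, 1), a2 = c(1, 1), b1 = c(1, 2), b2 = c(1, 2))
  res <- phospho_test(tab, c("a1", "a2"), c("b1", "b2"))$results
  eq <- res[res$gene == "EQ", ]
  expect_equal(eq$p, 1)
  expect_equal(eq$difference, 0)
  expect_false(eq$significant)
  ne <- res[res$gene == "NE", ]
  expect_equal(ne$p, .Machine$double.xmin)
  expect_true(ne$significant)

  # identical groups -> difference 0, p = 1
  same <- data.frame(gene = "S", position = 1L,
                     a1 = 0.3, a2 = 0.7, a3 = 0.5, a4 = 0.4,
                     b1 = 0.3, b2 = 0.7, b3 = 0.5, b4 = 0.4)
  r <- phospho_test(same, sprintf("a%d", 1:4), sprintf("b%d", 1:4))$results
  expect_equal(r$difference, 0)
  expect_equal(r$p, 1)

  # sites with too few values per group are excluded and counted
  sparse <- data.frame(gene = c("OK", "NO"), position = c(1L, 2L),
                       a1 = c(1, 2), a2 = c(1.2, NA), b1 = c(2, 3),
                       b2 = c(2.2, 3.3))
  out <- phospho_test(sparse, c("a1", "a2"), c("b1", "b2"))
  expect_identical(out$n_excluded, 1L)
  expect_identical(out$results$gene, "OK")
})

test_that("annotation attaches GO categories and known regulatory sites", {
  tab <- phospho_fixture()
  f <- filter_sites(tab)
  norm <- normalize_log(f$retained, c("stim_1", "stim_2", "ctrl_1", "ctrl_2"))
  res <- phospho_test(norm, c("stim_1", "stim_2"), c("ctrl_1", "ctrl_2"))$results
  expect_identical(res$site_id[res$gene == "MICAL3"], "MICAL3(120)")

  gobp <- data.frame(gene = c("SHANK3", "MICAL3"),
                     category = c("cell adhesion", "cytoskeleton organization"))
  regm <- data.frame(gene = "MICAL3", position = 120L)
  ann <- annotate_sites(res, gobp, regm)
  expect_true(ann$cell_adhesion[ann$gene == "SHANK3"])
  expect_false(ann$cell_adhesion[ann$gene == "MICAL3"])
  expect_true(ann$known_regulatory[ann$gene == "MICAL3"])
  expect_false(any(ann$known_regulatory[ann$gene != "MICAL3"]))

  bare <- annotate_sites(res)
  expect_false(any(bare$known_regulatory))
})

test_that("volcano export is a deterministic reshaping of the results", {
  res <- data.frame(site_id = c("B(2)", "A(1)", "C(3)"),
                    gene = c("B", "A", "C"), position = c(2L, 1L, 3L),
                    difference = c(0.5, -0.3, 0), t = c(3, -2, 0),
                    df = rep(6, 3), p = c(0.01, 0.2, 1),
                    p_adj = c(0.03, 0.3, 1),
                    significant = c(TRUE, FALSE, FALSE),
                    direction = c("up", "down", "up"))
  v <- volcano_table(res)
  expect_identical(v$site_id, c("A(1)", "B(2)", "C(3)"))
  expect_equal(v$neg_log10_p, -log10(c(0.2, 0.01, 1)))
  expect_identical(names(v)[1:5],
                   c("site_id", "difference", "neg_log10_p", "significant",
                     "direction"))
  empty <- volcano_table(res[0, ])
  expect_identical(nrow(empty), 0L)
})
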