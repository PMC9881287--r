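# Mann-Whitney U, Bonferroni, fold change, gate comparison and volcano.

test_that("exact Mann-Whitney p matches hand-enumerated cases", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1)   # 2 of the C(6,3)=20 assignments are as extreme
  expect_true(mw$exact)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)

  const <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(const$U, 10)       # n1*n2/2
  expect_equal(const$p.value, 1)
})

test_that("the exact branch equals full-permutation enumeration, ties included", {
  set.seed(202)
  for (rep in 1:40) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sample(0:5, na, replace = TRUE)  # integer values force midrank ties
    b <- sample(0:5, nb, replace = TRUE)
    got <- mann_whitney_u(a, b, exact = TRUE)$p.value
    expect_equal(got, perm_mwu_p(a, b), tolerance = 1e-12,
                 info = sprintf("rep %d: a=%s b=%s", rep,
                                paste(a, collapse = ","), paste(b, collapse = ",")))
  }
})

test_that("the normal approximation agrees with wilcox.test on larger groups", {
  set.seed(303)
  for (rep in 1:20) {
    a <- round(rnorm(30, 0, 2), 1)  # rounding induces ties
    b <- round(rnorm(25, 0.5, 2), 1)
    got <- mann_whitney_u(a, b)
    expect_false(got$exact)
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE, exact = FALSE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bonferroni scales, caps, and matches p.adjust when m = length(p)", {
  expect_equal(bonferroni(0.01, m = 10), 0.1)
  expect_equal(bonferroni(0.2, m = 10), 1)
  expect_equal(bonferroni(0.37, m = 1), 0.37)
  p <- c(0.001, 0.02, 0.4, 1)
  expect_equal(bonferroni(p), stats::p.adjust(p, method = "bonferroni"))
  expect_error(bonferroni(1.2), class = "spotgate_stat_error")
  expect_error(bonferroni(p, m = 2), class = "spotgate_stat_error")
})

test_that("fold change is the ratio of group means, flagged when undefined", {
  fc <- fold_change(c(3, 5), c(1, 3))
  expect_equal(fc$fc, 2)
  expect_equal(fc$log2fc, 1)
  expect_identical(fc$flag, "ok")

  swapped <- fold_change(c(1, 3), c(3, 5))
  expect_equal(swapped$fc, 0.5)
  expect_equal(swapped$log2fc, -1)

  undef <- fold_change(c(1, 2), c(-1, 1))
  expect_identical(undef$flag, "fc_undefined")
  expect_true(is.na(undef$fc))
  # an offset can rescue signed scores, explicitly
  expect_identical(fold_change(c(1, 2), c(-1, 1), offset = 10)$flag, "ok")
})

test_that("compare_gates recovers a planted effect and flags degenerate input", {
  ds <- make_dataset(synthetic_spec(n_rows = 10, n_cols = 10, n_features = 40,
                                    n_planted = 1, effect_size = 3, seed = 77))
  cmp <- compare_gates(ds$spots, ds$gates, mode = "group1_vs_rest")
  expect_s3_class(cmp, "comparison_table")
  expect_equal(nrow(cmp), 40)
  expect_equal(attr(cmp, "m"), 40)
  expect_identical(cmp$feature[which.min(cmp$p_adj)], ds$truth$planted)
  expect_true(all(cmp$p_raw <= cmp$p_adj & cmp$p_adj <= 1))
  expect_equal(cmp$p_adj, pmin(1, attr(cmp, "m") * cmp$p_raw))

  tab <- ds$spots
  tab$flat <- 1  # constant feature: no information, p = 1
  cmp2 <- compare_gates(tab, ds$gates, mode = "group1_vs_rest", features = "flat")
  expect_equal(cmp2$p_raw, 1)

  # group1 covering every spot leaves an empty rest
  W <- dim(ds$image)[2]; H <- dim(ds$image)[1]
  univ <- polygon_gate("univ", cbind(c(-1, W + 1, W + 1, -1),
                                     c(-1, -1, H + 1, H + 1)), group = "group1")
  expect_error(compare_gates(tab, gate_set(list(univ)), mode = "group1_vs_rest"),
               class = "spotgate_grouping_error")
  expect_error(compare_gates(tab, gate_set(list(square_gate(group = "group1"))),
                             mode = "group1_vs_group2"),
               class = "spotgate_grouping_error")
})

test_that("swapping group labels inverts fold changes and leaves p untouched", {
  ds <- halved_dataset(seed = 9, n_features = 30)
  gs <- ds$gates
  swapped <- gate_set(list(
    polygon_gate("left", gs$left$vertices, group = "group2"),
    polygon_gate("right", gs$right$vertices, group = "group1")))
  cmp <- compare_gates(ds$spots, gs)
  cmp_sw <- compare_gates(ds$spots, swapped)
  expect_identical(cmp$p_raw, cmp_sw$p_raw)
  expect_identical(cmp$p_adj, cmp_sw$p_adj)
  ok <- cmp$flag == "ok" & cmp_sw$flag == "ok"
  expect_equal(cmp_sw$fc[ok], 1 / cmp$fc[ok])
  expect_equal(cmp_sw$log2fc[ok], -cmp$log2fc[ok])
})

test_that("overlapping group membership is excluded with a warning", {
  ds <- small_dataset(seed = 13, n_features = 5)
  W <- dim(ds$image)[2]; H <- dim(ds$image)[1]
  g1 <- polygon_gate("g1", cbind(c(0, 0.7 * W, 0.7 * W, 0), c(0, 0, H, H)),
                     group = "group1")
  g2 <- polygon_gate("g2", cbind(c(0.3 * W, W, W, 0.3 * W), c(0, 0, H, H)),
                     group = "group2")
  expect_warning(cmp <- compare_gates(ds$spots, gate_set(list(g1, g2))),
                 "both groups")
  xy <- spot_coords(ds$spots)
  only1 <- point_in_polygon(xy[, 1], xy[, 2], g1) & !point_in_polygon(xy[, 1], xy[, 2], g2)
  expect_equal(attr(cmp, "n1"), sum(only1))
})

test_that("volcano points transform the comparison table as advertised", {
  cmp <- structure(
    data.frame(feature = c("null", "up", "flagged", "tiny"),
               n1 = 5, n2 = 5,
               fc = c(1, 2, NA, 4), log2fc = c(0, 1, NA, 2),
               p_raw = c(1, 0.01, 0.5, 0), p_adj = c(1, 0.01, 0.5, 0),
               flag = c("ok", "ok", "fc_undefined", "ok")),
    m = 4L, mode = "group1_vs_group2", n1 = 5L, n2 = 5L,
    class = c("comparison_table", "data.frame"))
  pts <- volcano_points(cmp)
  expect_identical(pts$feature, c("null", "up", "tiny"))  # flagged row dropped
  expect_equal(pts$x[1:2], c(0, 1))
  expect_equal(pts$y[1:2], c(0, 2))
  expect_equal(pts$y[3], 300)  # p floored at 1e-300
})

test_that("select_feature projects the source column and finds planted effects", {
  ds <- make_dataset(synthetic_spec(n_rows = 10, n_cols = 10, n_features = 30,
                                    n_planted = 1, effect_size = 3, seed = 55))
  cmp <- compare_gates(ds$spots, ds$gates, mode = "group1_vs_rest")
  f <- cmp$feature[1]
  v <- select_feature(cmp, f, ds$spots)
  expect_identical(unname(v), ds$spots[[f]])
  expect_identical(names(v), spot_ids(ds$spots))
  expect_error(select_feature(cmp, "nope", ds$spots), class = "spotgate_lookup_error")

  ok <- cmp$flag == "ok"
  top <- cmp$feature[ok][which.max(abs(cmp$log2fc[ok]))]
  expect_identical(top, ds$truth$planted)
})

test_that("comparison tables round-trip through TSV with the m header", {
  ds <- halved_dataset(seed = 4, n_features = 8)
  cmp <- compare_gates(ds$spots, ds$gates)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_comparison_table(cmp, f)
  expect_match(readLines(f, n = 1), "features_tested=8")
  back <- read_comparison_table(f)
  expect_equal(attr(back, "m"), attr(cmp, "m"))
  expect_equal(back$p_adj, cmp$p_adj, tolerance = 1e-12)
  expect_identical(back$feature, cmp$feature)
})
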