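lct <- referenceCounts("layer_counts")

test_that("expected counts follow the marginal product rule", {
  obs <- contingency2x2(lct, "II")
  e <- expectedCounts(obs)
  expect_equal(e["SS", "shaft"], 57 * 130 / 968, tolerance = 1e-12)
  expect_equal(round(e["SS", "shaft"], 2), 7.65)
  expect_equal(rowSums(e), rowSums(obs))
  expect_equal(colSums(e), colSums(obs))
  expect_equal(sum(obs - e), 0, tolerance = 1e-9)
  obs4 <- contingency2x2(lct, "IV")
  expect_equal(round(expectedCounts(obs4)["SS", "shaft"], 2), 35.98)
  # an all-zero row stays zero
  z <- rbind(AS = c(10, 5), SS = c(0, 0))
  expect_equal(expectedCounts(z)["SS", ], c(0, 0), ignore_attr = TRUE)
  expect_error(expectedCounts(matrix(0, 2, 2)), "zero total")
})

test_that("enrichment ratios reproduce the published cells", {
  expect_equal(round(enrichmentRatio(contingency2x2(lct, "II")), 2), 5.75)
  expect_equal(round(enrichmentRatio(contingency2x2(lct, "IV")), 2), 2.70)
  perfect <- rbind(AS = c(90, 10), SS = c(9, 1))
  for (rw in 1:2) for (cl in 1:2)
    expect_equal(unname(enrichmentRatio(perfect, rw, cl)), 1, tolerance = 1e-12)
})

test_that("association is rejected in every layer", {
  for (ly in c("I", "II", "III", "IV", "V", "VI")) {
    ht <- chisqAssociation(contingency2x2(lct, ly))
    expect_identical(ht$df, 1L)
    expect_lt(ht$p.value, 1e-4)
  }
  perfect <- rbind(AS = c(90, 10), SS = c(9, 1))
  ht <- chisqAssociation(perfect)
  expect_equal(ht$statistic, 0, tolerance = 1e-9)
  expect_equal(ht$p.value, 1, tolerance = 1e-9)
})

test_that("chi-squared p agrees with a fixed-margin permutation oracle", {
  obs <- rbind(AS = c(28, 12), SS = c(11, 19))
  ht <- chisqAssociation(obs)
  set.seed(8)
  draws <- r2dtable(1e5, rowSums(obs), colSums(obs))
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  pPerm <- mean(vapply(draws, stat, numeric(1)) >= ht$statistic - 1e-9)
  expect_lt(abs(ht$p.value - pPerm), 0.02)
})

test_that("rank tests match exhaustive enumeration on small samples", {
  groups <- list(c(1.3, 2.7, 9.1), c(0.4, 5.5), c(7.2, 3.3, 8.8))
  ours <- kruskalWallis(groups)
  oracle <- kwOracle(groups)
  expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-9)
  expect_equal(ours$p.value, oracle$p.value, tolerance = 1e-9)
  expect_identical(ours$method, "exact")

  a <- c(1.1, 3.2, 5.9); b <- c(2.4, 7.7, 8.1, 9.3)
  ours <- mannWhitney(a, b)
  oracle <- mwOracle(a, b)
  expect_equal(unname(ours$statistic), oracle$statistic)
  expect_equal(ours$p.value, oracle$p.value, tolerance = 1e-9)

  expect_error(kruskalWallis(list(1:3)), "length")
  # identical groups: no evidence of difference
  same <- kruskalWallis(list(c(2, 2, 5), c(2, 5, 2)))
  expect_lt(same$statistic, 0.5)
  expect_gt(same$p.value, 0.9)
})

test_that("large-sample rank tests fall back to the classic approximations", {
  set.seed(2)
  g <- list(rnorm(15), rnorm(15, 1), rnorm(15))
  ours <- kruskalWallis(g)
  ref <- kruskal.test(unlist(g), rep(1:3, each = 15))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("the percentage table reconstructs every printed value", {
  t1 <- buildTable1(lct)
  printed <- rbind(
    AS_head = c(70.95, 84.09, 76.51, 69.93, 72.71, 69.27, 73.91),
    AS_neck = c(1.17, 1.14, 1.97, 2.20, 1.52, 1.82, 1.64),
    AS_shaft = c(15.36, 8.88, 13.74, 15.16, 17.23, 18.00, 14.73),
    SS_head = c(2.50, 0.72, 0.82, 4.24, 0.91, 2.55, 1.96),
    SS_neck = c(1.50, 0.62, 0.27, 0.57, 0.46, 0.73, 0.69),
    SS_shaft = c(8.51, 4.55, 6.68, 7.91, 7.16, 7.64, 7.08))
  got <- as.matrix(t1[rownames(printed), ])
  expect_true(all(abs(got - printed) <= 0.01 + 1e-9))
  # per-layer percentages sum to 100
  expect_true(all(abs(t1["Total", 1:6] - 100) < 0.01))
})

test_that("layer-averaged summary matches the published means", {
  s <- censusSummary(lct)
  expect_lt(abs(s[["mean_AS_pct"]] - 90.28), 0.011)
  expect_lt(abs(s[["mean_axospinous_pct"]] - 78.20), 0.011)
  expect_lt(abs(s[["mean_SS_on_shaft_pct"]] - 74.53), 0.011)
  expect_lt(abs(s[["heads_among_axospinous_pct"]] - 97.02), 0.011)
})

test_that("the density table splits densities by the count-derived shares", {
  t3 <- buildTable3(lct)
  expect_equal(unlist(t3["pct_spine", 1:6]),
               c(76.13, 86.57, 79.58, 76.94, 75.61, 74.36),
               tolerance = 0.006, ignore_attr = TRUE)
  expect_equal(t3["density_all", "Avg"], 0.89, tolerance = 0.006)
  expect_equal(t3["density_spine", "I"], 0.83 * 0.7613, tolerance = 0.001)
  expect_equal(t3["pct_SS_shaft", "Avg"], 74.53, tolerance = 0.006)
  # density rows are consistent: spine + shaft = total
  expect_equal(unlist(t3["density_spine", ] + t3["density_shaft", ]),
               unlist(t3["density_all", ]), tolerance = 1e-9)
})

test_that("bookkeeping and the spiny lower bound reproduce", {
  bk <- referenceCounts("bookkeeping")
  expect_equal(truncationShare(bk[["identified"]], bk[["truncated"]]),
               18.28, tolerance = 0.005)
  expect_equal(spinyLowerBound(lct, referenceCounts("shaft_spininess")[["all"]]),
               91.06, tolerance = 0.011)
})

test_that("count tables round-trip through CSV", {
  f <- file.path(tempdir(), "counts.csv")
  cm <- layerCounts(lct)
  df <- data.frame(layer = colnames(cm), t(cm), check.names = FALSE)
  write.csv(df, f, row.names = FALSE)
  back <- readLayerCounts(f)
  expect_equal(layerCounts(back), cm)
  unlink(f)
})
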