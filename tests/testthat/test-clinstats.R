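# Statistics layer: HAS rule, Bland-Altman, Spearman, chi-squared, tables
# and the agreement report.

test_that("the hyperdense artery sign threshold is >= 50 HU inclusive", {
  expect_true(hasFlag(54.0))
  expect_false(hasFlag(49.4))
  expect_true(hasFlag(50.0))
  expect_error(hasFlag(NaN), "finite")
})

test_that("Bland-Altman reproduces hand arithmetic and identity", {
  idty <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idty@bias, 0)
  expect_equal(idty@sd, 0)
  expect_equal(c(idty@loaLow, idty@loaHigh), c(0, 0))
  ba <- blandAltman(c(1, 2, 3), c(3, 2, 1))   # differences -2, 0, 2
  expect_equal(ba@bias, 0)
  expect_equal(ba@sd, 2)
  expect_equal(ba@loaLow, -3.92)
  expect_equal(ba@loaHigh, 3.92)
  expect_equal(ba@points$difference, c(-2, 0, 2))
  expect_equal(ba@points$average, c(2, 2, 2))
  expect_error(blandAltman(1, 1), "at least 2")
  expect_error(blandAltman(1:3, 1:4), "length mismatch")
})

test_that("Spearman handles perfect, frozen and tied cases", {
  expect_equal(spearmanRho(1:4, c(10, 20, 30, 40))@rho, 1)
  expect_equal(spearmanRho(1:4, c(10, 20, 30, 40))@p, 0)
  expect_equal(spearmanRho(1:4, c(8, 6, 4, 2))@rho, -1)
  # d^2 = (0,1,1,1,1): rho = 1 - 6*4/(5*24) = 0.8
  r <- spearmanRho(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r@rho, 0.8)
  expect_equal(r@p, 2 * pt(-0.8 * sqrt(3 / (1 - 0.64)), df = 3))
  expect_error(spearmanRho(c(1, 1, 1), 1:3), "constant input")
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("Spearman equals the explicit mid-rank oracle with ties", {
  set.seed(10)
  for (k in 1:40) {
    n <- sample(5:40, 1)
    x <- sample(0:9, n, TRUE)   # heavy ties
    y <- x + rnorm(n, 0, 3)
    if (sd(x) == 0) next
    ours <- spearmanRho(x, y)
    expect_equal(ours@rho, oracleSpearman(x, y), tolerance = 1e-9)
    expect_equal(ours@rho, cor(x, y, method = "spearman"), tolerance = 1e-9)
  }
})

test_that("exact permutation p agrees with the enumeration definition", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- spearmanRho(x, y, exact = TRUE)
  # independent enumeration using cor() on permuted ranks
  perms <- ClotQuant:::.permutations(5)
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(r@p, mean(abs(rhos) >= abs(cor(rank(x), rank(y))) - 1e-12))
  expect_error(spearmanRho(1:11, rnorm(11), exact = TRUE), "n <= 10")
})

test_that("chi-squared matches closed forms and the stats oracle", {
  r0 <- pearsonChi2(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0@statistic, 0)
  expect_equal(r0@p, 1)
  r1 <- pearsonChi2(rbind(c(20, 10), c(10, 20)))
  expect_equal(r1@statistic, 20 / 3)
  expect_equal(r1@df, 1L)
  # permutation invariance
  r2 <- pearsonChi2(rbind(c(10, 20), c(20, 10)))
  expect_equal(r2@statistic, r1@statistic)
  # against stats::chisq.test without continuity correction
  set.seed(2)
  for (k in 1:20) {
    tab <- matrix(sample(1:30, 6, TRUE), 2, 3)
    ours <- pearsonChi2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours@statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours@p, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours@df, as.integer(ref$parameter))
  }
  # Yates correction against the stats oracle on 2x2
  tab <- rbind(c(12, 5), c(7, 15))
  expect_equal(pearsonChi2(tab, correct = TRUE)@statistic,
               unname(chisq.test(tab, correct = TRUE)$statistic))
  expect_error(pearsonChi2(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(pearsonChi2(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("expected margins equal observed margins", {
  tab <- rbind(c(20, 10), c(10, 20), c(5, 7))
  r <- pearsonChi2(tab)
  expect_equal(rowSums(r@expected), rowSums(tab))
  expect_equal(colSums(r@expected), colSums(tab))
})

test_that("category/HAS tables tally and collapse correctly", {
  t <- compositionHasTable(c("RBC_RICH", "MIXED", "FIBRIN_RICH"),
                           c(TRUE, TRUE, TRUE))
  expect_equal(unname(t$table3x2), rbind(c(1, 0), c(1, 0), c(1, 0)))
  expect_equal(unname(t$table2x2), rbind(c(1, 0), c(2, 0)))
  # zero row is kept (and chi-squared on it errors via the margin rule)
  t2 <- compositionHasTable(c("RBC_RICH", "RBC_RICH", "MIXED"),
                            c(TRUE, FALSE, TRUE))
  expect_equal(unname(t2$table3x2["FIBRIN_RICH", ]), c(0, 0))
  expect_error(pearsonChi2(t2$table3x2), "zero margin")
  # aggregation consistency
  expect_equal(colSums(t2$table3x2), colSums(t2$table2x2))
})

test_that("agreement report: self-agreement, invariance, determinism", {
  set.seed(5)
  n <- 12
  tab <- data.frame(clot_id = sprintf("c%02d", 1:n),
                    pct_rbc = runif(n, 10, 85))
  tab$pct_wbc <- runif(n, 2, 10)
  tab$pct_fibrin <- 100 - tab$pct_rbc - tab$pct_wbc
  clinical <- data.frame(clot_id = tab$clot_id,
                         mean_hu = 35 + 0.3 * tab$pct_rbc + rnorm(n, 0, 3))
  rep1 <- agreementReport(tab, tab, clinical)
  expect_equal(rep1@pooledSpearman@rho, 1)
  expect_equal(rep1@pooledBlandAltman@bias, 0)
  expect_equal(rep1@n, n)
  # row-order invariance
  shuffle <- sample(n)
  rep2 <- agreementReport(tab[shuffle, ], tab, clinical[rev(seq_len(n)), ])
  expect_equal(rep2@pooledSpearman@rho, rep1@pooledSpearman@rho)
  expect_equal(rep2@rbcHuSpearman$methodA@rho, rep1@rbcHuSpearman$methodA@rho)
  # determinism of the serialized report
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  reportAsList(rep1, p1); reportAsList(rep1, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(agreementReport(tab, tab[0, ], clinical), "at least 3")
})

test_that("clot tables import from CSV and XLSX via a column mapping", {
  tab <- data.frame(ID = c("a", "b", "c"), RBC = c(70, 20, 40),
                    WBC = c(5, 10, 10), Fibrin = c(25, 70, 50),
                    HU = c(55, 42, 51))
  p <- tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  mapping <- c(clot_id = "ID", pct_rbc = "RBC", pct_wbc = "WBC",
               pct_fibrin = "Fibrin", mean_hu = "HU")
  got <- importClotTable(p, mapping)
  expect_equal(names(got), names(mapping))
  expect_equal(got$pct_rbc, tab$RBC)
  expect_error(importClotTable(p, c(clot_id = "NoSuchColumn")),
               "not found")
})
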