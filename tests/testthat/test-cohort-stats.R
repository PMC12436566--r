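test_that("the hand-enumerable 2x2 table gives exactly p = 34/70", {
  res <- fisherExactRxC(matrix(c(3, 1, 1, 3), 2))
  expect_equal(pValue(res), 34 / 70, tolerance = 1e-12)
  expect_equal(attr(res, "totalMass"), 1, tolerance = 1e-9)
})

test_that("2x2 enumeration agrees with the closed-form hypergeometric sum", {
  set.seed(6)
  for (i in 1:15) {
    m <- matrix(rpois(4, 4), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- pValue(fisherExactRxC(m))
    # closed form: sum dhyper over all tables with prob <= observed
    k <- sum(m[1, ]); K <- sum(m[, 1]); n <- sum(m)
    xs <- max(0, k + K - n):min(k, K)
    probs <- dhyper(xs, K, n - K, k)
    pObs <- dhyper(m[1, 1], K, n - K, k)
    expect_equal(p, sum(probs[probs <= pObs * (1 + 1e-7)]),
                 tolerance = 1e-12)
  }
})

test_that("enumeration matches the standard exact-test implementation on random tables", {
  set.seed(12)
  for (i in 1:20) {
    nr <- sample(2:3, 1); nc <- sample(2:4, 1)
    m <- matrix(rpois(nr * nc, 2), nr, nc)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    res <- fisherExactRxC(m)
    expect_equal(pValue(res), stats::fisher.test(m)$p.value,
                 tolerance = 1e-8)
    expect_equal(attr(res, "totalMass"), 1, tolerance = 1e-9)
  }
})

test_that("proportional rows give p = 1 and permutations leave p unchanged", {
  prop <- matrix(c(2, 4, 3, 6, 1, 2), 2)
  expect_equal(pValue(fisherExactRxC(prop)), 1, tolerance = 1e-12)
  m <- matrix(c(4, 2, 3, 4, 7, 7, 0, 7, 3, 0), 2)
  p0 <- pValue(fisherExactRxC(m))
  expect_equal(pValue(fisherExactRxC(m[2:1, ])), p0, tolerance = 1e-12)
  expect_equal(pValue(fisherExactRxC(m[, c(3, 1, 5, 2, 4)])), p0,
               tolerance = 1e-12)
})

test_that("degenerate tables are handled: zero margins dropped, single lines independent", {
  withZero <- matrix(c(3, 1, 0, 0, 1, 3), 2)
  expect_warning(res <- fisherExactRxC(withZero), "zero-margin")
  expect_equal(pValue(res), 34 / 70, tolerance = 1e-12)
  expect_warning(one <- fisherExactRxC(matrix(c(2, 0, 5, 0), 2)),
                 "zero-margin")
  expect_equal(pValue(one), 1)
  expect_error(fisherExactRxC(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisherExactRxC(matrix(c(0.5, 2, 3, 4), 2)), "non-negative")
})

test_that("the Kruskal-Wallis test reproduces the hand-ranked reference", {
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw@statistic, 3.857142857, tolerance = 1e-6)
  expect_equal(pValue(kw), 0.0495346, tolerance = 1e-4)
  ident <- kruskalWallis(list(c(1, 2), c(1, 2), c(1, 2)))
  # identical distributions but not identical values: small H, p near 1
  expect_lt(ident@statistic, 1e-9)
  degen <- kruskalWallis(list(c(2, 2), c(2, 2)))
  expect_equal(degen@statistic, 0)
  expect_equal(pValue(degen), 1)
  expect_error(kruskalWallis(list(c(1, 2))), "two")
  expect_error(kruskalWallis(list(c(1, 2), numeric(0))), "two")
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(9)
  g <- list(runif(8), runif(6) + 0.2, runif(7) * 2)
  h0 <- kruskalWallis(g)@statistic
  expect_equal(kruskalWallis(lapply(g, exp))@statistic, h0, tolerance = 1e-9)
  expect_equal(kruskalWallis(lapply(g, function(x) x^3 + 5))@statistic, h0,
               tolerance = 1e-9)
})

test_that("contingency tables are assembled from screened cohorts by threshold", {
  mk <- function(vals, id, grp) {
    list(series = list(primary = makeSeries(vals)), subjectId = id,
         subgroup = grp)
  }
  cohort <- list(mk(rep(0.1, 4), "a", "Normal"),
                 mk(rep(0.9, 4), "b", "Normal"),
                 mk(rep(0.9, 4), "c", "HF"))
  res <- cohortScreen(cohort)
  tab <- contingencyTable(res, 1 / 3)
  expect_identical(dim(tableCounts(tab)), c(2L, 2L))
  expect_equal(tableCounts(tab)["pass", "Normal"], 1L)
  expect_equal(tableCounts(tab)["fail", "HF"], 1L)
  tab1 <- contingencyTable(res, 1)
  expect_true(all(tableCounts(tab1)["fail", ] == 0L))
  expect_error(contingencyTable(res, 0.42), "not screened")
  expect_error(contingencyTable(list(summary = NULL), 1 / 3), "empty")
  single <- cohortTable(fail = c(HCM = 1L), pass = c(HCM = 3L))
  expect_identical(dim(tableCounts(single)), c(2L, 1L))
})

test_that("cohort reports render pass fractions, exact p-values and probability summaries", {
  mk <- function(vals, id, grp, missSecondary = FALSE) {
    series <- list(primary = makeSeries(vals),
                   alternate = makeSeries(vals, role = "alternate"))
    series$secondary <- if (missSecondary) {
      makeSeries(numeric(0), role = "secondary", missing = TRUE)
    } else makeSeries(vals, role = "secondary")
    list(series = series, subjectId = id, subgroup = grp)
  }
  cohort <- list(mk(rep(0.1, 4), "a", "Normal"),
                 mk(rep(0.1, 4), "b", "Normal", missSecondary = TRUE),
                 mk(rep(0.9, 4), "c", "HF"),
                 mk(rep(0.2, 4), "d", "HF"))
  # zero-margin warnings are expected here: some thresholds have no failures
  rep <- suppressWarnings(buildReport(cohortScreen(cohort)))
  ov <- rep$overall
  expect_equal(ov$overallPass[abs(ov$threshold - 1 / 3) < 1e-9],
               "3/4 (75%)")
  expect_true(all(ov$fisherP > 0 & ov$fisherP <= 1))
  # per-vector denominators exclude the missing secondary
  pv <- rep$perVector
  sec13 <- pv[pv$vector == "secondary" & abs(pv$threshold - 1 / 3) < 1e-9, ]
  expect_match(sec13$overallPass, "^2/3")
  prim13 <- pv[pv$vector == "primary" & abs(pv$threshold - 1 / 3) < 1e-9, ]
  expect_match(prim13$overallPass, "^3/4")
  # probability summary covers Overall plus each subgroup
  expect_identical(rep$probabilitySummary$table$subgroup[1], "Overall")
  expect_true(all(rep$probabilitySummary$table$mean >= 0 &
                    rep$probabilitySummary$table$mean <= 1))
  expect_true(rep$probabilitySummary$kruskalWallisP > 0)
})

test_that("an all-pass cohort reports every p-value as one and full pass rates", {
  mk <- function(id, grp) {
    list(series = list(primary = makeSeries(rep(0.05, 4))),
         subjectId = id, subgroup = grp)
  }
  cohort <- list(mk("a", "Normal"), mk("b", "HF"), mk("c", "HCM"))
  # every table has an empty fail row, so zero-margin warnings are expected
  rep <- suppressWarnings(buildReport(cohortScreen(cohort)))
  expect_true(all(rep$overall$fisherP == 1))
  expect_true(all(grepl("(100%)", rep$overall$overallPass, fixed = TRUE)))
  expect_equal(pValue(kruskalWallis(
    split(rep(1, 3), c("a", "b", "c")))), 1)
})
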