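test_that("favourability is strict: a ratio at the threshold is unfavourable", {
  expect_identical(favourability(c(0.2, 1 / 3, 0.4), 1 / 3),
                   c(TRUE, FALSE, FALSE))
  expect_true(all(favourability(rep(0, 5), 0.1)))
  expect_true(all(favourability(c(0.2, 0.5, 0.99), 1)))
  expect_identical(favourability(makeSeries(c(0.1, NA)), 1 / 3)[2], NA)
  expect_error(favourability(c(0.1), 0), "threshold")
})

test_that("standard pass probability counts segments with any favourable vector", {
  sl <- list(makeSeries(c(0.1, 0.5, 0.5, 0.5)),
             makeSeries(c(0.5, 0.1, 0.5, 0.5), role = "alternate"),
             makeSeries(c(0.5, 0.5, 0.5, 0.5), role = "secondary"))
  expect_equal(standardPassProbability(sl), 0.5)
  expect_equal(standardPassProbability(list(makeSeries(rep(0.1, 8)))), 1)
  # vector-order invariance
  expect_equal(standardPassProbability(rev(sl)),
               standardPassProbability(sl))
  # missing channels are ignored; missing values never count as favourable
  slNA <- list(makeSeries(c(NA, 0.1)),
               makeSeries(numeric(0), role = "secondary", missing = TRUE))
  expect_equal(standardPassProbability(slNA), 0.5)
  expect_error(standardPassProbability(list(makeSeries(numeric(0)))),
               "zero segments")
  expect_error(standardPassProbability(
    list(makeSeries(numeric(0), missing = TRUE))), "non-missing")
})

test_that("pass probability equals one minus the all-unfavourable fraction", {
  set.seed(14)
  for (i in 1:10) {
    sl <- lapply(c("primary", "alternate", "secondary"), function(role) {
      makeSeries(runif(40, 0, 0.8), role = role)
    })
    thr <- runif(1, 0.1, 0.7)
    favs <- vapply(sl, function(s) favourability(s, thr), logical(40))
    expect_equal(standardPassProbability(sl, thr),
                 1 - mean(rowSums(favs) == 0))
  }
})

test_that("twenty consecutive unfavourable seconds fail; silent episodes pass", {
  # alternating favourability: runs of one segment only
  alt <- makeSeries(rep(c(0.1, 0.9), 10))
  r <- vectorProlongedPass(alt, 1 / 3)
  expect_true(r$pass)
  expect_equal(r$longestRunS, 10)
  expect_equal(r$nFailingRuns, 0L)
  # one run of two unfavourable segments = 20 s
  two <- makeSeries(c(0.1, 0.1, 0.9, 0.9, 0.1))
  r2 <- vectorProlongedPass(two, 1 / 3)
  expect_false(r2$pass)
  expect_equal(r2$longestRunS, 20)
  expect_equal(r2$nFailingRuns, 1L)
  # all favourable
  ok <- vectorProlongedPass(makeSeries(rep(0.1, 6)), 1 / 3)
  expect_true(ok$pass)
  expect_equal(ok$longestRunS, 0)
  # missing channel propagates
  miss <- vectorProlongedPass(makeSeries(numeric(0), missing = TRUE), 1 / 3)
  expect_true(miss$missing)
  expect_error(vectorProlongedPass(alt, 1 / 3, minFailDurationS = 25),
               "divide")
})

test_that("missing estimates break runs conservatively and are reported", {
  s <- makeSeries(c(0.9, NA, 0.9, 0.9))
  r <- vectorProlongedPass(s, 1 / 3)
  expect_equal(r$nMissing, 1L)
  expect_equal(r$longestRunS, 20)   # the NA splits the would-be run of 3
  expect_false(r$pass)              # the trailing run of 2 still fails
  s2 <- makeSeries(c(0.9, NA, 0.9, 0.1))
  expect_true(vectorProlongedPass(s2, 1 / 3)$pass)
})

test_that("run detection agrees with a brute-force contiguous-window oracle", {
  set.seed(99)
  for (i in 1:200) {
    vals <- runif(sample(5:40, 1), 0, 1)
    thr <- runif(1, 0.2, 0.8)
    r <- vectorProlongedPass(makeSeries(vals), thr)
    brute <- bruteLongestRun(!favourability(vals, thr))
    expect_equal(r$longestRunS, brute * 10)
    expect_identical(r$pass, brute < 2)
  }
})

test_that("a patient passes a threshold when any non-missing vector passes", {
  pass13 <- makeSeries(rep(0.1, 6))
  fail13 <- makeSeries(c(0.4, 0.4, 0.4, 0.1, 0.1, 0.1), role = "alternate")
  p <- patientScreen(list(primary = pass13, alternate = fail13),
                     subjectId = "a", subgroup = "HF")
  expect_true(all(p@patientPass))     # monotone: passing 1/3 passes all
  # primary fails at 1/3 but alternate passes at 1/2
  prim <- makeSeries(rep(0.45, 6))
  alt <- makeSeries(rep(0.45, 6), role = "alternate")
  p2 <- patientScreen(list(primary = prim, alternate = alt))
  expect_false(p2@patientPass[["0.333333"]])
  expect_true(p2@patientPass[["0.5"]])
  # missing secondary cannot rescue two failing vectors
  p3 <- patientScreen(list(
    primary = makeSeries(rep(0.9, 6)),
    alternate = makeSeries(rep(0.9, 6), role = "alternate"),
    secondary = makeSeries(numeric(0), role = "secondary", missing = TRUE)))
  expect_false(p3@patientPass[["0.333333"]])
  expect_error(patientScreen(list(
    primary = makeSeries(numeric(0), missing = TRUE))), "all vectors")
})

test_that("pass flags are monotone in the threshold at vector and patient level", {
  set.seed(41)
  for (i in 1:20) {
    sl <- lapply(c("primary", "alternate", "secondary"), function(role) {
      makeSeries(runif(30, 0, 1.2), role = role)
    })
    names(sl) <- c("primary", "alternate", "secondary")
    p <- patientScreen(sl)
    expect_true(all(diff(as.integer(p@patientPass)) >= 0))
    vr <- p@vectorResults
    for (role in unique(vr$role)) {
      flags <- vr$pass[vr$role == role][order(vr$threshold[vr$role == role])]
      expect_true(all(diff(as.integer(flags)) >= 0))
    }
  }
})

test_that("at threshold one, vectors whose ratios stay below one always pass", {
  set.seed(77)
  for (i in 1:10) {
    s <- makeSeries(runif(25, 0, 0.999))
    expect_true(vectorProlongedPass(s, 1)$pass)
  }
})

test_that("cohort screening aggregates counts by subgroup and threshold", {
  mk <- function(vals, id, grp) {
    list(series = list(primary = makeSeries(vals)), subjectId = id,
         subgroup = grp)
  }
  cohort <- list(mk(rep(0.1, 6), "a", "Normal"),
                 mk(rep(0.45, 6), "b", "Normal"),  # fails 1/3, passes 1/2
                 mk(rep(0.9, 6), "c", "HF"))       # fails up to 3/4
  res <- cohortScreen(cohort)
  s <- res$summary
  n13 <- s[abs(s$threshold - 1 / 3) < 1e-9 & s$subgroup == "Normal", ]
  expect_equal(n13$nPass, 1)
  expect_equal(n13$nFail, 1)
  n12 <- s[abs(s$threshold - 0.5) < 1e-9 & s$subgroup == "Normal", ]
  expect_equal(n12$nPass, 2)
  hf1 <- s[s$threshold == 1 & s$subgroup == "HF", ]
  expect_equal(hf1$nPass, 1)
  # pass rates monotone at cohort level
  tot <- tapply(s$nPass, s$threshold, sum)
  expect_true(all(diff(tot[order(as.numeric(names(tot)))]) >= 0))
  # planted failures at 1/3 only: pass rate rises from 1/3 to 1/2
  expect_lt(tot[["0.333333333333333"]], tot[["0.5"]])

  empty <- cohortScreen(list())
  expect_equal(nrow(empty$summary), 0)
  single <- cohortScreen(list(mk(rep(0.1, 4), "z", "HCM")))
  expect_true(all(single$summary$nPass == 1))
})

test_that("screening JSON export is machine-readable and faithful", {
  cohort <- list(list(series = list(primary = makeSeries(rep(0.2, 4))),
                      subjectId = "p1", subgroup = "Normal"))
  res <- cohortScreen(cohort)
  path <- tempfile(fileext = ".json")
  writeScreeningJson(res, path)
  back <- jsonlite::read_json(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$subjectId, "p1")
  expect_equal(back[[1]]$standardPassProbability, 1)
  expect_true(back[[1]]$patientPass[["0.333333"]])
})
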