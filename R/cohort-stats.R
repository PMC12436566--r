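## Cohort-level statistics: outcome-by-subgroup contingency tables, the
## exact r x c Fisher test by complete enumeration, the Kruskal-Wallis
## rank-sum test, and report builders shaped like the screening tables.

#' Outcome-by-subgroup contingency table at one threshold
#'
#' Builds the 2 x K fail/pass count table across subgroups from a
#' screened cohort (the output of [cohortScreen()]).
#'
#' @param cohortResult output of [cohortScreen()].
#' @param threshold the T:R threshold whose outcome to tabulate (must be
#'   one of the screened thresholds).
#' @return a [CohortTable-class] with rows \code{fail}, \code{pass}.
#' @export
contingencyTable <- function(cohortResult, threshold) {
  s <- cohortResult$summary
  if (is.null(s) || nrow(s) == 0) stop("empty cohort")
  sel <- abs(s$threshold - threshold) < 1e-9
  if (!any(sel)) stop("threshold was not screened: ", threshold)
  s <- s[sel, ]
  counts <- rbind(fail = s$nFail, pass = s$nPass)
  colnames(counts) <- s$subgroup
  storage.mode(counts) <- "integer"
  new("CohortTable", counts = counts)
}

#' Build a cohort table directly from counts
#'
#' @param fail,pass integer fail and pass counts per subgroup.
#' @param subgroups subgroup labels.
#' @return a [CohortTable-class].
#' @export
cohortTable <- function(fail, pass, subgroups = names(fail)) {
  counts <- rbind(fail = as.integer(fail), pass = as.integer(pass))
  if (!is.null(subgroups)) colnames(counts) <- subgroups
  new("CohortTable", counts = counts)
}

## Enumerate all non-negative integer tables with the given margins,
## calling fun(logProb) for each; logConst is the margin-dependent part
## of the multivariate hypergeometric log-probability.
.enumerateTables <- function(rowM, colM, fun, budget = 2e7) {
  r <- length(rowM)
  nTab <- 0L
  colRem <- colM
  lgSum <- 0       # running sum of lgamma(nij + 1) over filled cells
  cellLg <- matrix(0, r, length(colM))

  fillRow <- function(i) {
    if (i == r) {
      ## last row forced by the remaining column margins
      if (any(colRem < 0)) return()
      nTab <<- nTab + 1L
      if (nTab > budget) {
        stop("enumeration budget exceeded; table too large for complete ",
             "enumeration (consider a Monte-Carlo approximation)")
      }
      fun(lgSum + sum(lgamma(colRem + 1)))
      return()
    }
    fillCell(i, 1L, rowM[i])
  }
  fillCell <- function(i, j, rem) {
    nc <- length(colRem)
    if (j == nc) {
      if (rem > colRem[nc]) return()
      colRem[nc] <<- colRem[nc] - rem
      lgSum <<- lgSum + lgamma(rem + 1)
      fillRow(i + 1L)
      colRem[nc] <<- colRem[nc] + rem
      lgSum <<- lgSum - lgamma(rem + 1)
      return()
    }
    ## v must leave enough mass for the remaining cells of this row
    maxLater <- sum(colRem[(j + 1L):nc])
    lo <- max(0L, rem - maxLater)
    hi <- min(rem, colRem[j])
    if (lo > hi) return()
    for (v in lo:hi) {
      colRem[j] <<- colRem[j] - v
      lgSum <<- lgSum + lgamma(v + 1)
      fillCell(i, j + 1L, rem - v)
      colRem[j] <<- colRem[j] + v
      lgSum <<- lgSum - lgamma(v + 1)
    }
  }
  fillRow(1L)
  nTab
}

#' Exact r x c Fisher test by complete enumeration
#'
#' Two-sided exact conditional test of independence for an r x c count
#' table: with both margins fixed, table probabilities follow the
#' multivariate hypergeometric distribution, and the p-value is the sum
#' of the probabilities of all tables no more probable than the observed
#' one. Every compatible table is enumerated by recursive cell filling
#' with margin-feasibility pruning; probabilities are computed in
#' log-factorial arithmetic, and a relative tolerance of 1e-7 guards
#' floating-point ties when applying the "no more probable" rule.
#'
#' Rows or columns with a zero margin carry no information and are
#' dropped with a warning. Tables whose enumeration would exceed the
#' budget (2e7 tables) raise an error suggesting a Monte-Carlo
#' approximation instead.
#'
#' @param table a [CohortTable-class] or a count matrix.
#' @return a [TestResult-class]; the enumerated probability mass (which
#'   must equal 1) is attached as attribute \code{totalMass} for
#'   auditing.
#' @examples
#' fisherExactRxC(matrix(c(3, 1, 1, 3), 2))  # p = 34/70
#' @export
fisherExactRxC <- function(table) {
  counts <- if (is(table, "CohortTable")) table@counts else as.matrix(table)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  rowM <- rowSums(counts)
  colM <- colSums(counts)
  if (any(rowM == 0) || any(colM == 0)) {
    warning("dropping zero-margin row(s)/column(s)")
    counts <- counts[rowM > 0, colM > 0, drop = FALSE]
    rowM <- rowSums(counts)
    colM <- colSums(counts)
  }
  n <- sum(counts)
  if (n == 0) stop("empty table")
  if (length(rowM) < 2 || length(colM) < 2) {
    ## a single row or column is always independent
    res <- new("TestResult", statistic = NA_real_, pValue = 1,
               method = "Exact Fisher test (r x c enumeration)",
               n = as.integer(n))
    attr(res, "totalMass") <- 1
    return(res)
  }

  logConst <- sum(lgamma(rowM + 1)) + sum(lgamma(colM + 1)) - lgamma(n + 1)
  logPObs <- logConst - sum(lgamma(counts + 1))

  pSum <- 0
  mass <- 0
  tol <- 1e-7
  .enumerateTables(rowM, colM, function(lgCells) {
    lp <- logConst - lgCells
    p <- exp(lp)
    mass <<- mass + p
    if (lp <= logPObs + tol) pSum <<- pSum + p
  })

  res <- new("TestResult", statistic = NA_real_,
             pValue = min(1, pSum),
             method = "Exact Fisher test (r x c enumeration)",
             n = as.integer(n))
  attr(res, "totalMass") <- mass
  res
}

#' Kruskal-Wallis rank-sum test across subgroups
#'
#' Tie-corrected H statistic with the chi-square approximation on K - 1
#' degrees of freedom (standard practice at cohort sizes like these).
#' The degenerate case where every value in every group is identical is
#' reported as H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per subgroup (at least two
#'   groups with at least one value each).
#' @return a [TestResult-class].
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("at least two non-empty groups required")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) stop("values must be non-missing")
  n <- length(pooled)
  if (length(unique(pooled)) == 1) {
    return(new("TestResult", statistic = 0, pValue = 1,
               method = "Kruskal-Wallis rank sum test",
               n = as.integer(n)))
  }
  kt <- stats::kruskal.test(groups)
  new("TestResult", statistic = unname(kt$statistic),
      pValue = kt$p.value, method = "Kruskal-Wallis rank sum test",
      n = as.integer(n))
}

## `n/N (x%)` formatting matching the precision class of the screening
## tables: one decimal below 10%, whole percent otherwise.
.fmtFrac <- function(n, N) {
  pct <- 100 * n / N
  txt <- if (pct > 0 && pct < 10) sprintf("%.1f", pct)
         else sprintf("%.0f", pct)
  sprintf("%d/%d (%s%%)", n, N, txt)
}

#' Cohort report tables
#'
#' Builds the publication-shaped report from a screened cohort: one
#' overall fail/pass table per threshold and one per sensing vector
#' (patients missing a vector are excluded from that vector's
#' denominators), each with its exact Fisher p-value, plus a
#' standard-pass-probability summary (mean (SD) per subgroup) with a
#' Kruskal-Wallis p-value across subgroups. Percentages are formatted
#' \code{n/N (x\%)}.
#'
#' @param cohortResult output of [cohortScreen()].
#' @param thresholds thresholds to report (default: those screened).
#' @return list with data.frames \code{overall}, \code{perVector} and
#'   \code{probabilitySummary}.
#' @export
buildReport <- function(cohortResult, thresholds = NULL) {
  patients <- cohortResult$patients
  if (length(patients) == 0) stop("empty cohort")
  if (is.null(thresholds)) thresholds <- patients[[1]]@thresholds
  thr <- as.numeric(thresholds)
  groups <- unique(vapply(patients, function(p) p@subgroup, character(1)))

  rowFor <- function(flags, grp) {
    ## flags: named by subject index; grp: subgroup per subject
    vapply(groups, function(g) {
      f <- flags[grp == g]
      f <- f[!is.na(f)]
      .fmtFrac(sum(!f), length(f))
    }, character(1))
  }

  grp <- vapply(patients, function(p) p@subgroup, character(1))

  overall <- do.call(rbind, lapply(thr, function(t) {
    flags <- vapply(patients, function(p) {
      p@patientPass[[sprintf("%.6g", t)]]
    }, logical(1))
    counts <- t(vapply(groups, function(g) {
      c(fail = sum(!flags[grp == g]), pass = sum(flags[grp == g]))
    }, integer(2)))
    p <- fisherExactRxC(t(counts))
    data.frame(threshold = t,
               overallFail = .fmtFrac(sum(!flags), length(flags)),
               overallPass = .fmtFrac(sum(flags), length(flags)),
               t(rowFor(flags, grp)),
               fisherP = pValue(p), check.names = FALSE)
  }))

  perVector <- do.call(rbind, lapply(thr, function(t) {
    do.call(rbind, lapply(.VALID_ROLES, function(role) {
      flags <- vapply(patients, function(p) {
        vr <- p@vectorResults
        row <- vr[vr$role == role & abs(vr$threshold - t) < 1e-9, ]
        if (nrow(row) == 0 || row$missingChannel[1]) NA else row$pass[1]
      }, logical(1))
      present <- !is.na(flags)
      if (!any(present)) return(NULL)
      counts <- t(vapply(groups, function(g) {
        f <- flags[grp == g & present]
        c(fail = sum(!f), pass = sum(f))
      }, integer(2)))
      p <- fisherExactRxC(t(counts))
      data.frame(threshold = t, vector = role,
                 overallFail = .fmtFrac(sum(!flags[present]), sum(present)),
                 overallPass = .fmtFrac(sum(flags[present]), sum(present)),
                 t(rowFor(flags, grp)),
                 fisherP = pValue(p), check.names = FALSE)
    }))
  }))

  probs <- vapply(patients, function(p) p@standardPassProbability,
                  numeric(1))
  probRows <- do.call(rbind, lapply(c("Overall", groups), function(g) {
    v <- if (g == "Overall") probs else probs[grp == g]
    data.frame(subgroup = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  }))
  kwP <- if (length(groups) >= 2 &&
             all(vapply(groups, function(g) sum(grp == g) >= 1, logical(1)))) {
    pValue(kruskalWallis(split(probs, grp)))
  } else NA_real_
  probabilitySummary <- list(table = probRows, kruskalWallisP = kwP)

  list(overall = overall, perVector = perVector,
       probabilitySummary = probabilitySummary)
}
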