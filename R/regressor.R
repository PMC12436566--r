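## Trainable PSR-image T:R regressor: a compact convolutional feature
## extractor (fixed 3x3 kernel bank -> rectification -> average pooling)
## plus amplitude-marginal quantile features, feeding a ridge (penalised
## linear) readout fitted per fold. Training is deterministic: the only
## randomness is the seeded fold shuffle.

## 'valid' 2-D convolution of a matrix with a 3x3 kernel, via shifts.
.conv3x3 <- function(m, k) {
  nr <- nrow(m) - 2L
  nc <- ncol(m) - 2L
  out <- matrix(0, nr, nc)
  for (i in 1:3) {
    for (j in 1:3) {
      out <- out + k[i, j] * m[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  out
}

## block-average pooling to a p x p grid
.avgPool <- function(m, p) {
  n <- nrow(m)
  idx <- ceiling(seq_len(n) / (n / p))
  rowsum(t(rowsum(m, idx)), idx) / (n / p)^2
}

## Fixed kernel bank: smoothing, horizontal/vertical edges, diagonal.
.KERNELS <- list(
  smooth = matrix(1 / 9, 3, 3),
  edgeH  = matrix(c(-1, 0, 1), 3, 3, byrow = TRUE) / 3,
  edgeV  = matrix(c(-1, 0, 1), 3, 3, byrow = FALSE) / 3,
  diag   = matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 2
)

## Quantile levels read off the image's amplitude marginal. The upper
## tail is sampled densely: the T cluster occupies the top few percent
## of the amplitude distribution (the R cluster, though taller, dwells
## an order of magnitude more briefly), so the T:R ratio is close to
## linear in these positions.
.QUANTILE_LEVELS <- c(0.05, 0.1, 0.25, 0.5, 0.75, 0.8, 0.85, 0.9, 0.92,
                      0.94, 0.95, 0.96, 0.965, 0.97, 0.975, 0.98, 0.985,
                      0.99, 0.995, 0.999)

## Interpolated amplitude quantiles from the image's row marginal (the
## occupancy histogram of the normalised sample amplitude), in units of
## the normalised amplitude, plus its mean and standard deviation.
.marginalQuantiles <- function(intensity) {
  h <- rowSums(intensity)
  total <- sum(h)
  if (total <= 0) return(numeric(length(.QUANTILE_LEVELS) + 2L))
  h <- h / total
  bins <- length(h)
  centres <- (seq_len(bins) - 0.5) / bins
  q <- stats::approx(c(0, cumsum(h)), c(0, seq_len(bins)) / bins,
                     xout = .QUANTILE_LEVELS, ties = "ordered",
                     yleft = 0, yright = 1)$y
  m <- sum(h * centres)
  c(q, m, sqrt(max(0, sum(h * centres^2) - m^2)))
}

## feature vector for one intensity matrix (length 350 at 32x32 input)
.psrFeatures <- function(intensity) {
  maps <- lapply(.KERNELS, function(k) {
    fm <- pmax(.conv3x3(intensity, k), 0)          # ReLU
    ## 30x30 map -> 6x6 average pool
    as.numeric(.avgPool(fm, 6))
  })
  pooled8 <- as.numeric(.avgPool(intensity, 8))     # raw 8x8 pool
  q <- .marginalQuantiles(intensity)
  nq <- length(.QUANTILE_LEVELS)
  c(unlist(maps, use.names = FALSE), pooled8,
    rowMeans(intensity), colMeans(intensity),       # marginal profiles
    q, q[seq_len(nq)] / max(q[nq], 1e-6))           # quantiles + ratios
}

.featureMatrix <- function(images) {
  t(vapply(images, function(img) .psrFeatures(img@intensity),
           numeric(length(.psrFeatures(images[[1]]@intensity)))))
}

## ridge fit with intercept; lambda chosen on the training set by
## generalised cross-validation over a small fixed grid
.ridgeFit <- function(X, y, lambdas = 10^seq(-4, 2, by = 0.5)) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ybar <- mean(y)
  yc <- y - ybar
  s <- svd(Xc)
  d2 <- s$d^2
  uty <- crossprod(s$u, yc)
  n <- nrow(X)
  gcv <- vapply(lambdas, function(l) {
    shrink <- d2 / (d2 + l)
    fit <- s$u %*% (shrink * uty)
    df <- sum(shrink)
    mean((yc - fit)^2) / (1 - df / n)^2
  }, numeric(1))
  l <- lambdas[which.min(gcv)]
  beta <- s$v %*% ((s$d / (d2 + l)) * uty)
  list(beta = as.numeric(beta), mu = mu, intercept = ybar, lambda = l)
}

.ridgePredict <- function(fit, X) {
  as.numeric(sweep(X, 2, fit$mu) %*% fit$beta) + fit$intercept
}

#' Train the PSR-image T:R regressor with k-fold cross-validation
#'
#' Fits the image regressor (convolutional feature extraction with a
#' penalised linear readout) under k-fold cross-validation and reports
#' pooled out-of-fold accuracy. Folds are assigned at the recording
#' level when \code{recordingIds} is given -- all segments of one
#' recording share a fold, avoiding leakage between highly correlated
#' neighbouring segments -- and at the image level otherwise. The final
#' returned model is refitted on all data.
#'
#' @param images list of [PSRImage-class] objects.
#' @param labels numeric reference T:R ratios, one per image.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed for the fold shuffle (the only source of
#'   randomness; the same seed reproduces the same folds and model).
#' @param recordingIds optional vector (same length as \code{images})
#'   identifying the source recording of each image.
#' @return list with elements \code{model} (for [predictTR()]),
#'   \code{report} (an [AccuracyReport-class] over pooled out-of-fold
#'   predictions), \code{folds} (per-image fold index) and
#'   \code{oofPredictions}.
#' @export
trainRegressor <- function(images, labels, nFolds = 10, seed = 1L,
                           recordingIds = NULL) {
  n <- length(images)
  if (n != length(labels) || anyNA(labels) || any(!is.finite(labels))) {
    stop("labels must be finite and match the number of images")
  }
  if (n < nFolds) stop("fewer images than folds")
  if (length(unique(labels)) == 1) {
    warning("constant labels: degenerate regression task")
  }
  set.seed(as.integer(seed))
  if (is.null(recordingIds)) recordingIds <- seq_len(n)
  ids <- unique(recordingIds)
  if (length(ids) < nFolds) {
    stop("fewer distinct recordings than folds; reduce nFolds")
  }
  shuffled <- sample(ids)
  idFold <- setNames(rep_len(seq_len(nFolds), length(ids)), shuffled)
  folds <- as.integer(idFold[as.character(recordingIds)])

  X <- .featureMatrix(images)
  oof <- numeric(n)
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    fit <- .ridgeFit(X[tr, , drop = FALSE], labels[tr])
    oof[!tr] <- pmax(.ridgePredict(fit, X[!tr, , drop = FALSE]), 0)
  }
  report <- evaluateAccuracy(oof, labels, folds)
  finalFit <- .ridgeFit(X, labels)
  model <- structure(list(fit = finalFit, bins = nrow(images[[1]]@intensity),
                          nFeatures = ncol(X)),
                     class = "psrRegressor")
  list(model = model, report = report, folds = folds, oofPredictions = oof)
}

#' Predict a T:R ratio from one PSR image
#'
#' @param model a model returned by [trainRegressor()].
#' @param image a [PSRImage-class] with the same bin count the model was
#'   trained on.
#' @return a single finite non-negative T:R estimate (negative linear
#'   outputs are clamped to 0).
#' @export
predictTR <- function(model, image) {
  stopifnot(inherits(model, "psrRegressor"), is(image, "PSRImage"))
  if (nrow(image@intensity) != model$bins ||
      ncol(image@intensity) != model$bins) {
    stop(sprintf("image is %dx%d but the model expects %dx%d",
                 nrow(image@intensity), ncol(image@intensity),
                 model$bins, model$bins))
  }
  feats <- .psrFeatures(image@intensity)
  max(0, .ridgePredict(model$fit, matrix(feats, nrow = 1)))
}
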