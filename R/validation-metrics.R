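# Internal and external validation statistics and Y-randomization.

#' Determination coefficient
#'
#' \code{R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)}.
#'
#' @param y observed response; \code{yhat} predictions.
#' @param yhat predicted response.
#' @return R-squared.
#' @export
rSquared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Standard error of estimate
#'
#' \code{SEE = sqrt(sum((y - yhat)^2) / (n - a - 1))} where \code{a} is the
#' number of fitted regression variables (latent variables for a PLS
#' model).
#'
#' @param y observed response; \code{yhat} predictions.
#' @param yhat predicted response.
#' @param nParams number of regression variables \code{a}.
#' @return the standard error of estimate.
#' @export
standardError <- function(y, yhat, nParams) {
  n <- length(y)
  sqrt(sum((y - yhat)^2) / (n - nParams - 1))
}

#' Variance ratio (F statistic) of a fit
#'
#' \code{F = (R2/a) / ((1 - R2)/(n - a - 1))}.
#'
#' @param y observed response; \code{yhat} predictions.
#' @param yhat predicted response.
#' @param nParams number of regression variables \code{a}.
#' @return the F statistic.
#' @export
fStatistic <- function(y, yhat, nParams) {
  n <- length(y)
  r2 <- rSquared(y, yhat)
  (r2 / nParams) / ((1 - r2) / (n - nParams - 1))
}

#' Root mean square error
#'
#' @param y observed response; \code{yhat} predictions.
#' @param yhat predicted response.
#' @return RMSE.
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Leave-one-out cross-validated Q2
#'
#' For every row, the full PLS model (including re-centring and
#' re-scaling) is refit without that row and the row predicted;
#' \code{Q2 = 1 - PRESS / sum((y - mean(y))^2)}. A fold where the refit
#' loses rank falls back to the training-mean prediction.
#'
#' @param X descriptor matrix; \code{y} response.
#' @param y numeric response.
#' @param nLv number of latent variables.
#' @param scale autoscale X (default TRUE).
#' @return leave-one-out Q2.
#' @export
q2Loo <- function(X, y, nLv, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    pred[i] <- tryCatch({
      fit <- fitPls(X[-i, , drop = FALSE], y[-i], nLv = nLv, scale = scale)
      predict(fit, X[i, , drop = FALSE])
    }, error = function(e) mean(y[-i]))
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' External predictivity metrics Q2F1 and Q2F2
#'
#' \code{Q2F1 = 1 - sum((y - yhat)^2) / sum((y - mean(y_train))^2)} and
#' \code{Q2F2 = 1 - sum((y - yhat)^2) / sum((y - mean(y_test))^2)},
#' differing only in which response mean defines the denominator.
#'
#' @param yTest observed test responses.
#' @param yhatTest predicted test responses.
#' @param yTrainMean mean response of the training set.
#' @return named numeric vector \code{q2F1}, \code{q2F2}, \code{rmse}.
#' @export
q2External <- function(yTest, yhatTest, yTrainMean) {
  press <- sum((yTest - yhatTest)^2)
  c(q2F1 = 1 - press / sum((yTest - yTrainMean)^2),
    q2F2 = 1 - press / sum((yTest - mean(yTest))^2),
    rmse = rmse(yTest, yhatTest))
}

#' Y-randomization of a PLS model
#'
#' The response is permuted \code{nPerm} times; for each permutation a PLS
#' model is refit and its R2 and leave-one-out Q2 recorded together with
#' \code{c = |cor(y_perm, y)|}. Straight lines of R2 and Q2 against c,
#' including the unpermuted model at c = 1, are extrapolated to c = 0; the
#' two intercepts summarise how much apparent fit survives destruction of
#' the structure-activity relationship. Conventionally the R2 intercept
#' should stay below 0.3 and the Q2 intercept below 0.05.
#'
#' @param X descriptor matrix; \code{y} response.
#' @param y numeric response.
#' @param nLv number of latent variables.
#' @param nPerm number of permutations (default 100; at least 10).
#' @param seed integer seed.
#' @param includeUnpermuted include the real model at c = 1 in the
#'   intercept regression (default TRUE).
#' @return list with \code{r2Intercept}, \code{q2Intercept}, \code{pass}
#'   (both thresholds met), \code{nPerm} and \code{records}
#'   (per-permutation data.frame with columns \code{c}, \code{r2},
#'   \code{q2}).
#' @export
yRandomization <- function(X, y, nLv, nPerm = 100, seed = 1,
                           includeUnpermuted = TRUE) {
  if (nPerm < 10L) stop("nPerm must be at least 10")
  X <- as.matrix(X)
  rng <- .seededRng(seed)
  rec <- data.frame(c = numeric(nPerm), r2 = numeric(nPerm),
                    q2 = numeric(nPerm))
  for (k in seq_len(nPerm)) {
    yp <- rng$sample(y)
    fit <- fitPls(X, yp, nLv = nLv)
    rec$c[k] <- abs(stats::cor(yp, y))
    rec$r2[k] <- rSquared(yp, fit@fitted)
    rec$q2[k] <- q2Loo(X, yp, nLv)
  }
  pts <- rec
  if (includeUnpermuted) {
    fit0 <- fitPls(X, y, nLv = nLv)
    pts <- rbind(pts, data.frame(c = 1, r2 = rSquared(y, fit0@fitted),
                                 q2 = q2Loo(X, y, nLv)))
  }
  r2i <- unname(stats::coef(stats::lm(r2 ~ c, data = pts))[1])
  q2i <- unname(stats::coef(stats::lm(q2 ~ c, data = pts))[1])
  list(r2Intercept = r2i, q2Intercept = q2i,
       pass = r2i < 0.3 && q2i < 0.05, nPerm = nPerm, records = rec)
}

#' Full validation report for a descriptor subset
#'
#' Fits a PLS model on the training compounds, computes internal (R2,
#' Q2LOO, SEE, F) and external (Q2F1, Q2F2, RMSEP) statistics and,
#' optionally, a Y-randomization summary.
#'
#' @param train training \linkS4class{DescriptorTable} (responses set).
#' @param test optional test \linkS4class{DescriptorTable}.
#' @param subset descriptor names to model (default: all columns).
#' @param nLv number of latent variables (default 3).
#' @param nPerm Y-randomization permutations (0 to skip).
#' @param seed integer seed for the permutations.
#' @return list with \code{model} (the \linkS4class{PLSModel}) and
#'   \code{report} (a \linkS4class{ValidationReport}).
#' @export
validateModel <- function(train, test = NULL, subset = NULL, nLv = 3,
                          nPerm = 0, seed = 1) {
  stopifnot(is(train, "DescriptorTable"))
  if (is.null(subset)) subset <- descriptorNames(train)
  Xtr <- descriptorValues(train)[, subset, drop = FALSE]
  ytr <- as.numeric(response(train))
  model <- fitPls(Xtr, ytr, nLv = nLv)
  r2 <- rSquared(ytr, model@fitted)
  a <- model@nLv
  q2 <- q2Loo(Xtr, ytr, nLv = nLv)
  see <- standardError(ytr, model@fitted, a)
  fst <- fStatistic(ytr, model@fitted, a)
  q2f1 <- q2f2 <- rmseTe <- NA_real_
  if (!is.null(test)) {
    Xte <- descriptorValues(test)[, subset, drop = FALSE]
    yte <- as.numeric(response(test))
    ext <- q2External(yte, predict(model, Xte), mean(ytr))
    q2f1 <- ext[["q2F1"]]; q2f2 <- ext[["q2F2"]]; rmseTe <- ext[["rmse"]]
  }
  yr <- if (nPerm > 0) yRandomization(Xtr, ytr, nLv = nLv, nPerm = nPerm,
                                      seed = seed) else list()
  report <- new("ValidationReport", r2 = r2, q2Loo = q2, q2F1 = q2f1,
                q2F2 = q2f2, rmseTrain = rmse(ytr, model@fitted),
                rmseTest = rmseTe, see = see, fStat = fst,
                df = c(a, length(ytr) - a - 1), yRand = yr)
  list(model = model, report = report)
}
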