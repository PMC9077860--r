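# NIPALS PLS1 with scores/loadings/weights, VIP, Hotelling T2 and DModX
# applicability-domain diagnostics.

#' Fit a PLS1 regression by NIPALS
#'
#' X is autoscaled (zero mean, unit variance per column) and y mean-centred
#' before component extraction; X is deflated after each component. The
#' sign of every component is fixed so that its y-loading \code{q[a]} is
#' non-negative, making all reported weights, scores and loadings
#' reproducible. When \code{y} has zero variance the mean model (all
#' coefficients zero, intercept = mean(y)) is returned with zero latent
#' variables.
#'
#' @param X numeric matrix (n x p) with column names.
#' @param y numeric response of length n.
#' @param nLv number of latent variables; \code{NULL} picks the count
#'   maximising leave-one-out Q2 (capped at the rank of centred X).
#' @param scale autoscale X columns (default TRUE).
#' @return a \linkS4class{PLSModel}.
#' @export
fitPls <- function(X, y, nLv = NULL, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(xs == 0)) stop("zero-variance column(s): ",
                         paste(colnames(X)[xs == 0], collapse = ", "))
  ym <- mean(y)
  E <- sweep(sweep(X, 2, xm), 2, xs, "/")
  f <- y - ym
  if (stats::var(y) == 0) {
    return(new("PLSModel", nLv = 0L, xMean = xm, xSd = xs, yMean = ym,
               W = matrix(0, p, 0, dimnames = list(colnames(X), NULL)),
               P = matrix(0, p, 0, dimnames = list(colnames(X), NULL)),
               q = numeric(), scores = matrix(0, n, 0),
               coef = stats::setNames(c(ym, rep(0, p)),
                                      c("(Intercept)", colnames(X))),
               xVar = numeric(), yVar = numeric(),
               y = y, fitted = rep(ym, n), trainXs = E))
  }
  Xs0 <- E
  rankX <- qr(E)$rank
  if (is.null(nLv)) {
    cap <- min(rankX, 10L)
    q2 <- vapply(seq_len(cap), function(a) q2Loo(X, y, a, scale = scale),
                 numeric(1))
    nLv <- which.max(q2)
  }
  nLv <- as.integer(nLv)
  if (nLv > rankX)
    stop("nLv = ", nLv, " exceeds the rank of centred X (", rankX, ")")
  W <- P <- matrix(0, p, nLv, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, nLv)
  q <- numeric(nLv)
  ssxTot <- sum(E^2); ssyTot <- sum(f^2)
  xVar <- yVar <- numeric(nLv)
  for (a in seq_len(nLv)) {
    w <- crossprod(E, f)
    if (sum(w^2) < 1e-24)
      stop("component ", a, ": no X/y residual covariance left; ",
           "reduce nLv to ", a - 1L)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    tt <- sum(t^2)
    pv <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    if (qa < 0) { w <- -w; t <- -t; pv <- -pv; qa <- -qa }
    W[, a] <- w; P[, a] <- pv; q[a] <- qa; Tm[, a] <- t
    xVar[a] <- tt * sum(pv^2) / ssxTot
    yVar[a] <- qa^2 * tt / ssyTot
    E <- E - t %*% t(pv)
    f <- f - qa * t
  }
  bScaled <- W %*% solve(crossprod(P, W), q)
  bOrig <- as.numeric(bScaled) / xs
  coef <- stats::setNames(c(ym - sum(bOrig * xm), bOrig),
                          c("(Intercept)", colnames(X)))
  fitted <- as.numeric(coef[1] + X %*% bOrig)
  new("PLSModel", nLv = nLv, xMean = xm, xSd = xs, yMean = ym,
      W = W, P = P, q = q, scores = Tm, coef = coef,
      xVar = xVar, yVar = yVar, y = y, fitted = fitted, trainXs = Xs0)
}

.checkNewX <- function(object, X) {
  X <- as.matrix(X)
  nm <- names(object@xMean)
  if (!is.null(colnames(X))) {
    if (!all(nm %in% colnames(X)))
      stop("newdata lacks descriptor(s): ",
           paste(setdiff(nm, colnames(X)), collapse = ", "))
    X <- X[, nm, drop = FALSE]
  } else if (ncol(X) != length(nm)) {
    stop("newdata must have ", length(nm), " columns")
  }
  X
}

#' Predict from a fitted PLS model
#'
#' @param object a \linkS4class{PLSModel}.
#' @param newdata numeric matrix with the training descriptor columns.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  X <- .checkNewX(object, newdata)
  as.numeric(object@coef[1] + X %*% object@coef[-1])
})

#' Project new rows into the latent-variable space
#'
#' @param model a \linkS4class{PLSModel}.
#' @param newdata numeric matrix with the training descriptor columns.
#' @return score matrix (rows x nLv).
#' @export
projectScores <- function(model, newdata) {
  X <- .checkNewX(model, newdata)
  E <- sweep(sweep(X, 2, model@xMean), 2, model@xSd, "/")
  if (model@nLv == 0L) return(matrix(0, nrow(X), 0))
  Wstar <- model@W %*% solve(crossprod(model@P, model@W))
  E %*% Wstar
}

#' Variable importance in projection
#'
#' \code{VIP_j = sqrt(p * sum_a[SSY_a (w_ja/||w_a||)^2] / sum_a SSY_a)};
#' the squared scores always sum to the descriptor count p.
#'
#' @param model a \linkS4class{PLSModel}.
#' @return named numeric VIP score per descriptor.
#' @export
vip <- function(model) {
  stopifnot(is(model, "PLSModel"))
  p <- nrow(model@W)
  if (model@nLv == 0L)
    return(stats::setNames(rep(NA_real_, p), rownames(model@W)))
  ssy <- model@yVar
  wn <- sweep(model@W, 2, sqrt(colSums(model@W^2)), "/")
  v <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  stats::setNames(v, rownames(model@W))
}

#' Coefficient and weight table of a PLS model
#'
#' Emits the original-scale regression coefficients (plus intercept), the
#' NIPALS weights \code{W} and the transformed weights
#' \code{W* = W (P'W)^-1} per component, all under the q-positive sign
#' convention.
#'
#' @param model a \linkS4class{PLSModel}.
#' @return list with \code{coefficients} (named numeric) and
#'   \code{weights}/\code{weightsStar} (p x nLv matrices).
#' @export
coefficientTable <- function(model) {
  stopifnot(is(model, "PLSModel"))
  ws <- if (model@nLv > 0L)
    model@W %*% solve(crossprod(model@P, model@W)) else model@W
  dimnames(ws) <- dimnames(model@W)
  list(coefficients = model@coef, weights = model@W, weightsStar = ws)
}

#' @rdname PLSModel-class
#' @export
setMethod("plsWeights", "PLSModel", function(object) object@W)

#' Hotelling T-squared statistics of score vectors
#'
#' \code{T2_i = sum_a t_ia^2 / var(t_a)} with the critical limit
#' \code{a (n-1)/(n-a) F(a, n-a, confidence)}; for two components the
#' score-plot ellipse semi-axes are returned as well.
#'
#' @param model a \linkS4class{PLSModel}.
#' @param newdata optional matrix of new rows (default: training scores).
#' @param confidence confidence level (default 0.95).
#' @return list with \code{t2} (per row), \code{limit} and, when at least
#'   two components exist, \code{ellipse} (semi-axes for components 1-2 at
#'   \code{confidence}).
#' @export
hotellingT2 <- function(model, newdata = NULL, confidence = 0.95) {
  stopifnot(is(model, "PLSModel"))
  a <- model@nLv
  if (a == 0L) stop("model has no latent variables")
  Tm <- if (is.null(newdata)) model@scores else projectScores(model, newdata)
  n <- nrow(model@scores)
  vt <- apply(model@scores, 2, stats::var)
  t2 <- as.numeric(sweep(Tm^2, 2, vt, "/") %*% rep(1, a))
  limit <- a * (n - 1) / (n - a) * stats::qf(confidence, a, n - a)
  out <- list(t2 = t2, limit = limit)
  if (a >= 2L) {
    lim2 <- 2 * (n - 1) / (n - 2) * stats::qf(confidence, 2, n - 2)
    out$ellipse <- sqrt(vt[1:2] * lim2)
  }
  out
}

#' DModX applicability-domain report
#'
#' Normalized distance to the model in X-space: the row residual standard
#' deviation after projection onto the latent variables, divided by the
#' pooled residual standard deviation of the training set
#' (\code{(n-a-1)(p-a)} degrees of freedom). The critical value is the
#' square root of the F-quantile with \code{(p-a)} and \code{(n-a-1)(p-a)}
#' degrees of freedom at \code{confidence}.
#'
#' @param model a \linkS4class{PLSModel}.
#' @param newdata optional matrix of rows to assess (default: training X
#'   residuals).
#' @param ids optional compound ids for the report.
#' @param confidence confidence level (default 0.99).
#' @return an \linkS4class{AdReport}.
#' @export
dmodx <- function(model, newdata = NULL, ids = NULL, confidence = 0.99) {
  stopifnot(is(model, "PLSModel"))
  a <- model@nLv
  p <- length(model@xMean)
  n <- nrow(model@scores)
  if (p - a <= 0L) stop("DModX undefined: no residual X dimensions")
  trainE <- .xResiduals(model, NULL)
  s0sq <- sum(trainE^2) / ((n - a - 1) * (p - a))
  if (s0sq <= .Machine$double.eps)
    stop("DModX undefined: model reproduces X perfectly")
  E <- if (is.null(newdata)) trainE else .xResiduals(model, newdata)
  si <- sqrt(rowSums(E^2) / (p - a))
  dm <- si / sqrt(s0sq)
  dcrit <- sqrt(stats::qf(confidence, p - a, (n - a - 1) * (p - a)))
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(E)))
  t2 <- hotellingT2(model, newdata = newdata, confidence = confidence)
  new("AdReport", ids = as.character(ids), dmodx = dm, dCrit = dcrit,
      t2 = t2$t2, t2Crit = t2$limit, inDomain = dm <= dcrit,
      confidence = confidence)
}

# scaled-X residuals after projection onto the model's components
.xResiduals <- function(model, newdata) {
  if (is.null(newdata))  # deflation identity: E_final = Xs - T P'
    return(model@trainXs - model@scores %*% t(model@P))
  X <- .checkNewX(model, newdata)
  Xs <- sweep(sweep(X, 2, model@xMean), 2, model@xSd, "/")
  Tm <- projectScores(model, X)
  Xs - Tm %*% t(model@P)
}
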