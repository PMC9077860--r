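randXy <- function(n, p, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p))),
       y = rnorm(n))
}

test_that("one-component PLS on one column equals simple regression", {
  d <- randXy(15, 1, 101)
  m <- fitPls(d$X, d$y, nLv = 1)
  ols <- lm(d$y ~ d$X[, 1])
  expect_equal(m@fitted, unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-rank PLS equals OLS predictions (normal-equations oracle)", {
  X <- matrix(c(1, 2, 0, 4, 3, 1,
                0, 1, 2, 1, 0, 2,
                5, 1, 1, 0, 2, 3), 6, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- c(0.3, 1.2, -0.5, 2.0, 1.1, 0.4)
  m <- fitPls(X, y, nLv = 3)
  Xd <- cbind(1, X)
  bOls <- solve(crossprod(Xd), crossprod(Xd, y))  # normal equations
  expect_equal(m@fitted, as.numeric(Xd %*% bOls), tolerance = 1e-8)
})

test_that("degenerate and ill-posed fits are handled as specified", {
  d <- randXy(10, 3, 103)
  yc <- rep(2.5, 10)
  m <- fitPls(d$X, yc, nLv = 3)
  expect_equal(nLatent(m), 0L)
  expect_equal(unname(m@coef), c(2.5, 0, 0, 0))
  expect_equal(predict(m, d$X), rep(2.5, 10))
  expect_error(fitPls(d$X, d$y, nLv = 4), "rank")
})

test_that("predictions are consistent, centred and duplicated-row stable", {
  d <- randXy(20, 4, 104)
  m <- fitPls(d$X, d$y, nLv = 2)
  expect_equal(predict(m, d$X), m@fitted)
  meanRow <- matrix(m@xMean, 1, dimnames = list(NULL, colnames(d$X)))
  expect_equal(predict(m, meanRow), m@yMean, tolerance = 1e-10)
  dup <- d$X[c(3, 3), ]
  expect_equal(predict(m, dup)[1], predict(m, dup)[2])
  expect_error(predict(m, d$X[, 1:2]), "lacks")
})

test_that("scores are orthogonal and variance explained is monotone", {
  d <- randXy(25, 6, 105)
  m <- fitPls(d$X, d$y, nLv = 4)
  G <- crossprod(plsScores(m))
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  r2ByLv <- vapply(1:4, function(a)
    rSquared(d$y, fitPls(d$X, d$y, nLv = a)@fitted), numeric(1))
  expect_true(all(diff(r2ByLv) >= -1e-12))
  xres <- vapply(1:4, function(a) {
    ma <- fitPls(d$X, d$y, nLv = a)
    sum((ma@trainXs - plsScores(ma) %*% t(plsLoadings(ma)))^2)
  }, numeric(1))
  expect_true(all(diff(xres) <= 1e-12))
})

test_that("VIP satisfies its normalization identity and flags signal", {
  d1 <- randXy(15, 1, 106)
  expect_equal(unname(vip(fitPls(d1$X, d1$y, nLv = 1))), 1)
  d <- randXy(30, 5, 107)
  m <- fitPls(d$X, d$y, nLv = 3)
  expect_equal(sum(vip(m)^2), 5, tolerance = 1e-10)
  set.seed(108)
  Xs <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("d", 1:5)))
  ys <- 2 * Xs[, 1] + rnorm(40, sd = 0.2)
  vs <- vip(fitPls(Xs, ys, nLv = 2))
  expect_gt(vs["d1"], 1)
  expect_true(all(vs[-1] < vs["d1"]))
})

test_that("coefficients and transformed weights follow the sign conventions", {
  set.seed(112)
  M <- scale(matrix(rnorm(48), 12, 4), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))  # mean-zero orthonormal columns
  colnames(Q) <- paste0("q", 1:4)
  y12 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8)
  m <- fitPls(Q, y12, nLv = 1, scale = FALSE)
  ct <- coefficientTable(m)
  expect_true(all(m@q >= 0))
  # orthonormal X: one component captures the least-squares projection,
  # there is no deflation mixing (w* = w) and nothing left to extract
  expect_equal(ct$weightsStar, ct$weights, tolerance = 1e-10)
  expect_equal(m@fitted, as.numeric(mean(y12) + Q %*% crossprod(Q, y12 - mean(y12))),
               tolerance = 1e-10)
  expect_error(fitPls(Q, y12, nLv = 2, scale = FALSE), "residual covariance")
  # in general P'W is unit upper-triangular, which defines W*
  d <- randXy(25, 5, 113)
  mg <- fitPls(d$X, d$y, nLv = 3)
  PtW <- crossprod(mg@P, mg@W)
  expect_equal(diag(PtW), rep(1, 3), tolerance = 1e-10)
  expect_lt(max(abs(PtW[lower.tri(PtW)])), 1e-10)
  set.seed(109)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "neg"))
  y <- -2 * x[, 1] + rnorm(30, sd = 0.1)
  m2 <- fitPls(x, y, nLv = 1)
  expect_lt(coefficientTable(m2)$coefficients["neg"], 0)
})

test_that("Hotelling T2 limit approaches the chi-square law for large n", {
  set.seed(110)
  n <- 1e5
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- X %*% c(1, 0.5, -1) + rnorm(n)
  m <- fitPls(X, as.numeric(y), nLv = 2)
  h <- hotellingT2(m, confidence = 0.95)
  expect_equal(h$limit, qchisq(0.95, 2), tolerance = 1e-3)
  # a row at the score origin has T2 = 0
  meanRow <- matrix(m@xMean, 1, dimnames = list(NULL, colnames(X)))
  expect_equal(hotellingT2(m, meanRow)$t2, 0, tolerance = 1e-10)
})

test_that("DModX flags rows off the model plane and rejects perfect fits", {
  set.seed(111)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- X %*% rnorm(p) + rnorm(n, sd = 0.3)
  m <- fitPls(X, as.numeric(y), nLv = 2)
  ad <- dmodx(m, confidence = 0.99)
  expect_s4_class(ad, "AdReport")
  expect_true(all(ad@inDomain == (ad@dmodx <= ad@dCrit)))
  # perturb a row along a left-null-space direction of the loadings
  P <- plsLoadings(m)
  nullsp <- qr.Q(qr(cbind(P, matrix(rnorm(p * (p - 2)), p))))[, (2 + 1):p]
  v <- nullsp[, 1]
  row <- X[1, ] + 50 * v * m@xSd
  adNew <- dmodx(m, matrix(row, 1, dimnames = list(NULL, colnames(X))))
  expect_false(adNew@inDomain[1])
  # an exactly reproduced X-space makes the distance undefined
  mFull <- fitPls(X[, 1:3], as.numeric(y), nLv = 3)
  expect_error(dmodx(mFull), "undefined")
})
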