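test_that("fit statistics match hand arithmetic", {
  y <- c(1, 2, 3, 4); yhat <- c(1.1, 1.9, 3.2, 3.8)
  # RSS = 0.01 + 0.01 + 0.04 + 0.04 = 0.10; TSS about mean 2.5 = 5.0
  expect_equal(rSquared(y, yhat), 1 - 0.10 / 5.0, tolerance = 1e-12)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0)
  expect_equal(standardError(y, yhat, 1), sqrt(0.10 / 2), tolerance = 1e-12)
  expect_equal(standardError(y, y, 1), 0)
  r2 <- 1 - 0.10 / 5
  expect_equal(fStatistic(y, yhat, 1), (r2 / 1) / ((1 - r2) / 2),
               tolerance = 1e-12)
})

test_that("external Q2F1/Q2F2 use the documented denominators", {
  yTest <- c(1, 2, 3); yhat <- c(1, 2, 4)
  # PRESS = 1; sum((y - 1.5)^2) = 0.25 + 0.25 + 2.25 = 2.75
  out <- q2External(yTest, yhat, yTrainMean = 1.5)
  expect_equal(out[["q2F1"]], 1 - 1 / 2.75, tolerance = 1e-12)
  expect_equal(out[["q2F2"]], 1 - 1 / 2, tolerance = 1e-12)
  expect_equal(out[["rmse"]], sqrt(1 / 3), tolerance = 1e-12)
  perfect <- q2External(yTest, yTest, 1.5)
  expect_equal(unname(perfect[c("q2F1", "q2F2")]), c(1, 1))
  # equal means make the two metrics coincide
  same <- q2External(yTest, yhat, yTrainMean = mean(yTest))
  expect_equal(same[["q2F1"]], same[["q2F2"]])
})

test_that("LOO Q2 equals an explicit refit loop and detects noise", {
  looOracle <- function(X, y, nLv) {  # independent naive loop
    pred <- vapply(seq_len(nrow(X)), function(i) {
      fit <- fitPls(X[-i, , drop = FALSE], y[-i], nLv = nLv)
      predict(fit, X[i, , drop = FALSE])
    }, numeric(1))
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }
  set.seed(201)
  for (rep in 1:10) {
    n <- sample(5:10, 1); p <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
    y <- rnorm(n)
    expect_equal(q2Loo(X, y, nLv = 2), looOracle(X, y, 2), tolerance = 1e-12)
  }
  # noiseless linear response
  set.seed(202)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- X %*% c(1, -2, 0.5)
  expect_gt(q2Loo(X, as.numeric(y), nLv = 3), 0.999)
  # y independent of X: Q2 at or below 0 on average
  q2s <- vapply(1:40, function(k) {
    set.seed(300 + k)
    Xr <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("d", 1:3)))
    q2Loo(Xr, rnorm(10), nLv = 2)
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("metrics are invariant to row permutation", {
  set.seed(203)
  X <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- X %*% rnorm(4) + rnorm(12, sd = 0.2)
  perm <- sample(12)
  expect_equal(q2Loo(X, as.numeric(y), 2),
               q2Loo(X[perm, ], as.numeric(y)[perm], 2), tolerance = 1e-10)
  m1 <- fitPls(X, as.numeric(y), nLv = 2)
  m2 <- fitPls(X[perm, ], as.numeric(y)[perm], nLv = 2)
  expect_equal(rSquared(as.numeric(y), m1@fitted),
               rSquared(as.numeric(y)[perm], m2@fitted), tolerance = 1e-10)
})

test_that("Y-randomization separates real structure from chance", {
  set.seed(204)
  X <- matrix(rnorm(41 * 5), 41, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- as.numeric(X %*% c(1, -1, 0.5, 0, 0) + rnorm(41, sd = 0.4))
  yr <- yRandomization(X, y, nLv = 3, nPerm = 30, seed = 9)
  expect_equal(nrow(yr$records), 30)
  expect_lt(yr$r2Intercept, 0.3)
  expect_lt(yr$q2Intercept, 0.05)
  expect_true(yr$pass)
  # determinism under the seed
  yr2 <- yRandomization(X, y, nLv = 3, nPerm = 30, seed = 9)
  expect_identical(yr$records, yr2$records)
  expect_identical(yr$r2Intercept, yr2$r2Intercept)
  expect_error(yRandomization(X, y, 3, nPerm = 5), "at least 10")
})

test_that("the unpermuted model anchors the intercept regression at c = 1", {
  set.seed(205)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- as.numeric(X %*% c(2, -1, 1) + rnorm(20, sd = 0.2))
  m <- fitPls(X, y, nLv = 2)
  r2Real <- rSquared(y, m@fitted)
  yrIn <- yRandomization(X, y, nLv = 2, nPerm = 15, seed = 2,
                         includeUnpermuted = TRUE)
  yrOut <- yRandomization(X, y, nLv = 2, nPerm = 15, seed = 2,
                          includeUnpermuted = FALSE)
  # anchoring at (1, r2Real) pulls the fitted line upward at c = 1,
  # so the two intercept estimates must differ
  expect_false(isTRUE(all.equal(yrIn$r2Intercept, yrOut$r2Intercept)))
  expect_gt(r2Real, max(yrIn$records$r2))
})
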