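makeSelTable <- function(X, y) {
  rownames(X) <- sprintf("c%02d", seq_len(nrow(X)))
  descriptorTable(X, stats::setNames(y, rownames(X)))
}

test_that("subset fitness recovers noiseless truth and guards degeneracy", {
  set.seed(301)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- 3 * X[, 2]
  tab <- makeSelTable(X, y)
  cfg <- dcvConfig(nRepeats = 2, seed = 4)
  expect_lt(evaluateSubset("d2", tab, cfg), 1e-10)
  # pure-noise subset on a shuffled response: error near the scale of the
  # mean-predictor's MAE (sd * sqrt(2/pi) for a normal response)
  set.seed(302)
  ysh <- sample(rnorm(40))
  tabN <- makeSelTable(X, ysh)
  fitN <- evaluateSubset("d5", tabN, cfg)
  expect_gt(fitN, 0.5 * sd(ysh) * sqrt(2 / pi))
  expect_lt(fitN, 2 * sd(ysh))
  # subset larger than a calibration fold
  small <- makeSelTable(X[1:8, ], y[1:8])
  expect_equal(evaluateSubset(paste0("d", 1:6), small,
                              dcvConfig(kFolds = 2, nRepeats = 1)), Inf)
  expect_error(evaluateSubset("nope", tab, cfg), "unknown")
})

test_that("the GA is reproducible and degenerates sensibly", {
  set.seed(303)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y <- as.numeric(X[, 3] - X[, 6] + rnorm(30, sd = 0.1))
  tab <- makeSelTable(X, y)
  cfg <- dcvConfig(population = 20, generations = 15, nRepeats = 2, seed = 11)
  r1 <- runGA(tab, cfg)
  r2 <- runGA(tab, cfg)
  expect_identical(r1, r2)
  expect_true(all(vapply(r1, function(c) c$size, numeric(1)) <= 5))
  expect_true(all(c("d3", "d6") %in% r1[[1]]$subset))
  # single-descriptor pool returns the singleton
  one <- makeSelTable(X[, 3, drop = FALSE], y)
  rOne <- runGA(one, cfg)
  expect_length(rOne, 1)
  expect_equal(rOne[[1]]$subset, "d3")
})

test_that("GA matches exhaustive search on a small pool (brute-force oracle)", {
  set.seed(304)
  n <- 50; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
  y <- as.numeric(X %*% replace(rep(0, p), c(3, 7, 11), c(1.5, -1, 1)) +
                    rnorm(n, sd = 0.1 * sd(X %*% rep(0.3, p))))
  tab <- makeSelTable(X, y)
  cfg <- dcvConfig(population = 40, generations = 40, nRepeats = 2,
                   maxSubsetSize = 3, seed = 21)
  top <- runGA(tab, cfg)[[1]]
  # oracle: every 3-subset evaluated with the same fitness functional
  combos <- utils::combn(p, 3)
  fits <- apply(combos, 2, function(s)
    evaluateSubset(paste0("d", s), tab, cfg))
  best <- combos[, which.min(fits)]
  expect_setequal(top$subset, paste0("d", best))
  expect_setequal(top$subset, c("d3", "d7", "d11"))
  expect_equal(top$fitness, min(fits), tolerance = 1e-12)
})

test_that("elitism makes the best fitness non-increasing over generations", {
  set.seed(305)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("d", 1:10)))
  y <- as.numeric(X[, 2] + rnorm(30, sd = 0.3))
  tab <- makeSelTable(X, y)
  fits <- vapply(c(2, 8, 25), function(g)
    runGA(tab, dcvConfig(population = 20, generations = g, nRepeats = 2,
                         seed = 31))[[1]]$fitness, numeric(1))
  expect_true(all(diff(fits) <= 1e-12))
})

test_that("external assessment never feeds the test set back into ranking", {
  set.seed(306)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y <- as.numeric(X[, 1] - 2 * X[, 4] + rnorm(60, sd = 0.2))
  tab <- makeSelTable(X, y)
  train <- tab[sprintf("c%02d", 1:40), ]
  test <- tab[sprintf("c%02d", 41:60), ]
  cand <- runGA(train, dcvConfig(population = 20, generations = 20,
                                 nRepeats = 2, seed = 41))
  rep <- dcvReport(cand, train, test, m = 3)
  expect_lte(nrow(rep), 3)
  expect_identical(rep$fitness, sort(rep$fitness))  # ranked by inner fitness
  truthRow <- grepl("d1\\b", rep$subset[1]) && grepl("d4", rep$subset[1])
  expect_true(truthRow)
  # the true model predicts the external set better than a random subset
  randRep <- dcvReport(list(list(subset = c("d2", "d3", "d5"), fitness = 1,
                                 size = 3L)), train, test, m = 1)
  expect_gt(rep$q2F1[1], randRep$q2F1[1])
})
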