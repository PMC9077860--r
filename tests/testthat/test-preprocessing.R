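makeTable <- function(X, y = rep(NA_real_, nrow(X)),
                      ids = sprintf("c%02d", seq_len(nrow(X)))) {
  rownames(X) <- ids
  descriptorTable(X, stats::setNames(y, ids))
}

test_that("pretreatment drops missing, constant and correlated columns", {
  set.seed(11)
  base <- rnorm(20)
  X <- cbind(const = rep(3.2, 20),
             allmiss = rep(NA_real_, 20),
             onemiss = c(NA, rnorm(19)),
             a = base,
             b = base,                      # r = 1 with a
             c = rnorm(20))
  out <- pretreat(makeTable(X))
  kept <- descriptorNames(out$table)
  expect_setequal(kept, c("a", "c"))
  expect_setequal(out$log$column, c("const", "allmiss", "onemiss", "b"))
  expect_match(out$log$reason[out$log$column == "const"], "sd")
  expect_match(out$log$reason[out$log$column == "b"], "a")
})

test_that("correlation pruning keeps the higher-variance member", {
  set.seed(12)
  a <- rnorm(50)
  X <- cbind(a = a,
             a2 = 3 * a + rnorm(50, sd = 0.1),  # r > 0.95, larger variance
             c = rnorm(50))
  kept <- descriptorNames(pretreat(makeTable(X))$table)
  expect_true("a2" %in% kept)
  expect_false("a" %in% kept)
  expect_true("c" %in% kept)
  r <- abs(cor(X[, c("a", "a2")]))[1, 2]
  expect_gte(r, 0.95)
})

test_that("pretreatment is idempotent", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("d", 1:10)))
  X[, 2] <- X[, 1] * 1.01 + 0.001
  once <- pretreat(makeTable(X))$table
  twice <- pretreat(once)$table
  expect_identical(descriptorNames(once), descriptorNames(twice))
  expect_equal(descriptorValues(once), descriptorValues(twice))
})

test_that("k-medoids separates well-separated blobs and matches PAM", {
  set.seed(21)
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 8), 20, 2))
  colnames(X) <- c("d1", "d2")
  tab <- makeTable(X)
  sr <- kMedoids(tab, k = 2, seed = 5)
  cl <- clusterAssignments(sr)
  truth <- rep(1:2, each = 20)
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
  expect_true(all(medoidIds(sr) %in% compoundIds(tab)))
  pam <- cluster::pam(scale(X), k = 2, cluster.only = TRUE)
  agreePam <- max(mean(cl == pam), mean(cl == 3 - pam))
  expect_equal(agreePam, 1)
})

test_that("k-medoids handles degenerate inputs deterministically", {
  X <- matrix(1, 8, 2, dimnames = list(NULL, c("d1", "d2")))
  X <- X + 0  # duplicate points only
  tab <- makeTable(X)
  sr <- kMedoids(tab, k = 2, seed = 3)
  expect_equal(length(unique(clusterAssignments(sr))), 2)
  # identical re-run
  sr2 <- kMedoids(tab, k = 2, seed = 3)
  expect_identical(clusterAssignments(sr), clusterAssignments(sr2))
  # k = n: every point its own medoid
  set.seed(31)
  X2 <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("d1", "d2")))
  sr3 <- kMedoids(makeTable(X2), k = 6, seed = 1)
  expect_equal(sort(unique(clusterAssignments(sr3))), 1:6)
  expect_equal(length(unique(medoidIds(sr3))), 6)
})

test_that("activity-ranked division fills per-cluster quotas", {
  set.seed(41)
  X <- matrix(rnorm(122), 61, 2, dimnames = list(NULL, c("d1", "d2")))
  y <- rnorm(61)
  tab <- makeTable(X, y)
  sr <- splitTrainTest(kMedoids(tab, k = 5, seed = 7), tab)
  expect_setequal(c(trainIds(sr), testIds(sr)), compoundIds(tab))
  expect_length(intersect(trainIds(sr), testIds(sr)), 0)
  expect_lte(abs(length(testIds(sr)) - 20), 1)

  # one cluster of 3: the middle-activity compound goes to the test set
  X3 <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y3 <- c(2, 0, 1)
  t3 <- makeTable(X3, y3)
  cl3 <- new("SplitResult",
             clusters = stats::setNames(rep(1L, 3), compoundIds(t3)),
             medoids = compoundIds(t3)[1],
             trainIds = character(), testIds = character())
  s3 <- splitTrainTest(cl3, t3)
  expect_equal(testIds(s3), compoundIds(t3)[3])  # rank 2 by activity
  expect_length(trainIds(s3), 2)
})

test_that("division is deterministic and tie-broken by input order", {
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("d1", "d2")))
  y <- rep(1, 15)  # all activities tied
  tab <- makeTable(X, y)
  cl <- new("SplitResult",
            clusters = stats::setNames(rep(1L, 15), compoundIds(tab)),
            medoids = compoundIds(tab)[1],
            trainIds = character(), testIds = character())
  s1 <- splitTrainTest(cl, tab)
  s2 <- splitTrainTest(cl, tab)
  expect_identical(testIds(s1), testIds(s2))
  expect_equal(testIds(s1), compoundIds(tab)[c(2, 5, 8, 11, 14)])
})
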