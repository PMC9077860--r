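# Descriptor-matrix pretreatment and k-medoids based train/test division.

#' Pretreat a descriptor table
#'
#' Removes, in order: columns with all values missing, columns with any
#' value missing, (near-)constant columns (standard deviation below
#' \code{sdCut}), and then, for every pair with absolute Pearson
#' correlation at or above \code{corrCut}, the lower-variance member
#' (earlier column kept on ties). The operation is idempotent.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param sdCut standard-deviation cutoff (default 0.0001).
#' @param corrCut absolute pair-correlation cutoff (default 0.95).
#' @return list with \code{table} (the pruned \linkS4class{DescriptorTable})
#'   and \code{log} (data.frame of dropped columns and reasons).
#' @export
pretreat <- function(table, sdCut = 1e-4, corrCut = 0.95) {
  stopifnot(is(table, "DescriptorTable"))
  X <- table@values
  if (ncol(X) == 0L) stop("empty descriptor table")
  log <- data.frame(column = character(), reason = character(),
                    stringsAsFactors = FALSE)
  drop <- function(cols, reason) {
    if (!length(cols)) return(invisible())
    log <<- rbind(log, data.frame(column = colnames(X)[cols],
                                  reason = reason))
    X <<- X[, -cols, drop = FALSE]
  }
  nmiss <- colSums(is.na(X))
  drop(which(nmiss == nrow(X)), "all values missing")
  nmiss <- colSums(is.na(X))
  drop(which(nmiss > 0), "missing value(s)")
  sds <- apply(X, 2, stats::sd)
  drop(which(sds < sdCut), sprintf("sd < %g", sdCut))
  # pairwise correlation pruning: repeatedly resolve the strongest pair
  repeat {
    if (ncol(X) < 2L) break
    r <- abs(suppressWarnings(stats::cor(X)))
    diag(r) <- 0
    if (max(r) < corrCut) break
    idx <- which(r == max(r), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    v <- apply(X[, c(i, j), drop = FALSE], 2, stats::var)
    loser <- if (v[1] > v[2]) j else if (v[2] > v[1]) i else j
    kept <- setdiff(c(i, j), loser)
    drop(loser, sprintf("|r| >= %g with %s", corrCut, colnames(X)[kept]))
  }
  if (ncol(X) == 0L) stop("pretreatment removed every descriptor column")
  out <- table
  out@values <- X
  validObject(out)
  list(table = out, log = log)
}

# Euclidean distances on autoscaled descriptors
.scaledDist <- function(X) {
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(matrix(0, nrow(X), nrow(X)))  # all rows identical
  Xs <- scale(X[, keep, drop = FALSE])
  as.matrix(stats::dist(Xs))
}

#' k-medoids clustering of a descriptor table
#'
#' PAM-style alternation on Euclidean distances over autoscaled
#' descriptors: points are assigned to the nearest medoid, then each
#' medoid is replaced by the member of its cluster minimising the
#' within-cluster distance sum, until assignments stabilise (at most
#' \code{maxIter} rounds). Medoids are initialised with a seeded
#' farthest-point (k-means++-style) rule; an emptied cluster is re-seeded
#' from the point farthest from all current medoids.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param k number of clusters (default 5).
#' @param seed integer seed.
#' @param maxIter iteration cap (default 300).
#' @return a \linkS4class{SplitResult} with cluster assignments and
#'   medoids (train/test empty until \code{\link{splitTrainTest}}).
#' @export
kMedoids <- function(table, k = 5, seed = 1, maxIter = 300) {
  stopifnot(is(table, "DescriptorTable"))
  n <- length(table@ids)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  D <- .scaledDist(table@values)
  med <- integer(k)
  rng <- .seededRng(seed)
  med[1] <- rng$int(n)
  for (j in 2:k) {
    dmin <- apply(D[, med[seq_len(j - 1L)], drop = FALSE], 1, min)
    dmin[med[seq_len(j - 1L)]] <- -1
    med[j] <- which.max(dmin)
  }
  assign <- integer(n)
  for (iter in seq_len(maxIter)) {
    newAssign <- apply(D[, med, drop = FALSE], 1, which.min)
    newAssign[med] <- seq_len(k)  # a medoid belongs to its own cluster
    for (c in seq_len(k)) {
      if (!any(newAssign == c)) {  # re-seed an emptied cluster
        dmin <- apply(D[, med, drop = FALSE], 1, min)
        far <- which.max(dmin)
        med[c] <- far
        newAssign[far] <- c
      }
    }
    for (c in seq_len(k)) {
      members <- which(newAssign == c)
      cost <- colSums(D[members, members, drop = FALSE])
      med[c] <- members[which.min(cost)]
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
  }
  new("SplitResult",
      clusters = stats::setNames(as.integer(assign), table@ids),
      medoids = table@ids[med],
      trainIds = character(), testIds = character())
}

#' Activity-ranked train/test division within clusters
#'
#' Within each cluster, members are sorted by response (ties broken by
#' input order) and every third member (ranks 2, 5, 8, ...) is assigned to
#' the test set until the per-cluster quota \code{round(testFraction *
#' size)} is met; the remainder stays in the training set.
#'
#' @param clusters a \linkS4class{SplitResult} from \code{\link{kMedoids}}.
#' @param table the \linkS4class{DescriptorTable} carrying the response.
#' @param testFraction target test fraction (default 0.34).
#' @return the \linkS4class{SplitResult} with \code{trainIds}/\code{testIds}
#'   filled in.
#' @export
splitTrainTest <- function(clusters, table, testFraction = 0.34) {
  stopifnot(is(clusters, "SplitResult"), is(table, "DescriptorTable"))
  ids <- names(clusters@clusters)
  resp <- response(table)[ids]
  if (anyNA(resp)) stop("response required for train/test division")
  test <- character()
  for (c in sort(unique(clusters@clusters))) {
    members <- ids[clusters@clusters == c]
    ord <- members[order(resp[members], match(members, ids))]
    quota <- round(testFraction * length(ord))
    picks <- if (length(ord) >= 2L) seq(2L, length(ord), by = 3L) else integer()
    test <- c(test, ord[utils::head(picks, quota)])
  }
  out <- clusters
  out@testIds <- test
  out@trainIds <- setdiff(ids, test)
  validObject(out)
  out
}

# small deterministic RNG helper: isolates seeded draws from the global
# RNG stream
.seededRng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  })
  draw <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    out
  }
  list(int = function(n) draw(function() sample.int(n, 1L)),
       sample = function(x, size = length(x), replace = FALSE, prob = NULL)
         draw(function() sample(x, size, replace, prob)),
       runif = function(n) draw(function() stats::runif(n)),
       rnorm = function(n, sd = 1) draw(function() stats::rnorm(n, sd = sd)))
}
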