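# Genetic-algorithm descriptor-subset search inside the inner loop of
# double cross-validation (DCV). The outer train/test division is fixed
# beforehand (see splitTrainTest); the GA only ever sees the training
# compounds, whose calibration/validation recompositions come from
# repeated stratified k-fold assignments.

#' Configuration for GA subset selection under double cross-validation
#'
#' @param kFolds inner cross-validation folds (default 10).
#' @param nRepeats number of reshuffled fold assignments the fitness is
#'   averaged over (default 10).
#' @param population GA population size (default 50).
#' @param generations GA generations (default 100).
#' @param crossoverP one-point crossover probability (default 0.9).
#' @param mutationP per-bit mutation probability (default 0.01).
#' @param elitism number of elites copied unchanged (default 1).
#' @param maxSubsetSize largest allowed descriptor subset (default 5).
#' @param fitness validation-error measure pooled over folds:
#'   \code{"mae"} (default) or \code{"rmse"}.
#' @param seed integer seed; the whole search is reproducible under it.
#' @return validated configuration list of class \code{dcvConfig}.
#' @export
dcvConfig <- function(kFolds = 10, nRepeats = 10, population = 50,
                      generations = 100, crossoverP = 0.9,
                      mutationP = 0.01, elitism = 1, maxSubsetSize = 5,
                      fitness = c("mae", "rmse"), seed = 1) {
  fitness <- match.arg(fitness)
  cfg <- list(kFolds = as.integer(kFolds), nRepeats = as.integer(nRepeats),
              population = as.integer(population),
              generations = as.integer(generations),
              crossoverP = crossoverP, mutationP = mutationP,
              elitism = as.integer(elitism),
              maxSubsetSize = as.integer(maxSubsetSize),
              fitness = fitness, seed = as.integer(seed))
  if (cfg$kFolds < 2L) stop("kFolds must be >= 2")
  if (cfg$maxSubsetSize < 1L) stop("maxSubsetSize must be >= 1")
  if (cfg$population < 2L) stop("population must be >= 2")
  class(cfg) <- "dcvConfig"
  cfg
}

# stratified fold assignment: rows are blocked by response quantile and
# fold labels dealt cyclically inside a shuffled order
.makeFolds <- function(y, k, rng) {
  n <- length(y)
  ord <- order(y)  # quantile blocks of k consecutive-response rows
  blocks <- split(ord, ceiling(seq_along(ord) / k))
  folds <- integer(n)
  for (b in blocks) {
    sh <- if (length(b) > 1L) rng$sample(b) else b
    folds[sh] <- rep_len(seq_len(k), length(sh))
  }
  folds
}

# pooled k-fold OLS validation error for one descriptor subset
.subsetCvError <- function(X, y, subset, foldSets, measure) {
  errs <- numeric()
  for (folds in foldSets) {
    for (f in sort(unique(folds))) {
      cal <- folds != f
      if (sum(cal) <= length(subset) + 2L) return(Inf)
      Xc <- cbind(1, X[cal, subset, drop = FALSE])
      fit <- tryCatch(.lm.fit(Xc, y[cal]), error = function(e) NULL)
      if (is.null(fit) || any(is.na(fit$coefficients)) ||
          fit$rank < ncol(Xc)) return(Inf)
      pv <- cbind(1, X[!cal, subset, drop = FALSE]) %*% fit$coefficients
      errs <- c(errs, y[!cal] - pv)
    }
  }
  if (measure == "mae") mean(abs(errs)) else sqrt(mean(errs^2))
}

#' Cross-validated fitness of one descriptor subset
#'
#' Fits ordinary least squares on each calibration part of the (repeated)
#' stratified k-fold assignment and pools the validation-part errors;
#' lower is better. Singular designs or subsets larger than a calibration
#' fold receive infinite fitness.
#'
#' @param subset descriptor names or column indices.
#' @param train training \linkS4class{DescriptorTable}.
#' @param cfg a \code{\link{dcvConfig}}.
#' @return pooled validation error (MAE by default).
#' @export
evaluateSubset <- function(subset, train, cfg = dcvConfig()) {
  stopifnot(is(train, "DescriptorTable"))
  X <- descriptorValues(train)
  if (is.character(subset)) subset <- match(subset, colnames(X))
  if (anyNA(subset) || !length(subset)) stop("unknown or empty subset")
  y <- as.numeric(response(train))
  rng <- .seededRng(cfg$seed)
  foldSets <- lapply(seq_len(cfg$nRepeats),
                     function(i) .makeFolds(y, cfg$kFolds, rng))
  .subsetCvError(X, y, subset, foldSets, cfg$fitness)
}

#' Genetic-algorithm descriptor selection
#'
#' Binary chromosomes over the descriptor columns evolve by tournament
#' selection (size 2), one-point crossover, per-bit mutation and elitism;
#' fitness is the pooled k-fold validation error of
#' \code{\link{evaluateSubset}}, averaged over \code{nRepeats} reshuffled
#' fold assignments that are drawn once per run. Subsets exceeding
#' \code{maxSubsetSize} are trimmed at random; empty ones receive a random
#' bit. Results are bit-identical across runs under a fixed seed.
#'
#' @param train pretreated training \linkS4class{DescriptorTable}.
#' @param cfg a \code{\link{dcvConfig}}.
#' @return list of chromosomes sorted by fitness (ties: fewer descriptors,
#'   then column order), each a list with \code{subset} (descriptor
#'   names), \code{fitness} and \code{size}.
#' @export
runGA <- function(train, cfg = dcvConfig()) {
  stopifnot(is(train, "DescriptorTable"))
  X <- descriptorValues(train)
  y <- as.numeric(response(train))
  p <- ncol(X)
  rng <- .seededRng(cfg$seed)
  foldSets <- lapply(seq_len(cfg$nRepeats),
                     function(i) .makeFolds(y, cfg$kFolds, rng))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fitnessOf <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- .subsetCvError(X, y, which(mask), foldSets, cfg$fitness)
    cache[[key]] <- v
    v
  }
  repairMask <- function(mask) {
    on <- which(mask)
    if (length(on) > cfg$maxSubsetSize) {
      keep <- rng$sample(on, cfg$maxSubsetSize)
      mask[] <- FALSE; mask[keep] <- TRUE
    } else if (!length(on)) {
      mask[rng$int(p)] <- TRUE
    }
    mask
  }
  if (p == 1L) {
    m <- rep(TRUE, 1)
    return(list(list(subset = colnames(X), fitness = fitnessOf(m), size = 1L)))
  }
  pop <- lapply(seq_len(cfg$population), function(i) {
    size <- rng$int(cfg$maxSubsetSize)
    mask <- rep(FALSE, p)
    mask[rng$sample(seq_len(p), size)] <- TRUE
    mask
  })
  fit <- vapply(pop, fitnessOf, numeric(1))
  orderPop <- function(fit, pop) {
    sizes <- vapply(pop, sum, numeric(1))
    firstCol <- vapply(pop, function(m) if (any(m)) which(m)[1] else p + 1L,
                       numeric(1))
    order(fit, sizes, firstCol)
  }
  for (gen in seq_len(cfg$generations)) {
    ord <- orderPop(fit, pop)
    newPop <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
    while (length(newPop) < cfg$population) {
      pick <- function() {  # tournament of 2
        ij <- rng$sample(seq_along(pop), 2L)
        if (fit[ij[1]] <= fit[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      a <- pick(); b <- pick()
      if (rng$runif(1) < cfg$crossoverP) {
        cut <- rng$int(p - 1L)
        child <- c(a[seq_len(cut)], b[(cut + 1L):p])
      } else child <- a
      flip <- rng$runif(p) < cfg$mutationP
      child[flip] <- !child[flip]
      newPop[[length(newPop) + 1L]] <- repairMask(child)
    }
    pop <- newPop
    fit <- vapply(pop, fitnessOf, numeric(1))
  }
  ord <- orderPop(fit, pop)
  lapply(ord, function(i)
    list(subset = colnames(X)[pop[[i]]], fitness = fit[i],
         size = sum(pop[[i]])))
}

#' External assessment of top GA candidates
#'
#' The top candidate subsets are refit by ordinary least squares on the
#' full training set and assessed once on the untouched test set; test
#' results are reported but never fed back into selection.
#'
#' @param candidates ranked chromosome list from \code{\link{runGA}}.
#' @param train training \linkS4class{DescriptorTable}.
#' @param test test \linkS4class{DescriptorTable}.
#' @param m number of top candidates to report (default 5).
#' @return data.frame with one row per candidate: subset, inner fitness,
#'   training R2, external Q2F1/Q2F2 and RMSEP.
#' @export
dcvReport <- function(candidates, train, test, m = 5) {
  seen <- character(); rows <- list()
  for (cand in candidates) {
    key <- paste(sort(cand$subset), collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    Xtr <- descriptorValues(train)[, cand$subset, drop = FALSE]
    ytr <- as.numeric(response(train))
    df <- data.frame(y = ytr, Xtr, check.names = FALSE)
    fit <- stats::lm(y ~ ., data = df)
    Xte <- descriptorValues(test)[, cand$subset, drop = FALSE]
    yte <- as.numeric(response(test))
    pred <- as.numeric(stats::predict(fit, data.frame(Xte, check.names = FALSE)))
    ext <- q2External(yte, pred, mean(ytr))
    rows[[length(rows) + 1L]] <- data.frame(
      subset = paste(cand$subset, collapse = "+"),
      size = cand$size, fitness = cand$fitness,
      r2Train = rSquared(ytr, stats::fitted(fit)),
      q2F1 = ext[["q2F1"]], q2F2 = ext[["q2F2"]], rmsep = ext[["rmse"]])
    if (length(rows) >= m) break
  }
  do.call(rbind, rows)
}
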