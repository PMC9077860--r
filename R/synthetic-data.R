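# Synthetic molecule sets with linearly structured activities. The
# generator emulates the chemistry of plant-derived larvicide panels --
# small C/H/O/N/Cl molecules built from monoterpene-like carbocycles and
# phenylpropanoid-like benzene cores carrying oxygenated substituents --
# so that descriptor ranges, collinearity and signal-plus-noise structure
# resemble what the modelling pipeline faces on real data.

.CORES <- c(cyclohexane = "C1CCCCC1", benzene = "c1ccccc1",
            cyclohexene = "C1=CCCCC1", norbornane = "C1CC2CCC1C2",
            decalin = "C1CCC2CCCCC2C1")
# substituent pool: SMILES fragment + heteroatom flag
.SUBS <- data.frame(
  frag = c("C", "CC", "C(C)C", "C=C", "CC=C",
           "O", "OC", "Cl", "C(=O)OC", "OC(=O)C", "C(=O)C", "N", "CO"),
  hetero = c(FALSE, FALSE, FALSE, FALSE, FALSE,
             TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Build a synthetic-data specification
#'
#' Defaults describe a 60-compound panel in which roughly one third of the
#' molecules are pure hydrocarbons and the rest carry oxygen-, nitrogen-
#' or chlorine-bearing substituents, and in which the activity is a linear
#' function of three ETA descriptors on the autoscaled scale
#' (hydrogen-bond-donor and sigma-count terms depressing it, the
#' functionality index raising it, mirroring the signs such panels show)
#' plus Gaussian noise at a 9:1 signal-to-noise variance ratio.
#'
#' @param nCompounds number of molecules (default 60).
#' @param heteroWeight probability that a drawn substituent is
#'   heteroatom-bearing (default 0.6).
#' @param maxSubstituents per-core substituent cap (default 3).
#' @param trueSubset descriptor names carrying the signal.
#' @param trueCoefficients their coefficients on autoscaled descriptors.
#' @param noiseSd absolute noise standard deviation; \code{NA} (default)
#'   derives it from the realised signal as \code{sd(signal)/3}, i.e. a
#'   9:1 signal-to-noise variance ratio.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nCompounds = 60, heteroWeight = 0.6,
                          maxSubstituents = 3,
                          trueSubset = c("ETA_dEpsilon_D", "ETA_EtaP_F",
                                         "ETA_BetaP_s"),
                          trueCoefficients = c(-1, 1, -1),
                          noiseSd = NA_real_, seed = 1) {
  new("SyntheticSpec", nCompounds = as.integer(nCompounds),
      heteroWeight = heteroWeight,
      maxSubstituents = as.integer(maxSubstituents),
      trueSubset = trueSubset, trueCoefficients = trueCoefficients,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# one random SMILES from the grammar: core + parenthesised substituents
.randomSmiles <- function(rng, heteroWeight, maxSubstituents) {
  core <- .CORES[[rng$int(length(.CORES))]]
  nSub <- rng$int(maxSubstituents + 1L) - 1L
  if (nSub == 0L) return(core)
  # ring-atom token positions where a branch can be attached
  pos <- gregexpr("[A-Za-z][0-9]*", core)[[1]]
  ends <- pos + attr(pos, "match.length") - 1L
  sites <- rng$sample(seq_along(pos), min(nSub, length(pos)))
  frags <- vapply(seq_along(sites), function(i) {
    pool <- if (rng$runif(1) < heteroWeight) which(.SUBS$hetero)
            else which(!.SUBS$hetero)
    .SUBS$frag[pool[rng$int(length(pool))]]
  }, character(1))
  out <- core
  for (i in order(sites, decreasing = TRUE)) {
    at <- ends[sites[i]]
    out <- paste0(substr(out, 1, at), "(", frags[i], ")",
                  substr(out, at + 1L, nchar(out)))
  }
  out
}

#' Generate a synthetic molecule set
#'
#' Seeded construction of valence-correct SMILES from the scaffold
#' grammar; duplicates (by canonical SMILES) are removed and generation
#' continues until \code{nCompounds} distinct molecules exist. All
#' molecules parse through \code{\link{readSmiles}}'s machinery, i.e. they
#' come back hydrogen-explicit and Kekulized.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return named list of \linkS4class{Molecule} (ids \code{syn01} ...).
#' @export
generateMolecules <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  rng <- .seededRng(spec@seed)
  smis <- character(); seen <- character()
  guard <- 0L
  while (length(smis) < spec@nCompounds) {
    guard <- guard + 1L
    if (guard > 50L * spec@nCompounds)
      stop("grammar failed to produce enough distinct molecules")
    s <- .randomSmiles(rng, spec@heteroWeight, spec@maxSubstituents)
    canon <- tryCatch(
      trimws(sub("\\s.*$", "",
                 ChemmineOB::convertFormat("SMI", "CAN", source = s))),
      error = function(e) NA_character_)
    if (is.na(canon) || !nzchar(canon) || canon %in% seen) next
    seen <- c(seen, canon)
    smis <- c(smis, s)
  }
  ids <- sprintf("syn%02d", seq_along(smis))
  mols <- mapply(.parseSmiles, smis, ids, SIMPLIFY = FALSE)
  stats::setNames(mols, ids)
}

#' Generate activities linear in a descriptor subset
#'
#' \code{y = sum_j c_j z_j + eps} where \code{z_j} are the autoscaled true
#' descriptors and \code{eps ~ N(0, noiseSd)}; with \code{noiseSd = NA}
#' the noise is scaled to a 9:1 signal-to-noise variance ratio. Noise
#' draws use \code{seed + 1} so molecule generation and activity noise are
#' independent streams.
#'
#' @param mols molecule list from \code{\link{generateMolecules}}.
#' @param spec the \linkS4class{SyntheticSpec}.
#' @return named numeric activity (pLC50-like) vector.
#' @export
generateActivity <- function(mols, spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  desc <- etaDescriptors(mols)
  miss <- setdiff(spec@trueSubset, colnames(desc))
  if (length(miss))
    stop("trueSubset not computable: ", paste(miss, collapse = ", "))
  Z <- scale(desc[, spec@trueSubset, drop = FALSE])
  if (any(!is.finite(Z)))
    stop("a true-subset descriptor is constant over the generated set")
  signal <- as.numeric(Z %*% spec@trueCoefficients)
  sdNoise <- if (is.finite(spec@noiseSd)) spec@noiseSd else
    stats::sd(signal) / 3
  rng <- .seededRng(spec@seed + 1L)
  y <- signal + rng$rnorm(length(signal), sd = sdNoise)
  stats::setNames(y, names(mols))
}

#' Build a planted-subset recovery-study dataset
#'
#' Constructs the dataset for a descriptor-selection recovery experiment:
#' a generated molecule panel with activity linear in the planted subset,
#' and a descriptor pool of fixed size holding the planted columns plus
#' distractors. Distractors are the pretreated ETA columns, screened so
#' that no planted column can be linearly recovered from them (multiple
#' R-squared at most \code{identifiabilityR2}) -- without this screen the
#' functional collinearity of the ETA block makes "which subset carries
#' the signal" statistically ill-posed -- and the pool is padded to
#' \code{poolSize} with seeded standard-normal decoy columns.
#'
#' @param seed integer seed driving generation, noise and decoys.
#' @param nCompounds panel size (default 60).
#' @param poolSize total descriptor-pool size (default 30).
#' @param identifiabilityR2 redundancy bound for distractors (default 0.8).
#' @return list with \code{table} (a \linkS4class{DescriptorTable} whose
#'   response carries the planted signal) and \code{trueSubset}.
#' @export
recoveryStudyPool <- function(seed, nCompounds = 60, poolSize = 30,
                              identifiabilityR2 = 0.8) {
  spec <- syntheticSpec(nCompounds = nCompounds, seed = seed)
  mols <- generateMolecules(spec)
  y <- generateActivity(mols, spec)
  desc <- etaDescriptors(mols)
  X <- descriptorValues(pretreat(descriptorTable(desc, y))$table)
  Xt <- desc[, spec@trueSubset, drop = FALSE]
  others <- setdiff(colnames(X), spec@trueSubset)
  repeat {
    r2max <- -Inf; jworst <- 1L
    for (j in seq_len(ncol(Xt))) {
      f <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), Xt[, j])
      r2 <- 1 - sum(f$residuals^2) / sum((Xt[, j] - mean(Xt[, j]))^2)
      if (r2 > r2max) { r2max <- r2; jworst <- j }
    }
    if (r2max <= identifiabilityR2 || !length(others)) break
    rr <- abs(stats::cor(X[, others, drop = FALSE], Xt[, jworst]))
    others <- others[-which.max(rr)]
  }
  pool <- cbind(Xt, X[, others, drop = FALSE])
  if (ncol(pool) < poolSize) {
    rng <- .seededRng(seed + 1000L)
    D <- matrix(rng$rnorm(nrow(pool) * (poolSize - ncol(pool))), nrow(pool))
    colnames(D) <- sprintf("decoy%02d", seq_len(ncol(D)))
    pool <- cbind(pool, D)
  } else {
    pool <- pool[, seq_len(poolSize), drop = FALSE]
  }
  rownames(pool) <- names(y)
  list(table = descriptorTable(pool, y), trueSubset = spec@trueSubset)
}

#' Curated named-compound set
#'
#' Monoterpene and phenylpropanoid larvicide-panel compounds referenced
#' by name throughout the package's tests, with their serial numbers in
#' the source panel and SMILES curated from the systematic names. The two
#' limonene entries are enantiomers and therefore share one molecular
#' graph: 2D topological descriptors are stereo-blind.
#'
#' @param asMolecules parse into \linkS4class{Molecule} objects (default
#'   FALSE returns the table).
#' @return data.frame with columns \code{id}, \code{name}, \code{smiles},
#'   or a named molecule list.
#' @export
fixtureCompounds <- function(asMolecules = FALSE) {
  tab <- data.frame(
    id = c("1", "3", "4", "8", "10", "14", "15", "23", "26", "35",
           "44", "49", "50", "54", "59"),
    name = c("(-)-camphene", "1,4-cineole", "1,8-cineole",
             "carvacryl trichloroacetate", "carvacryl benzoate",
             "thymyl chloroacetate", "thymyl trichloroacetate",
             "5-norbornene-2-endo-3-endo-dimethanol",
             "2-[2-methoxy-4-(2-propen-1-yl)phenoxy]acetic acid",
             "4-hydroxy-3-methoxy-benzenepropanol", "1,2-carvone oxide",
             "resorcinol", "R-limonene", "S-limonene", "3-carene"),
    smiles = c("CC1(C)C2CCC(C2)C1=C",
               "CC(C)C12CCC(C)(CC1)O2",
               "CC1(C)C2CCC(C)(CC2)O1",
               "Cc1ccc(cc1OC(=O)C(Cl)(Cl)Cl)C(C)C",
               "Cc1ccc(cc1OC(=O)c2ccccc2)C(C)C",
               "Cc1ccc(C(C)C)c(OC(=O)CCl)c1",
               "Cc1ccc(C(C)C)c(OC(=O)C(Cl)(Cl)Cl)c1",
               "OCC1C(CO)C2CC1C=C2",
               "COc1cc(CC=C)ccc1OCC(=O)O",
               "OCCCc1ccc(O)c(OC)c1",
               "CC(=C)C1CC2(C)OC2C(=O)C1",
               "Oc1cccc(O)c1",
               "CC(=C)C1CCC(C)=CC1",
               "CC(=C)C1CCC(C)=CC1",
               "CC1=CCC2C(C1)C2(C)C"),
    stringsAsFactors = FALSE)
  if (!asMolecules) return(tab)
  mols <- mapply(.parseSmiles, tab$smiles, tab$id,
                 MoreArgs = list(), SIMPLIFY = FALSE)
  for (i in seq_along(mols)) mols[[i]]@name <- tab$name[i]
  stats::setNames(mols, tab$id)
}
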