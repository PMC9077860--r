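# Extended Topochemical Atom (ETA) descriptors.
#
# Atomic quantities: for a heavy atom of period PN >= 2,
#   alpha = [(Z - Zv)/Zv] * 1/(PN - 1),  alpha(H) = 0
#   epsilon = -alpha + 0.3 * Zv
# The valence-electron-mobile (VEM) count beta of a vertex bookkeeps sigma,
# pi and lone-pair electron contributions of its bonds in the
# hydrogen-suppressed graph; the composite block is assembled from these,
# from the reference alkane (heteroatoms -> C, all bonds single) and from
# the saturated carbon skeleton (C-C multiple bonds demoted to single).

#' VEM contribution rules of the ETA scheme
#'
#' All bond-contribution constants live in this one table so the scheme is
#' inspectable and overridable: sigma contributions for bonded atoms of
#' similar/dissimilar electronegativity, pi contributions per pi bond,
#' the flat aromatic-ring contribution, the lone-pair conjugation increment
#' and the |delta epsilon| threshold that separates "similar" from
#' "dissimilar".
#'
#' @return named list of numeric constants.
#' @export
etaRules <- function() {
  list(sigmaSimilar = 0.5, sigmaDissimilar = 0.75,
       piSimilar = 1.0, piDissimilar = 1.5,
       aromatic = 2.0, lonePair = 0.5,
       epsilonThreshold = 0.3)
}

.symToInfo <- function(x) {
  if (is.character(x)) .elementRow(x)
  else x  # already an atom-table row
}

#' Atomic core-count term alpha
#'
#' @param element element symbol(s), e.g. \code{"C"}.
#' @return alpha value(s); 0 for hydrogen.
#' @export
atomicAlpha <- function(element) {
  info <- .symToInfo(element)
  out <- numeric(nrow(info))
  isH <- info$element == "H"
  if (any(!isH & info$PN == 1L))
    stop("alpha undefined for period-1 heavy atoms")
  out[!isH] <- ((info$Z[!isH] - info$Zv[!isH]) / info$Zv[!isH]) /
    (info$PN[!isH] - 1)
  out
}

#' Atomic electronegativity measure epsilon
#'
#' \code{epsilon = -alpha + 0.3 * Zv}; 0.3 for hydrogen.
#'
#' @param element element symbol(s).
#' @return epsilon value(s).
#' @export
atomicEpsilon <- function(element) {
  info <- .symToInfo(element)
  -atomicAlpha(element) + 0.3 * info$Zv
}

#' Sigma-bond VEM contribution of a bonded atom pair
#'
#' Two bonded atoms of similar electronegativity (|epsilon difference| at or
#' below the threshold) contribute 0.5 each to the other's sigma count;
#' dissimilar pairs contribute 0.75.
#'
#' @param a,b element symbols of the two bonded heavy atoms.
#' @param rules contribution constants, see \code{\link{etaRules}}.
#' @return the per-bond sigma contribution (0.5 or 0.75 by default).
#' @export
sigmaContribution <- function(a, b, rules = etaRules()) {
  de <- abs(atomicEpsilon(a) - atomicEpsilon(b))
  ifelse(de <= rules$epsilonThreshold, rules$sigmaSimilar,
         rules$sigmaDissimilar)
}

# per-heavy-atom beta components on the hydrogen-suppressed graph
.betaComponents <- function(mol, rules = etaRules()) {
  hs <- heavySkeleton(mol)
  n <- nrow(hs@atoms)
  eps <- atomicEpsilon(hs@atoms$element)
  betaS <- numeric(n); betaNs <- numeric(n)
  b <- hs@bonds
  aromAtom <- logical(n)
  if (nrow(b)) {
    aromAtom[c(b$from[b$aromatic], b$to[b$aromatic])] <- TRUE
    for (k in seq_len(nrow(b))) {
      i <- b$from[k]; j <- b$to[k]
      similar <- abs(eps[i] - eps[j]) <= rules$epsilonThreshold
      x <- if (similar) rules$sigmaSimilar else rules$sigmaDissimilar
      betaS[i] <- betaS[i] + x
      betaS[j] <- betaS[j] + x
      if (!b$aromatic[k] && b$order[k] > 1L) {
        y <- (b$order[k] - 1L) *
          if (similar) rules$piSimilar else rules$piDissimilar
        betaNs[i] <- betaNs[i] + y
        betaNs[j] <- betaNs[j] + y
      }
    }
  }
  betaNs[aromAtom] <- betaNs[aromAtom] + rules$aromatic
  # lone-pair atoms conjugated to a pi system: +0.5 once
  val <- .ELEMENTS$valence[match(hs@atoms$element, .ELEMENTS$element)]
  hasLp <- hs@atoms$Zv - val >= 2L
  inPi <- logical(n)
  if (nrow(b)) {
    multi <- b$order > 1L | b$aromatic
    inPi[c(b$from[multi], b$to[multi])] <- TRUE
  }
  if (any(hasLp) && nrow(b)) {
    for (i in which(hasLp)) {
      nb <- c(b$to[b$from == i & b$order == 1L & !b$aromatic],
              b$from[b$to == i & b$order == 1L & !b$aromatic])
      if (any(inPi[nb])) betaNs[i] <- betaNs[i] + rules$lonePair
    }
  }
  data.frame(element = hs@atoms$element, alpha = atomicAlpha(hs@atoms$element),
             epsilon = eps, betaS = betaS, betaNs = betaNs,
             beta = betaS + betaNs)
}

#' Atomic VEM counts of one heavy atom
#'
#' @param mol a \linkS4class{Molecule}.
#' @param atom index of the atom in the hydrogen-suppressed graph.
#' @param rules contribution constants, see \code{\link{etaRules}}.
#' @return list with \code{alpha}, \code{epsilon}, \code{betaS},
#'   \code{betaNs}, \code{beta} and \code{gamma} (= alpha/beta, NA when
#'   beta is 0).
#' @export
atomBeta <- function(mol, atom, rules = etaRules()) {
  bc <- .betaComponents(mol, rules)
  if (atom < 1L || atom > nrow(bc)) stop("atom index out of range")
  r <- bc[atom, ]
  list(alpha = r$alpha, epsilon = r$epsilon, betaS = r$betaS,
       betaNs = r$betaNs, beta = r$beta,
       gamma = if (r$beta > 0) r$alpha / r$beta else NA_real_)
}

#' Reference alkane of a molecule
#'
#' Every heteroatom of the heavy skeleton is replaced by carbon and every
#' bond made single; hydrogens are re-added to fill carbon valences.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return the reference-alkane \linkS4class{Molecule}.
#' @export
referenceAlkane <- function(mol) {
  hs <- heavySkeleton(mol)
  b <- hs@bonds
  b$order <- rep(1L, nrow(b)); b$aromatic <- rep(FALSE, nrow(b))
  out <- moleculeFromGraph(paste0(mol@id, "_refalkane"),
                           rep("C", nrow(hs@atoms)), b)
  addExplicitHydrogens(out)
}

#' Saturated carbon skeleton of a molecule
#'
#' Carbon-carbon multiple bonds (including aromatic ones) are demoted to
#' single bonds; heteroatoms and their bond orders are retained. Hydrogens
#' are re-added to fill the freed valences.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return the saturated-skeleton \linkS4class{Molecule}.
#' @export
saturatedSkeleton <- function(mol) {
  hs <- heavySkeleton(mol)
  b <- hs@bonds
  cc <- hs@atoms$element[b$from] == "C" & hs@atoms$element[b$to] == "C"
  b$order[cc] <- 1L
  b$aromatic <- rep(FALSE, nrow(b))
  out <- moleculeFromGraph(paste0(mol@id, "_satskel"),
                           hs@atoms$element, b)
  out <- addExplicitHydrogens(out)
  .flagAromaticRings(out)
}

#' Mean-epsilon variants of a molecule
#'
#' \itemize{
#'   \item eps1: mean epsilon over heavy atoms of the molecule;
#'   \item eps2: mean epsilon over all atoms including hydrogens;
#'   \item eps3: mean epsilon over all atoms (incl. H) of the reference
#'     alkane;
#'   \item eps4: mean epsilon over all atoms (incl. H) of the saturated
#'     carbon skeleton;
#'   \item eps5: mean epsilon over all atoms after deleting hydrogens
#'     bonded to N, O or S (the hydrogen-bond donors).
#' }
#'
#' @param mol a hydrogen-explicit \linkS4class{Molecule}.
#' @return named numeric vector \code{eps1..eps5}.
#' @export
epsilonVariants <- function(mol) {
  mol <- addExplicitHydrogens(mol)
  a <- mol@atoms
  eps <- atomicEpsilon(a$element)
  heavy <- !a$isH
  e1 <- sum(eps[heavy]) / sum(heavy)
  e2 <- sum(eps) / length(eps)
  ra <- referenceAlkane(mol)
  e3 <- sum(atomicEpsilon(ra@atoms$element)) / nrow(ra@atoms)
  ss <- saturatedSkeleton(mol)
  e4 <- sum(atomicEpsilon(ss@atoms$element)) / nrow(ss@atoms)
  donorH <- .donorHydrogens(mol)
  e5 <- sum(eps[!donorH]) / sum(!donorH)
  c(eps1 = e1, eps2 = e2, eps3 = e3, eps4 = e4, eps5 = e5)
}

# logical mask of hydrogens bonded to N, O or S
.donorHydrogens <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  out <- logical(nrow(a))
  if (!nrow(b)) return(out)
  hIdx <- which(a$isH)
  for (i in hIdx) {
    nb <- c(b$to[b$from == i], b$from[b$to == i])
    if (any(a$element[nb] %in% c("N", "O", "S"))) out[i] <- TRUE
  }
  out
}

# eta index over a heavy skeleton given per-atom gamma and the distance
# matrix; pairs at infinite/zero distance excluded
.etaIndex <- function(gamma, D, maxDist = Inf) {
  n <- length(gamma)
  if (n < 2L || any(!is.finite(gamma))) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- D[i, j]
    if (is.finite(d) && d >= 1 && d <= maxDist)
      tot <- tot + sqrt(gamma[i] * gamma[j] / d^2)
  }
  tot
}

#' Composite ETA descriptor block of a molecule
#'
#' Computes the full descriptor set, including the five modelling
#' descriptors \code{ETA_dEpsilon_D} (= eps5 - eps2, hydrogen-bond donor
#' measure), \code{ETA_EtaP_F} (functionality index relative to molecular
#' size), \code{ETA_dAlpha_B} (= max(0, 0.5 - mean alpha), polar-surface
#' measure), \code{ETA_BetaP_s} (= sum of sigma VEM counts / Nv) and
#' \code{ETA_dEpsilon_C} (= eps3 - eps4, electronegativity measure).
#'
#' @param mol a \linkS4class{Molecule} with a connected heavy skeleton.
#' @param rules contribution constants, see \code{\link{etaRules}}.
#' @return named numeric vector; see \code{\link{etaDescriptorNames}} for
#'   the column convention and which members are conformance-validated.
#' @export
etaComposite <- function(mol, rules = etaRules()) {
  if (!.isConnected(mol))
    stop("molecule '", mol@id, "': heavy skeleton is disconnected")
  mol <- addExplicitHydrogens(mol)
  hs <- heavySkeleton(mol)
  nv <- nrow(hs@atoms)
  nAll <- nrow(mol@atoms)
  bc <- .betaComponents(mol, rules)
  ev <- epsilonVariants(mol)
  ra <- referenceAlkane(mol)
  ss <- saturatedSkeleton(mol)
  nR <- nrow(ra@atoms); nSs <- nrow(ss@atoms)

  alphaSum <- sum(bc$alpha)
  alphaP <- alphaSum / nv
  betaSsum <- sum(bc$betaS); betaNsSum <- sum(bc$betaNs)
  betaSum <- betaSsum + betaNsSum

  g <- .heavyGraph(mol)
  D <- igraph::distances(g)
  gamma <- ifelse(bc$beta > 0, bc$alpha / bc$beta, NA_real_)
  eta <- if (nv >= 2L) .etaIndex(gamma, D) else 0
  etaL <- if (nv >= 2L) .etaIndex(gamma, D, maxDist = 1) else 0
  bcR <- .betaComponents(ra, rules)
  gammaR <- ifelse(bcR$beta > 0, bcR$alpha / bcR$beta, NA_real_)
  etaR <- if (nv >= 2L) .etaIndex(gammaR, igraph::distances(.heavyGraph(ra))) else 0
  etaF <- etaR - eta

  deg <- igraph::degree(g)
  shapeDenom <- if (alphaSum > 0) alphaSum else 1
  psi1 <- alphaP / ev[["eps1"]]
  psiRef <- atomicAlpha("C") / atomicEpsilon("C")  # infinite-alkane value

  c(Nv = nv, N = nAll, NR = nR, Nss = nSs,
    ETA_Alpha = alphaSum, ETA_AlphaP = alphaP,
    ETA_dAlpha_A = max(0, alphaP - 0.5),
    ETA_dAlpha_B = max(0, 0.5 - alphaP),
    ETA_Epsilon_1 = ev[["eps1"]], ETA_Epsilon_2 = ev[["eps2"]],
    ETA_Epsilon_3 = ev[["eps3"]], ETA_Epsilon_4 = ev[["eps4"]],
    ETA_Epsilon_5 = ev[["eps5"]],
    ETA_dEpsilon_A = ev[["eps1"]] - ev[["eps3"]],
    ETA_dEpsilon_B = ev[["eps1"]] - ev[["eps4"]],
    ETA_dEpsilon_C = ev[["eps3"]] - ev[["eps4"]],
    ETA_dEpsilon_D = ev[["eps5"]] - ev[["eps2"]],
    ETA_Beta_s = betaSsum, ETA_BetaP_s = betaSsum / nv,
    ETA_Beta_ns = betaNsSum, ETA_BetaP_ns = betaNsSum / nv,
    ETA_Beta = betaSum, ETA_BetaP = betaSum / nv,
    ETA_Eta = eta, ETA_EtaP = eta / nv,
    ETA_Eta_R = etaR, ETA_Eta_F = etaF, ETA_EtaP_F = etaF / nv,
    ETA_Eta_L = etaL, ETA_EtaP_L = etaL / nv,
    ETA_Shape_P = sum(bc$alpha[deg == 1]) / shapeDenom,
    ETA_Shape_Y = sum(bc$alpha[deg == 3]) / shapeDenom,
    ETA_Shape_X = sum(bc$alpha[deg == 4]) / shapeDenom,
    ETA_Psi_1 = psi1,
    ETA_dPsi_A = max(0, psiRef - psi1),
    ETA_dPsi_B = max(0, psi1 - psiRef))
}

#' Descriptor-name convention and validation status
#'
#' @return data.frame with columns \code{name} and \code{validated}
#'   (TRUE for the members whose construction is pinned by the published
#'   formulas; FALSE for best-effort members of the block).
#' @export
etaDescriptorNames <- function() {
  nm <- names(etaComposite(.parseSmiles("CC", "probe")))
  core <- c("Nv", "N", "NR", "Nss", "ETA_Alpha", "ETA_AlphaP",
            "ETA_dAlpha_A", "ETA_dAlpha_B",
            paste0("ETA_Epsilon_", 1:5),
            "ETA_dEpsilon_A", "ETA_dEpsilon_B", "ETA_dEpsilon_C",
            "ETA_dEpsilon_D", "ETA_Beta_s", "ETA_BetaP_s",
            "ETA_Beta_ns", "ETA_BetaP_ns", "ETA_Beta", "ETA_BetaP",
            "ETA_Eta", "ETA_EtaP", "ETA_Eta_R", "ETA_Eta_F", "ETA_EtaP_F")
  data.frame(name = nm, validated = nm %in% core)
}

#' ETA descriptor matrix for a molecule set
#'
#' @param mols list of \linkS4class{Molecule} (as returned by
#'   \code{\link{readSmiles}}).
#' @param rules contribution constants, see \code{\link{etaRules}}.
#' @return numeric matrix, one row per molecule (rownames = ids).
#' @export
etaDescriptors <- function(mols, rules = etaRules()) {
  rows <- lapply(mols, etaComposite, rules = rules)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(mols, molId, character(1))
  m
}

#' Join descriptors with a response into a DescriptorTable
#'
#' @param descriptors numeric matrix with compound rownames.
#' @param activity named numeric pLC50 vector; ids must cover the rows.
#' @return a \linkS4class{DescriptorTable}.
#' @export
descriptorTable <- function(descriptors, activity = NULL) {
  ids <- rownames(descriptors)
  if (is.null(ids)) stop("descriptor matrix must have compound rownames")
  resp <- rep(NA_real_, length(ids))
  if (!is.null(activity)) {
    miss <- setdiff(ids, names(activity))
    if (length(miss))
      stop("no activity for compound(s): ", paste(miss, collapse = ", "))
    resp <- as.numeric(activity[ids])
  }
  vals <- as.matrix(descriptors)
  rownames(vals) <- NULL
  new("DescriptorTable", ids = ids, values = vals, response = resp)
}
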