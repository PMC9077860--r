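# Parsing of SMILES / SDF V2000 into hydrogen-explicit, Kekulized Molecule
# graphs. Heavy parsing work is delegated to OpenBabel via
# ChemmineR/ChemmineOB; hydrogen completion and aromatic-ring flagging run
# on the resulting graph so that they are deterministic.

# Element data for the organic subset the ETA formulas cover.
.ELEMENTS <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  Z  = c(1L, 6L, 7L, 8L, 9L, 15L, 16L, 17L, 35L, 53L),
  Zv = c(1L, 4L, 5L, 6L, 7L, 5L, 6L, 7L, 7L, 7L),
  PN = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
  valence = c(1L, 4L, 3L, 2L, 1L, 3L, 2L, 1L, 1L, 1L),
  stringsAsFactors = FALSE)

.elementRow <- function(sym) {
  i <- match(sym, .ELEMENTS$element)
  if (anyNA(i))
    stop("unsupported element(s): ",
         paste(unique(sym[is.na(i)]), collapse = ", "))
  .ELEMENTS[i, , drop = FALSE]
}

#' Build a Molecule from element symbols and a bond list
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Hydrogens may be included explicitly or added afterwards with
#' \code{\link{addExplicitHydrogens}}.
#'
#' @param id compound identifier.
#' @param elements character vector of element symbols.
#' @param bonds data.frame with columns \code{from}, \code{to},
#'   \code{order}; an optional logical \code{aromatic} column is kept.
#' @param name optional compound name.
#' @return a \linkS4class{Molecule}.
#' @export
moleculeFromGraph <- function(id, elements, bonds, name = character()) {
  info <- .elementRow(elements)
  atoms <- data.frame(element = elements, Z = info$Z, Zv = info$Zv,
                      PN = info$PN, isH = elements == "H",
                      charge = 0L, stringsAsFactors = FALSE)
  if (nrow(bonds) == 0L)
    bonds <- data.frame(from = integer(), to = integer(),
                        order = integer(), aromatic = logical())
  if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
  bonds <- data.frame(from = as.integer(bonds$from),
                      to = as.integer(bonds$to),
                      order = as.integer(bonds$order),
                      aromatic = as.logical(bonds$aromatic))
  new("Molecule", id = as.character(id), name = as.character(name),
      atoms = atoms, bonds = bonds)
}

# implicit hydrogen count per heavy atom from standard valences
.implicitH <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  bsum <- numeric(nrow(a))
  if (nrow(b)) {
    ordsum <- tapply(c(b$order, b$order), c(b$from, b$to), sum)
    bsum[as.integer(names(ordsum))] <- ordsum
  }
  val <- .ELEMENTS$valence[match(a$element, .ELEMENTS$element)]
  h <- pmax(0L, as.integer(val - bsum))
  h[a$isH] <- 0L
  h
}

#' Add explicit hydrogens to fill standard valences
#'
#' Each heavy atom receives \code{valence - sum(bond orders)} hydrogens
#' (neutral organic valences: C 4, N 3, O 2, S 2, P 3, halogens 1). Atoms
#' already saturated are untouched, so the operation is idempotent.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return the hydrogen-explicit \linkS4class{Molecule}.
#' @export
addExplicitHydrogens <- function(mol) {
  h <- .implicitH(mol)
  tot <- sum(h)
  if (tot == 0L) return(mol)
  heavyIdx <- rep(seq_len(nrow(mol@atoms)), h)
  hinfo <- .elementRow(rep("H", tot))
  newAtoms <- data.frame(element = "H", Z = hinfo$Z, Zv = hinfo$Zv,
                         PN = hinfo$PN, isH = TRUE, charge = 0L,
                         stringsAsFactors = FALSE)
  newBonds <- data.frame(from = heavyIdx,
                         to = nrow(mol@atoms) + seq_len(tot),
                         order = 1L, aromatic = FALSE)
  mol@atoms <- rbind(mol@atoms, newAtoms)
  mol@bonds <- rbind(mol@bonds, newBonds)
  validObject(mol)
  mol
}

#' Hydrogen-suppressed view of a molecule
#'
#' @param mol a \linkS4class{Molecule}.
#' @return the \linkS4class{Molecule} restricted to heavy atoms.
#' @export
heavySkeleton <- function(mol) {
  keep <- which(!mol@atoms$isH)
  remap <- match(seq_len(nrow(mol@atoms)), keep)
  b <- mol@bonds
  b <- b[!is.na(remap[b$from]) & !is.na(remap[b$to]), , drop = FALSE]
  b$from <- remap[b$from]; b$to <- remap[b$to]
  mol@atoms <- mol@atoms[keep, , drop = FALSE]
  rownames(mol@atoms) <- NULL
  rownames(b) <- NULL
  mol@bonds <- b
  mol
}

# igraph over heavy atoms (used for distances, rings, connectivity)
.heavyGraph <- function(mol) {
  hs <- heavySkeleton(mol)
  igraph::graph_from_data_frame(
    d = if (nrow(hs@bonds)) hs@bonds[, c("from", "to")] else
      data.frame(from = integer(), to = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(hs@atoms))))
}

.isConnected <- function(mol) {
  g <- .heavyGraph(mol)
  igraph::vcount(g) <= 1L || igraph::is_connected(g)
}

# Flag bonds of benzenoid rings: even cycles (length 5-7 searched, 6 in
# practice) of C/N atoms whose Kekule orders alternate 1/2 around the ring.
.flagAromaticRings <- function(mol) {
  hs <- heavySkeleton(mol)
  nb <- nrow(hs@bonds)
  if (nb < 6L) return(mol)
  n <- nrow(hs@atoms)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[hs@bonds$from[k]]] <- c(adj[[hs@bonds$from[k]]], k)
    adj[[hs@bonds$to[k]]]   <- c(adj[[hs@bonds$to[k]]], k)
  }
  other <- function(k, v) if (hs@bonds$from[k] == v) hs@bonds$to[k] else hs@bonds$from[k]
  okAtom <- hs@atoms$element %in% c("C", "N")
  aromBond <- logical(nb)
  # DFS rooted at the smallest-index vertex of each candidate ring
  walk <- function(start, v, path, bpath, depth) {
    for (k in adj[[v]]) {
      w <- other(k, v)
      if (w == start && depth == 6L) {
        ords <- hs@bonds$order[c(bpath, k)]
        if (all(ords %in% 1:2) && all(abs(diff(ords)) == 1L) &&
            ords[1] != ords[length(ords)])
          aromBond[c(bpath, k)] <<- TRUE
      } else if (depth < 6L && w > start && !(w %in% path) && okAtom[w]) {
        walk(start, w, c(path, w), c(bpath, k), depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) if (okAtom[s]) walk(s, s, s, integer(), 1L)
  # map flags back onto the hydrogen-explicit bond table
  heavyMap <- which(!mol@atoms$isH)
  bm <- mol@bonds
  isHeavyBond <- !mol@atoms$isH[bm$from] & !mol@atoms$isH[bm$to]
  key <- function(f, t) paste(pmin(f, t), pmax(f, t))
  hk <- key(heavyMap[hs@bonds$from], heavyMap[hs@bonds$to])
  mk <- key(bm$from, bm$to)
  hit <- match(mk, hk)
  bm$aromatic <- ifelse(!is.na(hit) & isHeavyBond, aromBond[hit], FALSE)
  mol@bonds <- bm
  mol
}

# one ChemmineR SDF record -> Molecule
.sdfToMolecule <- function(sdf, id, name = character()) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0L)
    data.frame(from = integer(), to = integer(), order = integer())
  else data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  if (any(bonds$order == 4L))
    stop("aromatic (order 4) bonds present; input must be Kekulized")
  mol <- moleculeFromGraph(id, elements, bonds, name = name)
  mol <- addExplicitHydrogens(mol)
  .flagAromaticRings(mol)
}

# SMILES string -> Molecule (OpenBabel parse + Kekulize)
.parseSmiles <- function(smiles, id, name = character()) {
  # bond-less single-atom records do not survive the SDF round trip
  m1 <- regmatches(smiles, regexec("^\\[?([A-Z][a-z]?)H?[0-9]*\\]?$", smiles))[[1]]
  if (length(m1) == 2L && m1[2] %in% .ELEMENTS$element) {
    mol <- moleculeFromGraph(id, m1[2],
                             data.frame(from = integer(), to = integer(),
                                        order = integer()), name = name)
    return(addExplicitHydrogens(mol))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) stop("unparsable SMILES for '", id, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(sdf) < 1L || nrow(ChemmineR::atomblock(sdf[[1]])) == 0L)
    stop("unparsable SMILES for '", id, "'", call. = FALSE)
  .sdfToMolecule(sdf[[1]], id, name)
}

#' Read a SMILES file into Molecule graphs
#'
#' Each non-empty line must hold \code{SMILES<whitespace>ID}. Aromatic rings
#' are Kekulized and hydrogens made explicit; input order is preserved.
#'
#' @param path path to the .smi file.
#' @param hasHeader skip the first line if TRUE.
#' @return list of \linkS4class{Molecule}, named by id.
#' @export
readSmiles <- function(path, hasHeader = FALSE) {
  lines <- readLines(path, warn = FALSE)
  off <- 0L
  if (hasHeader && length(lines)) { lines <- lines[-1]; off <- 1L }
  keep <- which(nzchar(trimws(lines)))
  mols <- vector("list", length(keep))
  ids <- character(length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) < 2L)
      stop("line ", ln + off, ": expected 'SMILES ID'")
    ids[j] <- parts[2]
    mols[[j]] <- tryCatch(.parseSmiles(parts[1], parts[2]),
      error = function(e) stop("line ", ln + off, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(mols, ids)
}

#' Read an SDF (V2000) file into Molecule graphs
#'
#' Records with aromatic (order 4) bonds are Kekulized through OpenBabel;
#' explicit hydrogens are added where the connection table leaves valences
#' unfilled.
#'
#' @param path path to the SDF file.
#' @return list of \linkS4class{Molecule}, named by id (the SDF molecule
#'   name line, falling back to \code{mol<k>}).
#' @export
readSdf <- function(path) {
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
    error = function(e) stop("malformed SDF: ", conditionMessage(e),
                             call. = FALSE))
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok))
    stop("malformed SDF record(s) at index: ",
         paste(which(!ok), collapse = ", "))
  n <- length(sdfset)
  mols <- vector("list", n)
  ids <- character(n)
  for (k in seq_len(n)) {
    sdf <- sdfset[[k]]
    id <- ChemmineR::sdfid(sdfset[k])
    if (!length(id) || !nzchar(id)) id <- paste0("mol", k)
    ids[k] <- id
    bb <- ChemmineR::bondblock(sdf)
    if (!is.null(bb) && nrow(bb) && any(bb[, 3] == 4L)) {
      # re-Kekulize the record through OpenBabel
      txt <- paste(unlist(ChemmineR::sdf2str(sdf)), collapse = "\n")
      kek <- ChemmineOB::convertFormat("SDF", "SDF", source = txt)
      tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(tmp), add = TRUE)
      writeLines(kek, tmp)
      sdf <- ChemmineR::read.SDFset(tmp)[[1]]
    }
    mols[[k]] <- .sdfToMolecule(sdf, id)
  }
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(mols, ids)
}

#' Write Molecule graphs to an SDF V2000 file
#'
#' Emits the stored graph (including explicit hydrogens) with zeroed
#' coordinates; atom indices are 1-based as the format requires.
#'
#' @param mols list of \linkS4class{Molecule}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSdf <- function(mols, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (mol in mols) {
    a <- mol@atoms; b <- mol@bonds
    writeLines(c(mol@id, "  etaqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    for (i in seq_len(nrow(a)))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, a$element[i]), con)
    for (k in seq_len(nrow(b)))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         b$from[k], b$to[k], b$order[k]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read an activity table and convert to pLC50
#'
#' Expects a CSV with header \code{id,value}. LC50 values (strictly
#' positive, in the source's concentration units) are converted as
#' \code{pLC50 = -log10(LC50)}; pLC50 values pass through unchanged.
#'
#' @param path path to the CSV file.
#' @param valueKind either \code{"LC50"} or \code{"pLC50"}.
#' @return named numeric vector of pLC50, named by compound id.
#' @export
readActivity <- function(path, valueKind = c("pLC50", "LC50")) {
  valueKind <- match.arg(valueKind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "value") %in% names(df)))
    stop("activity CSV must have columns 'id' and 'value'")
  if (anyDuplicated(df$id))
    stop("duplicate ids in activity table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  v <- as.numeric(df$value)
  if (valueKind == "LC50") {
    if (any(!is.finite(v) | v <= 0))
      stop("LC50 values must be strictly positive")
    v <- -log10(v)
  }
  stats::setNames(v, df$id)
}
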