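# Heavy-atom van der Waals radii (Angstrom), Bondi-style values with a
# conservative default for elements outside the table. Deposited
# ribosome models lack hydrogens, so a united-heavy-atom treatment is
# used throughout.
.vdwRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.defaultRadius <- 1.70

.waterResids <- c("HOH", "WAT", "DOD", "H2O")
.ionResids <- c("MG", "K", "NA", "CL", "ZN", "CA", "MN", "FE", "NI",
                "CU", "CD", "CO", "SR", "CS", "BA", "IOD", "BR", "SO4",
                "PO4", "NO3", "ACT", "GOL", "EDO", "PEG")

.atomRadii <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdwRadii[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            ": using default radius ", .defaultRadius, " A")
    r[unknown] <- .defaultRadius
  }
  unname(r)
}

#' Load heavy atoms from an mmCIF or PDB file
#'
#' Parses atomic coordinates (via bio3d) into a flat atom table grouped
#' by chain. Hydrogens, waters and common ions/buffer molecules are
#' excluded by default; alternate locations are resolved to the highest
#' occupancy (ties towards the alphabetically first altloc).
#'
#' @param path mmCIF (.cif) or PDB (.pdb/.ent) file.
#' @param removeWaters,removeIons drop solvent / ion and buffer
#'   heteroatoms (default TRUE).
#' @return data.frame with columns chain, resno, insert, resid, elety
#'   (atom name), element, x, y, z, occupancy.
#' @export
loadStructure <- function(path, removeWaters = TRUE, removeIons = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  obj <- tryCatch(suppressWarnings({
    if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE)
  }), error = function(e) stop("could not parse structure file ", path,
                               ": ", conditionMessage(e)))
  a <- obj$atom
  el <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                              substr(trimws(a$elety), 1, 1), a$elesy)))
  keep <- !(el %in% c("H", "D"))
  if (removeWaters) keep <- keep & !(a$resid %in% .waterResids)
  if (removeIons) keep <- keep & !(a$resid %in% .ionResids)
  a <- a[keep, , drop = FALSE]; el <- el[keep]
  occ <- ifelse(is.na(a$o), 1, a$o)
  atoms <- data.frame(chain = as.character(a$chain),
                      resno = as.integer(a$resno),
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      resid = as.character(a$resid),
                      elety = trimws(as.character(a$elety)),
                      element = el,
                      x = a$x, y = a$y, z = a$z,
                      occupancy = occ, stringsAsFactors = FALSE)
  alt <- ifelse(is.na(a$alt) | a$alt == "" | a$alt == ".", "",
                as.character(a$alt))
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
    orig <- seq_len(nrow(atoms))
    ord <- order(key, -atoms$occupancy, alt)
    atoms <- atoms[ord, , drop = FALSE]; orig <- orig[ord]
    keep <- !duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                              atoms$elety))
    atoms <- atoms[keep, , drop = FALSE]; orig <- orig[keep]
    atoms <- atoms[order(orig), , drop = FALSE]
  }
  if (!nrow(atoms)) stop("no heavy atoms retained from ", path)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  rownames(atoms) <- NULL
  atoms
}

#' Download a PDB entry (mmCIF) from RCSB
#'
#' Convenience fetcher for deposited coordinates; requires network
#' access. The file is cached in \code{destdir}.
#'
#' @param id 4-character PDB accession, e.g. "9HC4".
#' @param destdir cache directory.
#' @return path to the downloaded mmCIF file.
#' @export
fetchStructure <- function(id, destdir = tempdir()) {
  dest <- file.path(destdir, paste0(tolower(id), ".cif"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.cif", toupper(id))
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Finds the proper rotation and translation minimising the RMSD
#' between two paired coordinate sets, using the SVD-based Kabsch
#' algorithm with reflection correction.
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates (A is
#'   moved onto B).
#' @return list: \code{rotation} (3x3), \code{translation} (length 3;
#'   \code{coordsA \%*\% rotation + translation} superposes onto B),
#'   \code{rmsd} (Angstrom).
#' @export
superposeRmsd <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  stopifnot(ncol(A) == 3L, ncol(B) == 3L, nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 paired atoms for superposition")
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  s <- svd(crossprod(A0, B0))
  if (min(s$d) < 1e-10 && s$d[2] < 1e-10)
    stop("degenerate (collinear) coordinates: superposition ill-conditioned")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  list(rotation = R, translation = as.numeric(cB - cA %*% R), rmsd = rmsd)
}

#' Pair equivalent atoms of two chains by residue number
#'
#' Selects one named atom per residue (default the C-alpha) from each of
#' two chains and pairs them by residue number over the range modelled
#' in both, for use with [superposeRmsd()].
#'
#' @param atoms atom table from [loadStructure()].
#' @param chainA,chainB chain identifiers.
#' @param elety atom name to pair (default "CA").
#' @return list of two paired n x 3 coordinate matrices and the shared
#'   residue numbers.
#' @export
pairCommonResidues <- function(atoms, chainA, chainB, elety = "CA") {
  pick <- function(ch) {
    s <- atoms[atoms$chain == ch & atoms$elety == elety, , drop = FALSE]
    s[!duplicated(s$resno), , drop = FALSE]
  }
  a <- pick(chainA); b <- pick(chainB)
  shared <- intersect(a$resno, b$resno)
  if (length(shared) < 3L)
    stop("chains ", chainA, " and ", chainB,
         " share fewer than 3 residues with atom ", elety)
  a <- a[match(shared, a$resno), ]; b <- b[match(shared, b$resno), ]
  list(coordsA = as.matrix(a[, c("x", "y", "z")]),
       coordsB = as.matrix(b[, c("x", "y", "z")]),
       resno = shared)
}

# Deterministic golden-section spiral points on the unit sphere.
.spiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by the Shrake-Rupley point-counting method with a
#' deterministic golden-section spiral point set: each atom's sphere of
#' radius r + probe is sampled at \code{nPoints} points and the area is
#' the accessible fraction times the sphere area.
#'
#' @param atoms atom table (needs x, y, z, element) from
#'   [loadStructure()], or any data.frame with those columns.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param nPoints sphere sample points per atom (default 960).
#' @return numeric vector of per-atom areas, Angstrom^2.
#' @export
sasa <- function(atoms, probe = 1.4, nPoints = 960) {
  n <- nrow(atoms)
  r <- .atomRadii(atoms$element) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  S <- .spiralPoints(nPoints)
  area <- numeric(n)
  if (n == 0L) return(area)
  # neighbour lists: atoms whose expanded spheres can intersect
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    full <- 4 * pi * r[i]^2
    if (!length(nb)) { area[i] <- full; next }
    pts <- sweep(S * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dd <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dd >= r[j]^2
    }
    area[i] <- full * sum(acc) / nPoints
  }
  area
}

#' Buried interface area of a query chain against partner chains
#'
#' Solvent-accessible surface area lost upon complex formation:
#' \code{SASA(query alone) + SASA(partners alone) - SASA(complex)}.
#' The per-partner-chain split repeats the calculation with each
#' partner chain individually against the query.
#'
#' @param atoms atom table from [loadStructure()].
#' @param queryChain chain identifier of the query (e.g. a bS20 copy).
#' @param partnerChains character vector; default all other chains.
#' @param probe,nPoints passed to [sasa()].
#' @param splitByChain compute the per-partner decomposition (default
#'   TRUE; set FALSE to save time on large complexes).
#' @return an \linkS4class{InterfaceReport}.
#' @export
buriedArea <- function(atoms, queryChain, partnerChains = NULL,
                       probe = 1.4, nPoints = 960, splitByChain = TRUE) {
  if (!queryChain %in% atoms$chain)
    stop("query chain not present: ", queryChain)
  if (is.null(partnerChains))
    partnerChains <- setdiff(unique(atoms$chain), queryChain)
  q <- atoms[atoms$chain == queryChain, , drop = FALSE]
  p <- atoms[atoms$chain %in% partnerChains, , drop = FALSE]
  params <- list(probe = probe, nPoints = nPoints,
                 radii = "Bondi-style heavy-atom set",
                 defaultRadius = .defaultRadius)
  if (!nrow(p))
    return(new("InterfaceReport", queryChain = queryChain,
               buriedTotal = 0, buriedByChain = numeric(), parameters = params))
  aq <- sum(sasa(q, probe, nPoints))
  ap <- sum(sasa(p, probe, nPoints))
  ac <- sum(sasa(rbind(q, p), probe, nPoints))
  total <- max(0, aq + ap - ac)
  by <- numeric()
  if (splitByChain) {
    for (ch in partnerChains) {
      pc <- atoms[atoms$chain == ch, , drop = FALSE]
      apc <- sum(sasa(pc, probe, nPoints))
      acc <- sum(sasa(rbind(q, pc), probe, nPoints))
      by[ch] <- max(0, aq + apc - acc)
    }
  }
  new("InterfaceReport", queryChain = queryChain, buriedTotal = total,
      buriedByChain = by, parameters = params)
}

#' Contact residues of a query chain
#'
#' A query residue is a contact if any of its heavy atoms lies within
#' the cut-off of any heavy atom outside the query chain (optionally
#' restricted to given partner chains).
#'
#' @param atoms atom table from [loadStructure()].
#' @param queryChain chain identifier.
#' @param cutoff heavy-atom distance cut-off, Angstrom (default 4.0).
#' @param partnerChains optional restriction of the partner set.
#' @return data.frame of contacting query residues: resno, insert,
#'   resid, minDistance (A), nearestChain.
#' @export
contactResidues <- function(atoms, queryChain, cutoff = 4.0,
                            partnerChains = NULL) {
  stopifnot(cutoff > 0)
  q <- atoms[atoms$chain == queryChain, , drop = FALSE]
  p <- if (is.null(partnerChains))
         atoms[atoms$chain != queryChain, , drop = FALSE]
       else atoms[atoms$chain %in% setdiff(partnerChains, queryChain), ,
                  drop = FALSE]
  empty <- data.frame(resno = integer(), insert = character(),
                      resid = character(), minDistance = numeric(),
                      nearestChain = character())
  if (!nrow(q) || !nrow(p)) return(empty)
  P <- as.matrix(p[, c("x", "y", "z")])
  res <- split(seq_len(nrow(q)), paste(q$resno, q$insert, sep = "|"))
  out <- list()
  for (key in names(res)) {
    idx <- res[[key]]
    Q <- as.matrix(q[idx, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(Q^2), rowSums(P^2), "+") - 2 * Q %*% t(P)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin <= cutoff) {
      jmin <- which(d2 == min(d2), arr.ind = TRUE)[1, 2]
      out[[key]] <- data.frame(resno = q$resno[idx[1]],
                               insert = q$insert[idx[1]],
                               resid = q$resid[idx[1]],
                               minDistance = dmin,
                               nearestChain = p$chain[jmin])
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$resno, out$insert), , drop = FALSE]
}

#' Find pairs of protein chains with (near-)identical sequences
#'
#' Scans the C-alpha trace of every protein chain and scores chain
#' pairs by sequence identity over residues with shared numbering, to
#' locate a protein modelled at two sites of one complex (e.g. the two
#' bS20 copies of a ribosome) without assuming chain identifiers.
#'
#' @param atoms atom table from [loadStructure()].
#' @param minResidues,maxResidues size window for candidate chains.
#' @param minIdentity minimum fraction of identical residue names over
#'   the shared numbering (default 0.95).
#' @return data.frame of candidate pairs (chainA, chainB, nShared,
#'   identity), best first; zero rows if none qualify.
#' @export
findDuplicateProteinChains <- function(atoms, minResidues = 40,
                                       maxResidues = 250,
                                       minIdentity = 0.95) {
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  sizes <- table(ca$chain)
  chains <- names(sizes)[sizes >= minResidues & sizes <= maxResidues]
  out <- data.frame(chainA = character(), chainB = character(),
                    nShared = integer(), identity = numeric())
  if (length(chains) < 2L) return(out)
  seqs <- lapply(chains, function(ch) {
    s <- ca[ca$chain == ch, ]
    stats::setNames(s$resid, s$resno)
  })
  names(seqs) <- chains
  cmb <- utils::combn(chains, 2L)
  for (i in seq_len(ncol(cmb))) {
    a <- seqs[[cmb[1, i]]]; b <- seqs[[cmb[2, i]]]
    shared <- intersect(names(a), names(b))
    if (length(shared) < minResidues * 0.5) next
    id <- mean(a[shared] == b[shared])
    if (id >= minIdentity)
      out <- rbind(out, data.frame(chainA = cmb[1, i], chainB = cmb[2, i],
                                   nShared = length(shared),
                                   identity = id))
  }
  out[order(-out$identity * out$nShared), , drop = FALSE]
}

#' Classify residues into site-specific and shared binders
#'
#' Given the contact-residue sets of the same protein bound at two
#' sites (e.g. bS20 in the small and in the large subunit), classifies
#' residue numbers into those binding at both sites, only at the first,
#' or only at the second.
#'
#' @param contactsA,contactsB data.frames from [contactResidues()].
#' @return list: \code{shared}, \code{onlyA}, \code{onlyB} (sorted
#'   residue numbers).
#' @export
classifyBinders <- function(contactsA, contactsB) {
  a <- contactsA$resno; b <- contactsB$resno
  list(shared = sort(intersect(a, b)),
       onlyA = sort(setdiff(a, b)),
       onlyB = sort(setdiff(b, a)))
}
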