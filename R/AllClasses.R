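#' @import methods
NULL

.requiredParticleCols <- c("particleID", "tomoID", "x", "y", "z",
                           "rot", "tilt", "psi")

#' ParticleSet: subtomogram particles with poses and class labels
#'
#' Container for a table of subtomogram particles. Each row is one
#' particle with a sequential unique identifier, the tomogram (= cell) it
#' came from, its refined position in Angstrom, its orientation as ZYZ
#' Euler angles in degrees, and any number of categorical label columns
#' (for example a bS20 occupancy class or a Trigger-Factor state).
#'
#' @slot particles data.frame with columns \code{particleID} (integer,
#'   unique and contiguous from 0), \code{tomoID} (character), \code{x},
#'   \code{y}, \code{z} (numeric, Angstrom), \code{rot}, \code{tilt},
#'   \code{psi} (numeric, degrees, normalised so that tilt is in
#'   [0, 180] and rot/psi in [-180, 180]), plus one column per label.
#' @slot pixelSize numeric(1), Angstrom per pixel used at load time.
#' @slot labelColumns character, names of the label columns.
#' @slot provenance character(1), source file path or generator tag.
#'
#' @seealso [readParticles()], [simulateScene()]
#' @export
setClass("ParticleSet",
  representation(particles = "data.frame", pixelSize = "numeric",
                 labelColumns = "character", provenance = "character"),
  prototype(particles = data.frame(), pixelSize = 1,
            labelColumns = character(), provenance = NA_character_))

setValidity("ParticleSet", function(object) {
  p <- object@particles
  msg <- character()
  if (nrow(p) > 0L) {
    missing <- setdiff(.requiredParticleCols, names(p))
    if (length(missing))
      msg <- c(msg, paste("missing particle columns:",
                          paste(missing, collapse = ", ")))
    else {
      if (anyDuplicated(p$particleID))
        msg <- c(msg, "particleID values must be unique")
      if (!identical(sort(as.integer(p$particleID)),
                     seq_len(nrow(p)) - 1L))
        msg <- c(msg, "particleID must be contiguous from 0")
      if (!all(is.finite(p$x) & is.finite(p$y) & is.finite(p$z)))
        msg <- c(msg, "positions must be finite")
      if (any(p$tilt < -1e-9 | p$tilt > 180 + 1e-9))
        msg <- c(msg, "tilt must lie in [0, 180] degrees")
      if (any(abs(p$rot) > 180 + 1e-9) || any(abs(p$psi) > 180 + 1e-9))
        msg <- c(msg, "rot and psi must lie in [-180, 180] degrees")
    }
    bad <- setdiff(object@labelColumns, names(p))
    if (length(bad))
      msg <- c(msg, paste("label columns absent from table:",
                          paste(bad, collapse = ", ")))
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' MarkerConfig: mRNA entry/exit marker offsets and tracing cut-offs
#'
#' Fixed points on the ribosome reference (subtomogram-average) frame
#' where the mRNA threads in and out, given as offsets in Angstrom from
#' the particle centre, together with the two distance cut-offs used by
#' the tracing (default 250 A, i.e. 25 nm) and the neighbour-distance
#' analysis (default 500 A, i.e. 50 nm).
#'
#' @slot entryOffset,exitOffset numeric(3), Angstrom, reference frame.
#' @slot traceCutoff,distanceCutoff numeric(1), Angstrom.
#' @slot mapDirection "inverse" (default; stored angles rotate the
#'   particle onto the reference, so markers are mapped with the
#'   transpose) or "forward".
#'
#' @seealso [markerConfig()], [mapMarkers()]
#' @export
setClass("MarkerConfig",
  representation(entryOffset = "numeric", exitOffset = "numeric",
                 traceCutoff = "numeric", distanceCutoff = "numeric",
                 mapDirection = "character"))

setValidity("MarkerConfig", function(object) {
  msg <- character()
  if (length(object@entryOffset) != 3L || !all(is.finite(object@entryOffset)))
    msg <- c(msg, "entryOffset must be a finite 3-vector")
  if (length(object@exitOffset) != 3L || !all(is.finite(object@exitOffset)))
    msg <- c(msg, "exitOffset must be a finite 3-vector")
  if (!isTRUE(object@traceCutoff > 0) || !isTRUE(object@distanceCutoff > 0))
    msg <- c(msg, "cut-offs must be positive")
  if (isTRUE(object@traceCutoff > object@distanceCutoff))
    msg <- c(msg, "traceCutoff must not exceed distanceCutoff")
  if (!object@mapDirection %in% c("forward", "inverse"))
    msg <- c(msg, "mapDirection must be 'forward' or 'inverse'")
  if (length(msg)) msg else TRUE
})

#' LinkGraph: directed exit-to-entry candidate links
#'
#' Directed graph in which a link i -> j records that particle j's mRNA
#' entry site is the nearest entry site to particle i's mRNA exit site
#' (within one tomogram, below the cut-off). After shared-neighbour
#' resolution every node has in-degree <= 1; after cycle removal the
#' graph is a disjoint union of simple paths.
#'
#' @slot links data.frame with columns \code{from}, \code{to} (integer
#'   particle IDs), \code{distance} (Angstrom) and \code{tomoID}.
#' @slot nParticles integer(1), number of particles in the originating
#'   set (nodes of the graph).
#'
#' @seealso [buildLinks()], [resolveShared()], [breakCycles()]
#' @export
setClass("LinkGraph",
  representation(links = "data.frame", nParticles = "integer"),
  prototype(links = data.frame(from = integer(), to = integer(),
                               distance = numeric(), tomoID = character()),
            nParticles = 0L))

setValidity("LinkGraph", function(object) {
  l <- object@links
  msg <- character()
  need <- c("from", "to", "distance", "tomoID")
  if (!all(need %in% names(l)))
    return(paste("links must have columns", paste(need, collapse = ", ")))
  if (nrow(l)) {
    if (any(l$from == l$to)) msg <- c(msg, "self-links are not allowed")
    if (any(l$distance < 0)) msg <- c(msg, "distances must be >= 0")
    if (anyDuplicated(l$from)) msg <- c(msg, "out-degree must be <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' PolysomeChainSet: traced polysome chains
#'
#' Ordered particle-ID sequences of the traced polysomes, one element per
#' chain, with the per-step exit-to-entry distances that connected them.
#' A reported polysome has length >= 2; monosomes are not chains.
#'
#' @slot chains list of integer vectors; element i is chain with
#'   \code{chainID == i - 1}, ordered from the chain start (the particle
#'   with no incoming link) along surviving links.
#' @slot stepDistances list of numeric vectors, one per chain, of length
#'   \code{length(chain) - 1}.
#' @slot tomoIDs character, tomogram of each chain.
#'
#' @seealso [chainPolysomes()], [tracePolysomes()]
#' @export
setClass("PolysomeChainSet",
  representation(chains = "list", stepDistances = "list",
                 tomoIDs = "character"),
  prototype(chains = list(), stepDistances = list(), tomoIDs = character()))

setValidity("PolysomeChainSet", function(object) {
  msg <- character()
  if (length(object@chains) != length(object@stepDistances) ||
      length(object@chains) != length(object@tomoIDs))
    return("chains, stepDistances and tomoIDs must have equal length")
  for (i in seq_along(object@chains)) {
    ch <- object@chains[[i]]
    if (length(ch) < 2L) msg <- c(msg, "every chain must have length >= 2")
    if (length(object@stepDistances[[i]]) != length(ch) - 1L)
      msg <- c(msg, "stepDistances must have one entry per link")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' InterfaceReport: buried areas and parameters for one chain interface
#'
#' Result of a buried-surface-area calculation of a query chain against
#' partner chains: total buried area (SASA lost upon complex formation)
#' and its per-partner-chain split, with the numerical parameters used.
#'
#' @slot queryChain character(1).
#' @slot buriedTotal numeric(1), Angstrom^2.
#' @slot buriedByChain named numeric, Angstrom^2 per partner chain.
#' @slot parameters list: probe radius, sphere points, radii table tag.
#'
#' @seealso [buriedArea()]
#' @export
setClass("InterfaceReport",
  representation(queryChain = "character", buriedTotal = "numeric",
                 buriedByChain = "numeric", parameters = "list"))

setValidity("InterfaceReport", function(object) {
  msg <- character()
  if (object@buriedTotal < -1e-6) msg <- c(msg, "buried area must be >= 0")
  if (any(object@buriedByChain < -1e-6))
    msg <- c(msg, "per-chain buried areas must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ParticleSet", function(object) {
  p <- object@particles
  cat("ParticleSet with", nrow(p), "particles in",
      length(unique(p$tomoID)), "tomogram(s)\n")
  cat("  pixelSize:", object@pixelSize, "A/px;  provenance:",
      object@provenance, "\n")
  if (length(object@labelColumns))
    cat("  labels:", paste(object@labelColumns, collapse = ", "), "\n")
})

setMethod("show", "MarkerConfig", function(object) {
  cat("MarkerConfig\n")
  cat("  entry offset (A):", paste(signif(object@entryOffset, 4),
                                   collapse = ", "), "\n")
  cat("  exit  offset (A):", paste(signif(object@exitOffset, 4),
                                   collapse = ", "), "\n")
  cat("  trace cut-off:", object@traceCutoff, "A;  distance cut-off:",
      object@distanceCutoff, "A;  mapping:", object@mapDirection, "\n")
})

setMethod("show", "LinkGraph", function(object) {
  cat("LinkGraph with", nrow(object@links), "links over",
      object@nParticles, "particles\n")
})

setMethod("show", "PolysomeChainSet", function(object) {
  n <- length(object@chains)
  cat("PolysomeChainSet with", n, "chains\n")
  if (n) {
    len <- lengths(object@chains)
    cat("  lengths: min", min(len), "median", stats::median(len),
        "max", max(len), ";", sum(len), "linked particles\n")
  }
})

setMethod("show", "InterfaceReport", function(object) {
  cat("InterfaceReport for chain", object@queryChain, "\n")
  cat("  buried area:", round(object@buriedTotal, 1), "A^2\n")
  if (length(object@buriedByChain)) {
    for (nm in names(object@buriedByChain))
      cat("    vs", nm, ":", round(object@buriedByChain[[nm]], 1), "A^2\n")
  }
  cat("  probe", object@parameters$probe, "A,",
      object@parameters$nPoints, "sphere points\n")
})
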