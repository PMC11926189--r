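#' Build the directed exit-to-entry nearest-neighbour link graph
#'
#' For every particle i, maps the mRNA exit marker of i and the mRNA
#' entry markers of all other particles in the same tomogram into the
#' tomogram frame, and records at most one candidate link i -> j to the
#' particle j whose entry site is closest to i's exit site, provided
#' that distance is below the cut-off. Links never cross tomogram
#' (= cell) boundaries. Ties are broken towards the smaller particleID.
#'
#' @param pset a \linkS4class{ParticleSet}.
#' @param markers a \linkS4class{MarkerConfig}.
#' @param cutoff Angstrom; defaults to the tracing cut-off (250 A).
#' @return a \linkS4class{LinkGraph} with out-degree <= 1 per node.
#' @export
buildLinks <- function(pset, markers, cutoff = markers@traceCutoff) {
  stopifnot(cutoff > 0)
  p <- particles(pset)
  res <- list()
  if (nrow(p)) {
    exit <- mapMarkers(pset, markers@exitOffset, markers@mapDirection)
    entry <- mapMarkers(pset, markers@entryOffset, markers@mapDirection)
    for (tm in unique(p$tomoID)) {
      idx <- which(p$tomoID == tm)
      if (length(idx) < 2L) next
      E <- exit[idx, , drop = FALSE]
      N <- entry[idx, , drop = FALSE]
      # squared distance matrix exit(i) -> entry(j)
      d2 <- outer(rowSums(E^2), rowSums(N^2), "+") - 2 * E %*% t(N)
      diag(d2) <- Inf
      best <- apply(d2, 1L, which.min)   # first minimum = smaller ID
      dist <- sqrt(pmax(d2[cbind(seq_along(idx), best)], 0))
      keep <- dist < cutoff
      if (any(keep))
        res[[tm]] <- data.frame(
          from = p$particleID[idx[keep]],
          to = p$particleID[idx[best[keep]]],
          distance = dist[keep], tomoID = tm,
          stringsAsFactors = FALSE)
    }
  }
  lk <- if (length(res)) do.call(rbind, c(res, list(make.row.names = FALSE)))
        else data.frame(from = integer(), to = integer(),
                        distance = numeric(), tomoID = character())
  new("LinkGraph", links = lk, nParticles = nrow(p))
}

#' Resolve shared neighbours: keep only the shortest incoming link
#'
#' If multiple particles share the same nearest entry-site neighbour,
#' only the shortest of the competing links is kept, so that every node
#' ends with in-degree <= 1. Ties are broken towards the smaller source
#' particleID. No links are added.
#'
#' @param graph a \linkS4class{LinkGraph} from [buildLinks()].
#' @return a \linkS4class{LinkGraph} with in-degree <= 1 everywhere.
#' @export
resolveShared <- function(graph) {
  l <- links(graph)
  if (nrow(l) > 1L) {
    ord <- order(l$to, l$distance, l$from)
    l <- l[ord, , drop = FALSE]
    l <- l[!duplicated(l$to), , drop = FALSE]
    l <- l[order(l$from), , drop = FALSE]
    rownames(l) <- NULL
  }
  new("LinkGraph", links = l, nParticles = graph@nParticles)
}

#' Remove cycles: drop the longest link of every closed circle
#'
#' With in- and out-degree both <= 1 every weak component is a simple
#' path or a simple cycle. Each cycle is opened by removing its
#' maximal-distance link (ties: remove the link with the larger source
#' particleID), leaving a disjoint union of simple paths.
#'
#' @param graph a \linkS4class{LinkGraph} with degree bounds satisfied.
#' @return an acyclic \linkS4class{LinkGraph}.
#' @export
breakCycles <- function(graph) {
  l <- links(graph)
  if (anyDuplicated(l$from) || anyDuplicated(l$to))
    stop("breakCycles requires in-degree <= 1 and out-degree <= 1")
  if (nrow(l) == 0L) return(graph)
  succ <- stats::setNames(l$to, as.character(l$from))
  state <- new.env(hash = TRUE)                # 1 = in progress, 2 = done
  drop <- logical(nrow(l))
  for (start in l$from) {
    if (!is.null(state[[as.character(start)]])) next
    path <- character()
    node <- as.character(start)
    repeat {
      st <- state[[node]]
      if (!is.null(st)) {
        if (st == 1L) {                        # closed circle found
          cyc <- path[which(path == node)[1]:length(path)]
          rows <- match(as.numeric(cyc), l$from)
          dmax <- max(l$distance[rows])
          cand <- rows[l$distance[rows] == dmax]
          drop[cand[which.max(l$from[cand])]] <- TRUE
        }
        break
      }
      state[[node]] <- 1L
      path <- c(path, node)
      node2 <- succ[node]
      if (is.na(node2)) break
      node <- as.character(node2)
    }
    for (nd in path) state[[nd]] <- 2L
  }
  l <- l[!drop, , drop = FALSE]
  rownames(l) <- NULL
  new("LinkGraph", links = l, nParticles = graph@nParticles)
}

#' Assemble polysome chains from a resolved, acyclic link graph
#'
#' The first unit of each chain is the particle that has an outgoing
#' link but no incoming link; particles are then chained along surviving
#' links until none remains. Every linked particle belongs to exactly
#' one chain; isolated particles (monosomes) are not chains.
#'
#' @param graph an acyclic \linkS4class{LinkGraph} with degrees <= 1.
#' @return a \linkS4class{PolysomeChainSet}.
#' @export
chainPolysomes <- function(graph) {
  l <- links(graph)
  if (anyDuplicated(l$from) || anyDuplicated(l$to))
    stop("chainPolysomes requires in-degree <= 1 and out-degree <= 1")
  chains <- list(); steps <- list(); tomos <- character()
  if (nrow(l)) {
    starts <- sort(setdiff(l$from, l$to))
    if (!length(starts)) stop("link graph contains a cycle; run breakCycles first")
    for (s in starts) {
      mem <- s; dd <- numeric()
      node <- s
      repeat {
        row <- match(node, l$from)
        if (is.na(row)) break
        dd <- c(dd, l$distance[row])
        node <- l$to[row]
        mem <- c(mem, node)
      }
      chains[[length(chains) + 1L]] <- as.integer(mem)
      steps[[length(steps) + 1L]] <- dd
      tomos <- c(tomos, l$tomoID[match(s, l$from)])
    }
    if (sum(lengths(chains)) != length(unique(unlist(chains))))
      stop("internal error: particle assigned to two chains")
  }
  new("PolysomeChainSet", chains = chains, stepDistances = steps,
      tomoIDs = tomos)
}

#' Trace polysomes: full pipeline from particle poses to chains
#'
#' Composition of the four tracing stages, per tomogram: build the
#' exit-to-entry nearest-neighbour links at the tracing cut-off, keep
#' only the shortest link to any shared neighbour, open closed circles
#' by removing their longest link, and assemble the remaining paths into
#' ordered polysome chains. Fully deterministic for fixed input.
#'
#' @param pset a \linkS4class{ParticleSet}.
#' @param markers a \linkS4class{MarkerConfig}.
#' @param cutoff Angstrom, default the tracing cut-off in \code{markers}.
#' @return list with elements \code{chains}
#'   (\linkS4class{PolysomeChainSet}) and \code{graph} (the resolved,
#'   acyclic \linkS4class{LinkGraph}), plus \code{counts}: particles,
#'   candidate links, links removed by the shared-neighbour rule, links
#'   removed by cycle opening, chains formed.
#' @export
tracePolysomes <- function(pset, markers, cutoff = markers@traceCutoff) {
  g0 <- buildLinks(pset, markers, cutoff)
  g1 <- resolveShared(g0)
  g2 <- breakCycles(g1)
  ch <- chainPolysomes(g2)
  list(chains = ch, graph = g2,
       counts = c(particles = nParticles(pset),
                  candidateLinks = nrow(links(g0)),
                  removedShared = nrow(links(g0)) - nrow(links(g1)),
                  removedCycles = nrow(links(g1)) - nrow(links(g2)),
                  chains = length(chainMembers(ch))))
}
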