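# Independent brute-force oracles, written naively on purpose so they do
# not share code paths with the implementation they check.

# --- rotation built from scratch (scalar trig, no shared helpers) ------
bfRotation <- function(rot, tilt, psi) {
  d <- pi / 180
  a <- rot * d; b <- tilt * d; c <- psi * d
  Rza <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  Ryb <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rzc <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rza %*% Ryb %*% Rzc
}

bfMapMarker <- function(row, offset, direction = "inverse") {
  R <- bfRotation(row$rot, row$tilt, row$psi)
  A <- if (direction == "inverse") t(R) else R
  c(row$x, row$y, row$z) + as.numeric(A %*% offset)
}

# --- naive tracing pipeline -------------------------------------------
# particles: data.frame(particleID, tomoID, x, y, z, rot, tilt, psi)
bfBuildLinks <- function(p, entryOff, exitOff, cutoff,
                         direction = "inverse") {
  links <- data.frame(from = integer(), to = integer(),
                      distance = numeric(), tomoID = character())
  for (i in seq_len(nrow(p))) {
    best <- NA; bestD <- Inf
    ei <- bfMapMarker(p[i, ], exitOff, direction)
    for (j in seq_len(nrow(p))) {
      if (i == j || p$tomoID[i] != p$tomoID[j]) next
      nj <- bfMapMarker(p[j, ], entryOff, direction)
      dd <- sqrt(sum((ei - nj)^2))
      if (dd < bestD) { bestD <- dd; best <- j }
    }
    if (!is.na(best) && bestD < cutoff)
      links <- rbind(links, data.frame(from = p$particleID[i],
                                       to = p$particleID[best],
                                       distance = bestD,
                                       tomoID = p$tomoID[i]))
  }
  links
}

bfResolveShared <- function(links) {
  keep <- rep(TRUE, nrow(links))
  for (t in unique(links$to)) {
    rows <- which(links$to == t)
    if (length(rows) > 1L) {
      dmin <- min(links$distance[rows])
      cand <- rows[links$distance[rows] == dmin]
      winner <- cand[which.min(links$from[cand])]
      keep[setdiff(rows, winner)] <- FALSE
    }
  }
  links[keep, , drop = FALSE]
}

bfBreakCycles <- function(links) {
  repeat {
    # find a cycle by walking successors from every node
    cyc <- NULL
    for (s in links$from) {
      seen <- c()
      node <- s
      while (node %in% links$from) {
        if (node %in% seen) {
          cyc <- seen[which(seen == node):length(seen)]
          break
        }
        seen <- c(seen, node)
        node <- links$to[links$from == node]
      }
      if (!is.null(cyc)) break
    }
    if (is.null(cyc)) return(links)
    rows <- which(links$from %in% cyc & links$to %in% cyc)
    # restrict to the actual cycle edges (successor relation)
    rows <- rows[vapply(rows, function(r) {
      i <- which(cyc == links$from[r])
      nxt <- if (i == length(cyc)) cyc[1] else cyc[i + 1]
      links$to[r] == nxt
    }, logical(1))]
    dmax <- max(links$distance[rows])
    cand <- rows[links$distance[rows] == dmax]
    victim <- cand[which.max(links$from[cand])]
    links <- links[-victim, , drop = FALSE]
  }
}

bfChains <- function(links) {
  chains <- list()
  starts <- sort(setdiff(links$from, links$to))
  for (s in starts) {
    mem <- s; node <- s
    while (node %in% links$from) {
      node <- links$to[links$from == node]
      mem <- c(mem, node)
    }
    chains[[length(chains) + 1L]] <- as.integer(mem)
  }
  chains
}

bfTrace <- function(p, entryOff, exitOff, cutoff, direction = "inverse") {
  l <- bfBuildLinks(p, entryOff, exitOff, cutoff, direction)
  l <- bfResolveShared(l)
  l <- bfBreakCycles(l)
  list(links = l, chains = bfChains(l))
}

# --- random small scenes and comparison utilities ---------------------
randomParticleTable <- function(n, box = 600, nTomo = 1) {
  data.frame(particleID = seq_len(n) - 1L,
             tomoID = paste0("t", sample.int(nTomo, n, replace = TRUE)),
             x = runif(n, 0, box), y = runif(n, 0, box),
             z = runif(n, 0, box),
             rot = runif(n, -180, 180),
             tilt = acos(runif(n, -1, 1)) * 180 / pi,
             psi = runif(n, -180, 180),
             stringsAsFactors = FALSE)
}

asParticleSet <- function(p, labels = character()) {
  new("ParticleSet", particles = p, pixelSize = 1,
      labelColumns = labels, provenance = "test")
}

normLinks <- function(l) {
  l <- l[order(l$from), c("from", "to", "distance")]
  rownames(l) <- NULL
  l
}

sameChains <- function(a, b) {
  norm <- function(l) sort(vapply(l, function(x) paste(x, collapse = ","),
                                  character(1)))
  identical(norm(a), norm(b))
}

truthLinks <- function(truth) {
  do.call(rbind, lapply(truth$chains, function(ch) {
    if (length(ch) < 2) NULL
    else data.frame(from = ch[-length(ch)], to = ch[-1])
  }))
}

linkPrecisionRecall <- function(found, truth) {
  key <- function(df) paste(df$from, df$to)
  f <- key(found); t <- key(truth)
  c(precision = if (length(f)) mean(f %in% t) else NA_real_,
    recall = if (length(t)) mean(t %in% f) else NA_real_)
}

defaultMarkers <- function(...) markerConfig(c(55, 0, 0), c(-55, 0, 0), ...)

# --- toy structure fixtures -------------------------------------------
writeToyPDB <- function(path, atoms) {
  # atoms: data.frame(elety, alt, resid, chain, resno, x, y, z, occ, element)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
    atoms$alt, atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$occ, 10.0, atoms$element)
  writeLines(c(lines, "END"), path)
  path
}

writeToyCIF <- function(path, atoms) {
  hdr <- c("data_toy", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  alt <- ifelse(atoms$alt == " " | atoms$alt == "", ".", atoms$alt)
  rows <- sprintf(
    "ATOM %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 10.00 ? %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$element, atoms$elety, alt, atoms$resid,
    atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z, atoms$occ,
    atoms$resno, atoms$resid, atoms$chain, atoms$elety)
  writeLines(c(hdr, rows, "#"), path)
  path
}

toyAtomTable <- function(chain, resno, elety, element, x, y, z,
                         resid = "ALA", occupancy = 1) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, element = element, x = x, y = y, z = z,
             occupancy = occupancy, stringsAsFactors = FALSE)
}
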