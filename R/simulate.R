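#' Parameters for a synthetic particle scene
#'
#' Describes the statistical structure of a simulated multi-cell
#' particle dataset: planted polysome chains whose exit-to-entry step
#' distances fall well below the tracing cut-off, isolated monosomes
#' with a clearance that prevents spurious links, Bernoulli class labels
#' at stated rates, and optional positional noise. Defaults mirror the
#' cellular dataset the analysis targets: 28 cells, bS20 large-subunit
#' occupancy 0.67, Trigger-Factor bound fraction 0.88, polysome lengths
#' 2 + Poisson(3), step distances ~N(70, 15) A truncated positive.
#'
#' @param nCells number of cells (= tomograms).
#' @param cellBox numeric(3), Angstrom extents of each cell volume.
#' @param nPolysomesPerCell planted polysomes per cell.
#' @param polysomeLength fixed chain length, or NULL (default) to draw
#'   lengths as 2 + Poisson(\code{lengthLambda}).
#' @param lengthLambda Poisson mean for the length surplus over 2.
#' @param stepDistanceMean,stepDistanceSD Angstrom, exit-to-entry step
#'   distance distribution (normal truncated > 0).
#' @param monosomeCount isolated monosomes per cell.
#' @param monosomeMinClearance Angstrom, minimum centre-to-centre
#'   distance from a monosome to every other particle.
#' @param occupancyP probability a ribosome carries the second bS20 copy
#'   (label value "2xbS20").
#' @param tfBoundP probability the Trigger-Factor label is "bound".
#' @param stateProbs named probability vector over functional states.
#' @param positionNoiseSD Angstrom, isotropic noise added to particle
#'   centres (markers move rigidly with the particle).
#' @param maxTurnDeg maximum turning angle of the polysome path per step.
#' @param orientationJitterDeg angular jitter between consecutive
#'   polysome members (path-following orientation model).
#' @param markers \linkS4class{MarkerConfig}; defaults put entry and
#'   exit on opposite sides of the small subunit, 110 A (11 nm) apart.
#' @param seed default random seed used by [simulateScene()].
#' @return validated parameter list of class "SceneParams".
#' @export
sceneParams <- function(nCells = 28,
                        cellBox = c(5000, 5000, 1500),
                        nPolysomesPerCell = 6,
                        polysomeLength = NULL,
                        lengthLambda = 3,
                        stepDistanceMean = 70,
                        stepDistanceSD = 15,
                        monosomeCount = 30,
                        monosomeMinClearance = 600,
                        occupancyP = 0.67,
                        tfBoundP = 0.88,
                        stateProbs = c(aa_tRNA = 0.25,
                                       pre_translocation = 0.35,
                                       post_translocation = 0.40),
                        positionNoiseSD = 0,
                        maxTurnDeg = 60,
                        orientationJitterDeg = 20,
                        markers = markerConfig(c(55, 0, 0), c(-55, 0, 0)),
                        seed = 1L) {
  stopifnot(nCells >= 1, length(cellBox) == 3L, all(cellBox > 0),
            nPolysomesPerCell >= 0, monosomeCount >= 0,
            stepDistanceMean > 0, stepDistanceSD >= 0,
            monosomeMinClearance > 0,
            occupancyP >= 0, occupancyP <= 1,
            tfBoundP >= 0, tfBoundP <= 1,
            abs(sum(stateProbs) - 1) < 1e-9,
            positionNoiseSD >= 0, maxTurnDeg >= 0,
            is(markers, "MarkerConfig"))
  if (!is.null(polysomeLength)) stopifnot(polysomeLength >= 2)
  structure(as.list(environment()), class = "SceneParams")
}

.truncNorm <- function(mean, sd) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
}

# Rotation taking unit vector a onto unit vector b (minimal rotation).
.rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    return(.axisAngleToMatrix(ax / sqrt(sum(ax^2)), pi))
  }
  .axisAngleToMatrix(v / s, atan2(s, cth))
}

# Bounded random turn of a unit direction (angle <= maxDeg).
.turnDirection <- function(u, maxDeg) {
  as.numeric(.randomJitterRotation(maxDeg) %*% u)
}

#' Simulate a multi-cell particle scene with planted ground truth
#'
#' Generates particle positions, orientations and labels per
#' [sceneParams()]. Polysomes are built as bounded-turn 3-D random
#' walks: each successive ribosome is oriented by a path-following
#' rotation with angular jitter and positioned so that its mapped mRNA
#' entry marker lies exactly at the drawn step distance from the
#' predecessor's mapped mRNA exit marker (under the marker-mapping
#' convention in \code{params$markers}). Monosomes are rejection-sampled
#' with the stated clearance. Labels are i.i.d. Bernoulli/categorical.
#' Fully reproducible from the seed.
#'
#' @param params a list from [sceneParams()].
#' @param seed integer; overrides \code{params$seed}.
#' @return list: \code{particles} (\linkS4class{ParticleSet} with labels
#'   occupancy, tf, state), \code{truth} (list with \code{chains} = list
#'   of ordered particleID vectors, \code{stepDistances},
#'   \code{tomoIDs}).
#' @export
simulateScene <- function(params = sceneParams(), seed = params$seed) {
  stopifnot(inherits(params, "SceneParams"))
  set.seed(as.integer(seed))
  mk <- params$markers
  entryOff <- mk@entryOffset; exitOff <- mk@exitOffset
  inv <- mk@mapDirection == "inverse"
  margin <- max(sqrt(sum(entryOff^2)), sqrt(sum(exitOff^2))) + 50
  rows <- list(); truthChains <- list(); truthSteps <- list()
  truthTomo <- character()
  nextID <- 0L
  maxAttempts <- 10000L
  for (cell in seq_len(params$nCells)) {
    tomo <- sprintf("cell_%02d", cell)
    cellPos <- list()   # particle centres placed so far in this cell
    addRow <- function(pos, A) {
      # stored angles: marker mapping uses t(R) when inverse, so R = t(A)
      R <- if (inv) t(A) else A
      eul <- .matrixToEuler(R)
      rows[[length(rows) + 1L]] <<- data.frame(
        particleID = nextID, tomoID = tomo,
        x = pos[1], y = pos[2], z = pos[3],
        rot = eul$rot, tilt = eul$tilt, psi = eul$psi)
      cellPos[[length(cellPos) + 1L]] <<- pos
      nextID <<- nextID + 1L
      nextID - 1L
    }
    inBox <- function(p) all(p > margin) && all(p < params$cellBox - margin)
    clearOf <- function(p, dmin) {
      if (!length(cellPos)) return(TRUE)
      all(vapply(cellPos, function(q) sum((p - q)^2), numeric(1)) >= dmin^2)
    }
    for (pl in seq_len(params$nPolysomesPerCell)) {
      L <- if (!is.null(params$polysomeLength)) params$polysomeLength
           else 2L + stats::rpois(1, params$lengthLambda)
      placed <- FALSE
      w <- exitOff / sqrt(sum(exitOff^2))   # reference exit direction
      for (attempt in seq_len(maxAttempts)) {
        pos1 <- stats::runif(3, margin, params$cellBox - margin)
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        # path-following orientation: the exit marker faces the next
        # member along the walk, with bounded angular jitter
        A <- .randomJitterRotation(params$orientationJitterDeg) %*%
          .rotationBetween(w, u)
        posList <- list(pos1); rotList <- list(A); dList <- numeric()
        ok <- inBox(pos1) && clearOf(pos1, params$monosomeMinClearance)
        if (ok) {
          for (k in seq_len(L - 1L)) {
            d <- .truncNorm(params$stepDistanceMean, params$stepDistanceSD)
            prev <- posList[[k]]; Ap <- rotList[[k]]
            exitPt <- prev + as.numeric(Ap %*% exitOff)
            u <- .turnDirection(u, params$maxTurnDeg)
            entryPt <- exitPt + d * u
            Anew <- .randomJitterRotation(params$orientationJitterDeg) %*%
              .rotationBetween(w, u)
            posNew <- entryPt - as.numeric(Anew %*% entryOff)
            if (!inBox(posNew) ||
                !clearOf(posNew, params$monosomeMinClearance)) {
              ok <- FALSE; break
            }
            posList[[k + 1L]] <- posNew
            rotList[[k + 1L]] <- Anew
            dList <- c(dList, d)
          }
        }
        if (ok && L > 1L) {
          # planted links must be the strictly nearest exit-to-entry
          # pairs within the chain, so recovery is a geometric fact
          ex <- t(vapply(seq_len(L), function(k)
            posList[[k]] + as.numeric(rotList[[k]] %*% exitOff),
            numeric(3)))
          en <- t(vapply(seq_len(L), function(k)
            posList[[k]] + as.numeric(rotList[[k]] %*% entryOff),
            numeric(3)))
          dmax <- max(dList)
          for (i in seq_len(L)) {
            for (j in seq_len(L)) {
              if (j == i || j == i + 1L) next
              if (sqrt(sum((ex[i, ] - en[j, ])^2)) <= dmax * 1.001) {
                ok <- FALSE; break
              }
            }
            if (!ok) break
          }
        }
        if (ok) {
          ids <- integer(L)
          for (k in seq_len(L)) ids[k] <- addRow(posList[[k]], rotList[[k]])
          truthChains[[length(truthChains) + 1L]] <- ids
          truthSteps[[length(truthSteps) + 1L]] <- dList
          truthTomo <- c(truthTomo, tomo)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("capacity: could not place polysome ", pl, " in ", tomo,
             " after ", maxAttempts, " attempts; enlarge cellBox or reduce content")
    }
    for (ms in seq_len(params$monosomeCount)) {
      placed <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        pos <- stats::runif(3, margin, params$cellBox - margin)
        if (clearOf(pos, params$monosomeMinClearance)) {
          addRow(pos, .randomRotation())
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("capacity: could not place monosome ", ms, " in ", tomo,
             " after ", maxAttempts, " attempts; enlarge cellBox or reduce content")
    }
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(particleID = integer(), tomoID = character(),
                         x = numeric(), y = numeric(), z = numeric(),
                         rot = numeric(), tilt = numeric(), psi = numeric())
  n <- nrow(tab)
  if (n && params$positionNoiseSD > 0) {
    tab$x <- tab$x + stats::rnorm(n, 0, params$positionNoiseSD)
    tab$y <- tab$y + stats::rnorm(n, 0, params$positionNoiseSD)
    tab$z <- tab$z + stats::rnorm(n, 0, params$positionNoiseSD)
  }
  if (n) {
    tab$occupancy <- ifelse(stats::runif(n) < params$occupancyP,
                            "2xbS20", "1xbS20")
    tab$tf <- ifelse(stats::runif(n) < params$tfBoundP, "bound", "free")
    tab$state <- sample(names(params$stateProbs), n, replace = TRUE,
                        prob = params$stateProbs)
  } else {
    tab$occupancy <- character(); tab$tf <- character()
    tab$state <- character()
  }
  pset <- new("ParticleSet", particles = tab, pixelSize = 1,
              labelColumns = c("occupancy", "tf", "state"),
              provenance = sprintf("simulateScene(seed=%d)", as.integer(seed)))
  list(particles = pset,
       truth = list(chains = truthChains, stepDistances = truthSteps,
                    tomoIDs = truthTomo))
}

# Symmetric ring scene: k particles whose exit-to-entry links close into
# a cycle. Junction points sit on a regular k-gon; each particle's
# orientation is solved so its entry marker lands exactly on a junction
# and its exit marker points along the chord towards the next junction,
# at gap distance d + perturb[i]. Forces breakCycles to fire.
.ringScene <- function(k = 6, d = 40,
                       markers = markerConfig(c(55, 0, 0), c(-55, 0, 0)),
                       perturb = NULL, tomoID = "ring_cell",
                       centre = c(2000, 2000, 500)) {
  stopifnot(k >= 3)
  if (is.null(perturb)) perturb <- seq(0, by = 2, length.out = k)
  w <- markers@exitOffset - markers@entryOffset
  s <- sqrt(sum(w^2))
  chord <- s + d
  Rc <- chord / (2 * sin(pi / k))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  J <- cbind(centre[1] + Rc * cos(ang), centre[2] + Rc * sin(ang),
             centre[3])
  rows <- list()
  inv <- markers@mapDirection == "inverse"
  for (i in seq_len(k)) {
    nxt <- if (i == k) 1L else i + 1L
    u <- J[nxt, ] - J[i, ]
    u <- u / sqrt(sum(u^2))
    A <- .rotationBetween(w / s, u)
    # shift the particle back along its own chord so link lengths differ
    pos <- J[i, ] - perturb[i] * u - as.numeric(A %*% markers@entryOffset)
    R <- if (inv) t(A) else A
    eul <- .matrixToEuler(R)
    rows[[i]] <- data.frame(particleID = i - 1L, tomoID = tomoID,
                            x = pos[1], y = pos[2], z = pos[3],
                            rot = eul$rot, tilt = eul$tilt, psi = eul$psi)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$occupancy <- rep(c("2xbS20", "1xbS20"), length.out = k)
  tab$tf <- "bound"; tab$state <- "pre_translocation"
  new("ParticleSet", particles = tab, pixelSize = 1,
      labelColumns = c("occupancy", "tf", "state"),
      provenance = "ringScene")
}

#' Write a graded suite of synthetic fixtures
#'
#' Emits a set of STAR files plus ground-truth JSON covering the regimes
#' the tracer must handle: a tiny hand-checkable 3-particle chain, a
#' study-scale 28-cell mimic (occupancy 0.67, Trigger Factor 0.88),
#' a tie case (two particles exactly equidistant from one shared
#' neighbour), a near-cut-off case (one pair just below, one just above
#' the tracing cut-off), and a symmetric ring whose naive linking closes
#' into a cycle.
#'
#' @param outDir writable directory (created if needed).
#' @param seed integer seed for the stochastic scenes.
#' @return invisibly, named character vector of files written.
#' @export
emitFixtureSuite <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, pset, truth = NULL) {
    star <- file.path(outDir, paste0(name, ".star"))
    writeParticles(pset, star)
    files[star] <<- star
    if (!is.null(truth)) {
      js <- file.path(outDir, paste0(name, "_truth.json"))
      jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
      files[js] <<- js
    }
  }
  mk <- markerConfig(c(55, 0, 0), c(-55, 0, 0))

  tiny <- simulateScene(sceneParams(nCells = 1, nPolysomesPerCell = 1,
                                    polysomeLength = 3, monosomeCount = 0,
                                    cellBox = c(3000, 3000, 3000),
                                    markers = mk), seed = seed)
  emit("tiny_chain3", tiny$particles, tiny$truth)

  study <- simulateScene(sceneParams(), seed = seed + 1L)
  emit("study_mimic_28cell", study$particles, study$truth)

  # ties: exits of particles 1 and 2 are both exactly 30 A from the
  # entry of particle 0 (flipped poses), so every rule fires with a tie
  p <- data.frame(particleID = 0:2, tomoID = "tie_cell",
                  x = c(1000, 1000, 1000),
                  y = c(1000, 1030, 970),
                  z = 500, rot = 0, tilt = c(0, 180, 180), psi = 0)
  p$occupancy <- "1xbS20"; p$tf <- "free"; p$state <- "aa_tRNA"
  ties <- new("ParticleSet", particles = p, pixelSize = 1,
              labelColumns = c("occupancy", "tf", "state"),
              provenance = "ties fixture")
  emit("shared_neighbour_tie", ties,
       list(note = paste("exits of 1 and 2 are both 30 A from the entry of 0;",
                         "shortest-link tie keeps 1->0 (smaller from-ID),",
                         "0's exit ties between the entries of 1 and 2 (keeps 0->1),",
                         "the resulting 2-cycle 0<->1 is opened by removing 1->0",
                         "(equal lengths, larger from-ID), leaving chain 0->1")))

  # near cut-off: pair at gap 249.5 (kept) and pair at gap 250.5 (dropped);
  # identity poses along +x, so the particle at larger x leads
  q <- data.frame(particleID = 0:3, tomoID = "edge_cell",
                  x = c(0, 110 + 249.5, 8000, 8000 + 110 + 250.5),
                  y = 0, z = 0, rot = 0, tilt = 0, psi = 0)
  q$occupancy <- "2xbS20"; q$tf <- "bound"; q$state <- "post_translocation"
  edge <- new("ParticleSet", particles = q, pixelSize = 1,
              labelColumns = c("occupancy", "tf", "state"),
              provenance = "near-cutoff fixture")
  emit("near_cutoff_pairs", edge,
       list(note = "link 1->0 at 249.5 A survives the 250 A trace cut-off; 3->2 at 250.5 A does not"))

  ring <- .ringScene(k = 6, d = 40, markers = mk)
  emit("ring_cycle6", ring,
       list(note = "6 particles on a ring; naive linking forms a 6-cycle; the longest link (largest perturbation) must be removed"))
  invisible(files)
}
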