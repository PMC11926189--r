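#' Construct a MarkerConfig
#'
#' The mRNA entry and exit sites are fixed points on the small ribosomal
#' subunit, given here as offsets (Angstrom) from the particle centre in
#' the subtomogram-average reference frame. The two cut-offs are those
#' of the tracing workflow: 250 A (25 nm) for polysome tracing and
#' 500 A (50 nm) for the neighbour-distance (elongation-rate) analysis.
#'
#' @param entryOffset,exitOffset numeric(3), Angstrom.
#' @param traceCutoff,distanceCutoff numeric(1), Angstrom.
#' @param mapDirection how stored Euler angles relate the reference frame
#'   to the tomogram frame. With \code{"inverse"} (default, the RELION
#'   alignment convention: stored angles rotate the particle onto the
#'   reference) a marker at reference offset v maps to
#'   \code{position + t(R) \%*\% v}; with \code{"forward"} to
#'   \code{position + R \%*\% v}. Use [exportMarkers()] to render both
#'   candidate clouds and verify against a map.
#' @return a \linkS4class{MarkerConfig}.
#' @examples
#' markerConfig(entryOffset = c(55, 0, 0), exitOffset = c(-55, 0, 0))
#' @export
markerConfig <- function(entryOffset, exitOffset,
                         traceCutoff = 250, distanceCutoff = 500,
                         mapDirection = c("inverse", "forward")) {
  mapDirection <- match.arg(mapDirection)
  new("MarkerConfig", entryOffset = as.numeric(entryOffset),
      exitOffset = as.numeric(exitOffset),
      traceCutoff = as.numeric(traceCutoff),
      distanceCutoff = as.numeric(distanceCutoff),
      mapDirection = mapDirection)
}

#' Read a MarkerConfig from a YAML file
#'
#' Expects keys \code{entry_offset}, \code{exit_offset} (3-vectors, A)
#' and optionally \code{trace_cutoff}, \code{distance_cutoff} (A) and
#' \code{map_direction}.
#'
#' @param path YAML file.
#' @return a \linkS4class{MarkerConfig}.
#' @export
readMarkerConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entry_offset) || is.null(cfg$exit_offset))
    stop("marker config must define entry_offset and exit_offset")
  markerConfig(entryOffset = unlist(cfg$entry_offset),
               exitOffset = unlist(cfg$exit_offset),
               traceCutoff = cfg$trace_cutoff %||% 250,
               distanceCutoff = cfg$distance_cutoff %||% 500,
               mapDirection = cfg$map_direction %||% "inverse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a reference-frame marker into tomogram coordinates
#'
#' Applies each particle's rigid pose to a marker offset defined in the
#' subtomogram-average frame, returning the marker position in the
#' tomogram frame: \code{position + A \%*\% offset}, where A is the
#' reference-to-particle rotation implied by the stored Euler angles
#' under the configured direction convention. Rigid mapping preserves
#' all intra-particle marker distances.
#'
#' @param object a \linkS4class{ParticleSet} (or a single-row particle
#'   data.frame).
#' @param offset numeric(3), Angstrom, reference frame.
#' @param mapDirection "inverse" (default) or "forward"; see
#'   [markerConfig()].
#' @return numeric matrix (n x 3) of tomogram-frame coordinates in
#'   Angstrom.
#' @export
mapMarkers <- function(object, offset,
                       mapDirection = c("inverse", "forward")) {
  mapDirection <- match.arg(mapDirection)
  p <- if (is(object, "ParticleSet")) particles(object) else object
  stopifnot(length(offset) == 3L, all(is.finite(offset)))
  out <- matrix(NA_real_, nrow(p), 3)
  for (i in seq_len(nrow(p))) {
    R <- eulerToRotation(p$rot[i], p$tilt[i], p$psi[i])
    A <- if (mapDirection == "inverse") t(R) else R
    out[i, ] <- c(p$x[i], p$y[i], p$z[i]) + as.numeric(A %*% offset)
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Export mapped entry/exit marker clouds for visual validation
#'
#' Writes the marker positions under both direction conventions as CSV
#' point clouds (and a simple marker STAR file per convention), so the
#' correct convention can be confirmed by overlaying on a tomogram or
#' map. Columns: particleID, tomoID, marker (entry/exit), convention,
#' x, y, z.
#'
#' @param pset a \linkS4class{ParticleSet}.
#' @param markers a \linkS4class{MarkerConfig}.
#' @param path output CSV path; a sibling \code{.star} file is written
#'   alongside for each convention.
#' @return invisibly, the data.frame written.
#' @export
exportMarkers <- function(pset, markers, path) {
  p <- particles(pset)
  res <- list()
  for (conv in c("inverse", "forward")) {
    for (mk in c("entry", "exit")) {
      off <- if (mk == "entry") markers@entryOffset else markers@exitOffset
      xyz <- mapMarkers(pset, off, conv)
      res[[paste(conv, mk)]] <- data.frame(
        particleID = p$particleID, tomoID = p$tomoID,
        marker = mk, convention = conv, xyz)
    }
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  utils::write.csv(out, path, row.names = FALSE)
  for (conv in c("inverse", "forward")) {
    sub <- out[out$convention == conv, ]
    df <- data.frame(rlnTomoName = sub$tomoID,
                     rlnCoordinateX = sub$x, rlnCoordinateY = sub$y,
                     rlnCoordinateZ = sub$z, rlnMarkerType = sub$marker)
    .writeStarTable(df, sub("\\.csv$", paste0("_", conv, ".star"), path))
  }
  invisible(out)
}
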