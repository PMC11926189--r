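# Minimal RELION STAR table I/O (single data block, loop_ format).
# Only particle metadata is handled; optics groups, CTF metadata and
# multi-block pipelines are out of scope.

.readStarTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\\s+", "", sub("\\s+$", "", lines))
  i <- which(grepl("^data_", lines))
  if (!length(i)) stop("no data block found in STAR file: ", path)
  j <- which(grepl("^loop_", lines))
  j <- j[j > i[1]]
  if (!length(j)) stop("no loop_ section found in STAR file: ", path)
  k <- j[1] + 1L
  cols <- character()
  while (k <= length(lines) && grepl("^_", lines[k])) {
    cols <- c(cols, sub("^_", "", sub("\\s*#.*$", "", lines[k])))
    k <- k + 1L
  }
  if (!length(cols)) stop("loop_ section has no column definitions: ", path)
  body <- lines[k:length(lines)]
  stop_at <- which(body == "" | grepl("^data_", body))
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  body <- body[nzchar(body) & !grepl("^#", body)]
  fields <- strsplit(body, "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("STAR row ", which(nf != length(cols))[1], " has ", nf[nf != length(cols)][1],
         " fields, expected ", length(cols))
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- cols
  for (nm in names(df)) {
    suppressWarnings(num <- as.numeric(df[[nm]]))
    if (!anyNA(num)) df[[nm]] <- num
  }
  df
}

.writeStarTable <- function(df, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  cols <- lapply(df, function(x) {
    if (is.numeric(x)) sprintf("%.6f", x) else as.character(x)
  })
  writeLines(do.call(paste, cols), con)
  writeLines("", con)
  invisible(path)
}

#' Read subtomogram particles from a RELION STAR file
#'
#' Parses a particle STAR table, converts coordinates to Angstrom and
#' assigns every particle a sequential unique identifier in file order
#' (0-based). Both origin-offset dialects are honoured: RELION 3.1
#' (\code{rlnOriginX/Y/Z}, pixels) and RELION >= 4
#' (\code{rlnOriginX/Y/ZAngst}, Angstrom). The refined position is
#' \code{coordinate * pixelSize - origin_in_Angstrom} (shift-corrected
#' convention; the raw-coordinate alternative is available via
#' \code{applyShifts = FALSE}). Euler angles are normalised to tilt in
#' [0, 180] and rot/psi in [-180, 180].
#'
#' @param path STAR file.
#' @param pixelSize numeric(1), Angstrom per pixel of the coordinates.
#' @param labelColumns character, names of categorical label columns to
#'   attach (STAR column names with or without the leading "rln"); each
#'   must exist in the table.
#' @param applyShifts subtract refined origin offsets if present
#'   (default TRUE).
#' @return a \linkS4class{ParticleSet}.
#' @export
readParticles <- function(path, pixelSize, labelColumns = character(),
                          applyShifts = TRUE) {
  stopifnot(is.numeric(pixelSize), pixelSize > 0)
  df <- .readStarTable(path)
  need <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
  for (nm in need) {
    if (!nm %in% names(df))
      stop("STAR file lacks required column: ", nm)
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop("non-numeric value in column ", nm, " at row ", bad)
    }
  }
  tomo <- if ("rlnTomoName" %in% names(df)) df$rlnTomoName
          else if ("rlnMicrographName" %in% names(df)) df$rlnMicrographName
          else "tomo_1"
  pos <- cbind(df$rlnCoordinateX, df$rlnCoordinateY,
               df$rlnCoordinateZ) * pixelSize
  if (applyShifts) {
    px <- c("rlnOriginX", "rlnOriginY", "rlnOriginZ")
    ang <- paste0(px, "Angst")
    if (all(ang %in% names(df))) {
      pos <- pos - cbind(df[[ang[1]]], df[[ang[2]]], df[[ang[3]]])
    } else if (all(px %in% names(df))) {
      pos <- pos - cbind(df[[px[1]]], df[[px[2]]], df[[px[3]]]) * pixelSize
    }
  }
  eul <- normalizeEuler(df$rlnAngleRot, df$rlnAngleTilt, df$rlnAnglePsi)
  p <- data.frame(particleID = seq_len(nrow(df)) - 1L,
                  tomoID = as.character(tomo),
                  x = pos[, 1], y = pos[, 2], z = pos[, 3],
                  rot = eul$rot, tilt = eul$tilt, psi = eul$psi,
                  stringsAsFactors = FALSE)
  labs <- character()
  for (lc in labelColumns) {
    starName <- if (lc %in% names(df)) lc else paste0("rln", lc)
    if (!starName %in% names(df))
      stop("requested label column not in STAR file: ", lc)
    short <- sub("^rln", "", lc)
    p[[short]] <- as.character(df[[starName]])
    labs <- c(labs, short)
  }
  new("ParticleSet", particles = p, pixelSize = pixelSize,
      labelColumns = labs, provenance = normalizePath(path))
}

#' Write particles (with optional polysome annotations) to STAR
#'
#' Writes the particle table back to a RELION-style STAR file,
#' coordinates in pixels at the set's pixel size, angles and label
#' columns preserved. If chain annotations are supplied, three columns
#' are appended: \code{rlnPolysomeID}, \code{rlnChainPosition} (0-based
#' position within the chain) and \code{rlnChainLength}; particles not
#' in any polysome get the sentinel (-1, -1, 1).
#'
#' @param pset a \linkS4class{ParticleSet}.
#' @param path output STAR path.
#' @param chains optional \linkS4class{PolysomeChainSet}; every member
#'   ID must exist in the set.
#' @return invisibly, the path written.
#' @export
writeParticles <- function(pset, path, chains = NULL) {
  p <- particles(pset)
  df <- data.frame(rlnTomoName = p$tomoID,
                   rlnCoordinateX = p$x / pixelSize(pset),
                   rlnCoordinateY = p$y / pixelSize(pset),
                   rlnCoordinateZ = p$z / pixelSize(pset),
                   rlnAngleRot = p$rot, rlnAngleTilt = p$tilt,
                   rlnAnglePsi = p$psi, stringsAsFactors = FALSE)
  for (lc in labelColumns(pset)) df[[paste0("rln", lc)]] <- p[[lc]]
  if (!is.null(chains)) {
    pid <- rep(-1L, nrow(p)); cpos <- rep(-1L, nrow(p))
    clen <- rep(1L, nrow(p))
    for (ci in seq_along(chainMembers(chains))) {
      mem <- chainMembers(chains)[[ci]]
      row <- match(mem, p$particleID)
      if (anyNA(row))
        stop("chain ", ci - 1L, " references unknown particleID: ",
             mem[which(is.na(row))[1]])
      pid[row] <- ci - 1L
      cpos[row] <- seq_along(mem) - 1L
      clen[row] <- length(mem)
    }
    df$rlnPolysomeID <- pid
    df$rlnChainPosition <- cpos
    df$rlnChainLength <- clen
  }
  .writeStarTable(df, path)
  invisible(path)
}
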