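#' Read a GRO file (single- or multi-frame)
#'
#' GRO coordinates are nanometres on disk and are converted to Angstrom on
#' read. Files written by \code{\link{writeGRO}} carry four decimals
#' (1e-4 nm), so coordinates round-trip to better than 1e-3 Angstrom.
#' Concatenated frames are read as a trajectory.
#'
#' @param path GRO file.
#' @return list with \code{atoms} (data.frame: name, resname, resid),
#'   \code{coords} (list of n x 3 matrices, Angstrom) and \code{box}
#'   (n_frames x 3, Angstrom).
#' @export
readGRO <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- as.integer(trimws(lines[i + 1L]))
    body <- lines[(i + 2L):(i + 1L + natoms)]
    resid <- as.integer(substr(body, 1L, 5L))
    resname <- trimws(substr(body, 6L, 10L))
    name <- trimws(substr(body, 11L, 15L))
    rest <- substr(body, 21L, nchar(body))
    xyz <- matrix(scan(text = rest, quiet = TRUE), nrow = natoms, byrow = TRUE)
    xyz <- xyz[, 1:3, drop = FALSE] * mtConstants$nm_to_A
    box <- scan(text = lines[i + 2L + natoms], quiet = TRUE)[1:3] *
      mtConstants$nm_to_A
    if (is.null(atoms))
      atoms <- data.frame(id = seq_len(natoms), name = name,
                          resname = resname, resid = resid,
                          chain = "X", stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- unname(xyz)
    boxes[[length(boxes) + 1L]] <- box
    i <- i + 3L + natoms
  }
  list(atoms = atoms, coords = frames,
       box = do.call(rbind, boxes))
}

#' Write a SystemTrajectory (or raw pieces) as a GRO file
#'
#' Coordinates are written in nm with four decimals so that a read/write
#' round trip preserves positions to 1e-3 Angstrom. Multiple frames are
#' concatenated, which \code{\link{readGRO}} understands.
#'
#' @param traj a SystemTrajectory.
#' @param path output file.
#' @param frames frame indices to write (default: all).
#' @return \code{path}, invisibly.
#' @export
writeGRO <- function(traj, path, frames = seq_len(nFrames(traj))) {
  at <- traj@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    xyz <- traj@coords[[f]] / mtConstants$nm_to_A
    writeLines(c("membraneTools system", sprintf("%5d", nrow(at))), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.4f%8.4f%8.4f",
                       at$resid %% 100000L, at$resname, at$name,
                       at$id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       traj@box[f, 1] / 10, traj@box[f, 2] / 10,
                       traj@box[f, 3] / 10), con)
  }
  invisible(path)
}

#' Write a SystemTrajectory as a (multi-model) PDB file
#'
#' Each frame becomes one MODEL record; the box is stored in CRYST1.
#'
#' @param traj a SystemTrajectory.
#' @param path output file.
#' @param frames frame indices to write (default: all).
#' @return \code{path}, invisibly.
#' @export
writeMultiPDB <- function(traj, path, frames = seq_len(nFrames(traj))) {
  at <- traj@atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj@box[1, 1], traj@box[1, 2], traj@box[1, 3],
                     90, 90, 90), con)
  for (f in frames) {
    xyz <- traj@coords[[f]]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      at$id %% 100000L, substr(at$name, 1, 4), substr(at$resname, 1, 4),
      substr(at$chain, 1, 1), at$resid %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file (single- or multi-model) via bio3d
#'
#' @param path PDB file.
#' @return list(atoms, coords, box) in the same shape as
#'   \code{\link{readGRO}}; the box comes from CRYST1 (Angstrom) or is NA.
#' @export
readPDB <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(id = seq_len(nrow(a)), name = a$elety,
                      resname = a$resid, resid = a$resno,
                      chain = ifelse(is.na(a$chain), "X", a$chain),
                      stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  coords <- lapply(seq_len(nf), function(f)
    matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE))
  box <- c(NA_real_, NA_real_, NA_real_)
  cr <- grep("^CRYST1", readLines(path, n = 50), value = TRUE)
  if (length(cr))
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
  list(atoms = atoms, coords = coords,
       box = matrix(rep(box, nf), ncol = 3, byrow = TRUE))
}

#' Read a DCD trajectory via bio3d
#'
#' @param path DCD file.
#' @param box fallback n_frames x 3 or numeric(3) box (Angstrom) when the
#'   DCD carries no unit cell.
#' @return list(coords, box); atom metadata must come from a topology.
#' @export
readDCD <- function(path, box = NULL) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  coords <- lapply(seq_len(nf), function(f)
    matrix(xyz[f, ], ncol = 3, byrow = TRUE))
  if (is.null(box)) stop("DCD carries no readable unit cell; supply `box`")
  if (is.null(dim(box))) box <- matrix(rep(box, nf), ncol = 3, byrow = TRUE)
  list(coords = coords, box = box)
}
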