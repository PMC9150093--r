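AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
            "SER", "THR", "TRP", "TYR", "VAL")
SOLVENT <- c("SOL", "WAT", "HOH", "TIP3", "TIP4", "SPC", "NA", "CL", "K",
             "NA+", "CL-", "POT", "CLA", "SOD", "MG", "CA2", "CAL")

#' Build a SystemTrajectory from in-memory pieces
#'
#' @param atoms atom data.frame (id, name, resname, resid, chain; optional
#'   element, radius, charge). A missing element column is guessed from
#'   atom names.
#' @param coords list of n_atoms x 3 matrices (Angstrom), or one matrix.
#' @param box numeric(3) or n_frames x 3 matrix (Angstrom).
#' @param selections named list of integer atom-index vectors.
#' @param metadata free-form list.
#' @return a \linkS4class{SystemTrajectory}.
#' @export
systemTrajectory <- function(atoms, coords, box, selections = list(),
                             metadata = list()) {
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) unname(as.matrix(m)))
  if (is.null(dim(box)))
    box <- matrix(rep(as.numeric(box), length(coords)), ncol = 3, byrow = TRUE)
  if (!"element" %in% names(atoms))
    atoms$element <- guessElement(atoms$name)
  new("SystemTrajectory", atoms = atoms, coords = coords, box = box,
      selections = selections, metadata = metadata)
}

#' Load a topology + trajectory into a SystemTrajectory
#'
#' Reads a GRO or PDB topology, optionally replaces its coordinates with a
#' trajectory (multi-frame GRO, multi-model PDB, or DCD), and classifies
#' every residue: residues named in \code{lipidDefs} populate the
#' "membrane" selection and one selection per lipid type; standard amino
#' acid residues populate "protein"; water and ions are dropped (count kept
#' in metadata); anything else is dropped and reported in
#' \code{metadata$rejected}.
#'
#' @param topologyPath GRO or PDB file.
#' @param trajectoryPath optional trajectory (GRO/PDB/DCD). Atom counts
#'   must match the topology.
#' @param lipidDefs named list of \code{\link{lipidDefinition}} objects
#'   (default \code{\link{defaultLipidDefinitions}()}).
#' @param box fallback box lengths (Angstrom) for formats without one.
#' @return a \linkS4class{SystemTrajectory}.
#' @export
loadSystem <- function(topologyPath, trajectoryPath = NULL,
                       lipidDefs = defaultLipidDefinitions(), box = NULL) {
  if (!file.exists(topologyPath)) stop("topology not found: ", topologyPath)
  ext <- tolower(tools::file_ext(topologyPath))
  top <- switch(ext,
    gro = readGRO(topologyPath),
    pdb = readPDB(topologyPath),
    stop("unsupported topology format: .", ext))
  coords <- top$coords
  boxm <- top$box
  if (!is.null(trajectoryPath)) {
    if (!file.exists(trajectoryPath))
      stop("trajectory not found: ", trajectoryPath)
    text <- tolower(tools::file_ext(trajectoryPath))
    trj <- switch(text,
      gro = readGRO(trajectoryPath),
      pdb = readPDB(trajectoryPath),
      dcd = readDCD(trajectoryPath,
                    box = if (all(is.finite(top$box[1, ]))) top$box[1, ]
                          else box),
      stop("unsupported trajectory format: .", text))
    ntraj <- nrow(trj$coords[[1]])
    if (ntraj != nrow(top$atoms))
      stop(sprintf("atom-count mismatch: topology has %d, trajectory has %d",
                   nrow(top$atoms), ntraj))
    coords <- trj$coords
    boxm <- trj$box
  }
  if (any(!is.finite(boxm))) {
    if (is.null(box)) stop("no box in input; supply `box`")
    boxm <- matrix(rep(as.numeric(box), length(coords)), ncol = 3,
                   byrow = TRUE)
  }
  classifyResidues(top$atoms, coords, boxm, lipidDefs)
}

# Residue classification shared by loadSystem and the synthetic generator:
# lipid types from the definitions, polypeptide -> "protein", solvent/ions
# dropped with a logged count, anything else dropped and reported.
classifyResidues <- function(atoms, coords, boxm, lipidDefs) {
  lipnames <- names(lipidDefs)
  is_lip <- atoms$resname %in% lipnames
  is_prot <- atoms$resname %in% AMINO3
  is_solv <- toupper(atoms$resname) %in% SOLVENT
  rejected <- unique(atoms$resname[!(is_lip | is_prot | is_solv)])
  keep <- which(is_lip | is_prot)
  n_dropped_solvent <- length(unique(paste(atoms$resid,
                                           atoms$resname)[is_solv]))
  if (length(rejected))
    warning("dropping unrecognized residue type(s): ",
            paste(rejected, collapse = ", "))
  atoms2 <- atoms[keep, , drop = FALSE]
  atoms2$id <- seq_len(nrow(atoms2))
  rownames(atoms2) <- NULL
  coords2 <- lapply(coords, function(m) m[keep, , drop = FALSE])
  sel <- list(membrane = which(atoms2$resname %in% lipnames))
  if (length(sel$membrane) == 0L) stop("empty membrane selection")
  prot <- which(atoms2$resname %in% AMINO3)
  if (length(prot)) sel$protein <- prot
  for (ln in lipnames) {
    idx <- which(atoms2$resname == ln)
    if (length(idx)) sel[[ln]] <- idx
  }
  systemTrajectory(atoms2, coords2, boxm, selections = sel,
                   metadata = list(n_dropped_solvent = n_dropped_solvent,
                                   rejected = rejected))
}

#' Membrane centre along z
#'
#' z = 0 of the membrane frame is placed at the centre of the membrane.
#' The default is the unweighted mean z over membrane atoms; mass weighting
#' and a head-atom (P) variant are available.
#'
#' @param traj a SystemTrajectory.
#' @param frame frame index.
#' @param sel atom indices (default: the "membrane" selection).
#' @param weighting "none" (default) or "mass".
#' @return z0 in Angstrom.
#' @export
membraneCenter <- function(traj, frame = 1L,
                           sel = selection(traj, "membrane"),
                           weighting = c("none", "mass")) {
  weighting <- match.arg(weighting)
  if (length(sel) == 0L) stop("empty selection")
  z <- frameCoords(traj, frame)[sel, 3]
  if (weighting == "none") return(mean(z))
  m <- mtMasses[atoms(traj)$element[sel]]
  m[is.na(m)] <- mtMasses["C"]
  sum(m * z) / sum(m)
}

#' Assign membrane lipids to leaflets
#'
#' A lipid belongs to the upper leaflet iff the z coordinate of its head
#' atom is >= the membrane centre z0 (ties go to the upper leaflet, a
#' deterministic convention).
#'
#' @param traj a SystemTrajectory.
#' @param frame frame index.
#' @param lipidDefs lipid definitions resolving the head atom per type.
#' @param z0 membrane centre; computed with \code{\link{membraneCenter}}
#'   when missing.
#' @return data.frame (frame, resid, resname, leaflet, head_z) with
#'   attribute \code{z0}.
#' @export
assignLeaflets <- function(traj, frame = 1L,
                           lipidDefs = defaultLipidDefinitions(),
                           z0 = membraneCenter(traj, frame)) {
  at <- atoms(traj)
  xyz <- frameCoords(traj, frame)
  mem <- selection(traj, "membrane")
  memat <- at[mem, ]
  keys <- unique(paste(memat$resid, memat$resname))
  parts <- strsplit(keys, " ")
  resid <- as.integer(vapply(parts, `[`, "", 1L))
  resname <- vapply(parts, function(p) paste(p[-1], collapse = " "), "")
  head_z <- vapply(seq_along(keys), function(i) {
    def <- lipidDefs[[resname[i]]]
    if (is.null(def)) stop("no lipid definition for ", resname[i])
    idx <- mem[memat$resid == resid[i] & memat$name == def$headAtom]
    if (length(idx) != 1L)
      stop(sprintf("lipid %s %d: expected exactly one head atom '%s', got %d",
                   resname[i], resid[i], def$headAtom, length(idx)))
    xyz[idx, 3]
  }, numeric(1))
  out <- data.frame(frame = frame, resid = resid, resname = resname,
                    leaflet = ifelse(head_z >= z0, "upper", "lower"),
                    head_z = head_z, stringsAsFactors = FALSE)
  attr(out, "z0") <- z0
  out
}

#' Radius of gyration of a selection
#'
#' Mass-weighted Rg about the selection's centre of mass.
#'
#' @param traj a SystemTrajectory.
#' @param sel atom indices.
#' @param frame frame index.
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(traj, sel, frame = 1L) {
  if (length(sel) == 0L) stop("empty selection")
  xyz <- frameCoords(traj, frame)[sel, , drop = FALSE]
  m <- mtMasses[atoms(traj)$element[sel]]
  m[is.na(m)] <- mtMasses["C"]
  com <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Unwrap lateral Brownian tracks across periodic boundaries
#'
#' Removes box jumps (|step| > box/2) from per-particle lateral tracks so
#' mean-square displacements can be computed on continuous coordinates.
#'
#' @param pos array (n_frames, n_particles, 2) of wrapped positions.
#' @param box numeric(2) lateral box lengths.
#' @return array of the same shape, unwrapped.
#' @export
unwrapLateral <- function(pos, box) {
  for (k in 1:2) {
    x <- pos[, , k, drop = FALSE]
    dx <- x[-1, , 1, drop = FALSE] - x[-dim(x)[1], , 1, drop = FALSE]
    shift <- -round(dx / box[k]) * box[k]
    cum <- apply(shift, 2, cumsum)
    pos[-1, , k] <- pos[-1, , k] + cum
  }
  pos
}

#' Write leaflet assignments as CSV
#' @param assignments data.frame from \code{\link{assignLeaflets}} (rows of
#'   several frames may be concatenated).
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeLeafletCSV <- function(assignments, path) {
  utils::write.csv(assignments[, c("frame", "resid", "resname", "leaflet")],
                   path, row.names = FALSE)
  invisible(path)
}
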