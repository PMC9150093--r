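#' Number of frames in a trajectory
#' @param x a SystemTrajectory
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "SystemTrajectory", function(x) length(x@coords))

#' Number of atoms
#' @param x a SystemTrajectory
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SystemTrajectory", function(x) nrow(x@atoms))

#' Atom table accessor
#' @param x a SystemTrajectory
#' @return the atom data.frame
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "SystemTrajectory", function(x) x@atoms)

#' Coordinates of one frame
#' @param x a SystemTrajectory
#' @param frame frame index (1-based)
#' @return n_atoms x 3 matrix, Angstrom
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "SystemTrajectory", function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= length(x@coords))
  x@coords[[frame]]
})

#' Box lengths of one frame
#' @param x a SystemTrajectory
#' @param frame frame index
#' @return numeric(3), Angstrom
#' @export
setGeneric("boxLengths", function(x, frame = 1L) standardGeneric("boxLengths"))

#' @rdname boxLengths
#' @export
setMethod("boxLengths", "SystemTrajectory", function(x, frame = 1L)
  as.numeric(x@box[frame, ]))

#' Named atom selection accessor
#' @param x a SystemTrajectory
#' @param name selection name; omit to list available names
#' @return integer atom indices, or character names when \code{name} missing
#' @export
setGeneric("selection", function(x, name) standardGeneric("selection"))

#' @rdname selection
#' @export
setMethod("selection", "SystemTrajectory", function(x, name) {
  if (missing(name)) return(names(x@selections))
  if (!name %in% names(x@selections))
    stop("no selection named '", name, "'")
  x@selections[[name]]
})

#' Map values accessor
#' @param x a GridMap or OccupancyGrid
#' @return the value matrix / occupancy array
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "GridMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "OccupancyGrid", function(x) x@occupied)

#' Crack summary table accessor
#' @param x a CrackSet
#' @return data.frame of per-crack statistics
#' @export
setGeneric("crackTable", function(x) standardGeneric("crackTable"))

#' @rdname crackTable
#' @export
setMethod("crackTable", "CrackSet", function(x) x@cracks)

setMethod("show", "SystemTrajectory", function(object) {
  cat("SystemTrajectory:", nrow(object@atoms), "atoms,",
      length(object@coords), "frame(s)\n")
  cat("  box (frame 1):",
      paste(sprintf("%.2f", object@box[1, ]), collapse = " x "), "A\n")
  sel <- vapply(object@selections, length, integer(1))
  if (length(sel))
    cat("  selections:",
        paste(sprintf("%s(%d)", names(sel), sel), collapse = ", "), "\n")
})

setMethod("show", "GridMap", function(object) {
  cat(sprintf("GridMap [%s]: %d x %d bins of %.2f A, %g frame(s)\n",
              object@kind, nrow(object@values), ncol(object@values),
              object@binSize, object@frames))
  cat(sprintf("  value range: %.3f .. %.3f\n",
              min(object@values), max(object@values)))
})

setMethod("show", "OccupancyGrid", function(object) {
  d <- dim(object@occupied)
  cat(sprintf("OccupancyGrid: %d x %d x %d voxels of %.2f A, %.1f%% occupied\n",
              d[1], d[2], d[3], object@voxel, 100 * mean(object@occupied)))
})

setMethod("show", "CrackSet", function(object) {
  cat("CrackSet:", nrow(object@cracks), "crack(s)\n")
  if (nrow(object@cracks)) {
    cat(sprintf("  deepest: %.2f A%s\n", max(object@cracks$depth),
                if (any(object@cracks$channel)) " (contains channel)" else ""))
  }
})
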