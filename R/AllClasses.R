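#' @import methods
NULL

#' SystemTrajectory: atoms, frames and named selections
#'
#' The central container of the package: a static atom table, per-frame
#' coordinates with orthorhombic box lengths, and named atom-index
#' selections ("membrane", "protein", and one per lipid type). The membrane
#' normal is assumed to be the box z axis throughout; coordinates are
#' Angstrom.
#'
#' @slot atoms data.frame with columns \code{id}, \code{name},
#'   \code{resname}, \code{resid}, \code{chain}, \code{element}, and
#'   optionally \code{radius} (vdW, Angstrom) and \code{charge} (e).
#' @slot coords list of n_atoms x 3 numeric matrices, one per frame.
#' @slot box n_frames x 3 matrix of box lengths (Angstrom).
#' @slot selections named list of integer vectors indexing \code{atoms}.
#' @slot metadata free-form list (e.g. ground truth planted by the
#'   synthetic generators, counts of dropped solvent residues).
#'
#' @export
setClass("SystemTrajectory",
  representation(atoms = "data.frame", coords = "list", box = "matrix",
                 selections = "list", metadata = "list"),
  prototype(metadata = list()))

setValidity("SystemTrajectory", function(object) {
  msg <- character()
  na <- nrow(object@atoms)
  if (length(object@coords) == 0L) msg <- c(msg, "no frames")
  dims_ok <- vapply(object@coords, function(m)
    is.matrix(m) && nrow(m) == na && ncol(m) == 3L, logical(1))
  if (!all(dims_ok))
    msg <- c(msg, "every frame must be an n_atoms x 3 matrix")
  if (nrow(object@box) != length(object@coords) || ncol(object@box) != 3L)
    msg <- c(msg, "box must be n_frames x 3")
  if (any(object@box <= 0)) msg <- c(msg, "box lengths must be > 0")
  bad_sel <- vapply(object@selections, function(i)
    length(i) > 0 && (min(i) < 1L || max(i) > na), logical(1))
  if (any(bad_sel))
    msg <- c(msg, sprintf("selection '%s' indexes atoms that do not exist",
                          names(object@selections)[bad_sel][1]))
  if (length(msg)) msg else TRUE
})

#' GridMap: a 2D lateral map over the membrane plane
#'
#' Holds a density (counts/Angstrom^2), thickness (Angstrom) or crack-depth
#' (Angstrom) field on a regular x-y grid.
#'
#' @slot origin numeric(2), lower-left corner (x, y) in Angstrom.
#' @slot binSize numeric(1), lateral bin edge length (Angstrom).
#' @slot values n_x x n_y numeric matrix.
#' @slot kind one of "density", "thickness", "crack_depth".
#' @slot frames number of frames accumulated.
#' @slot interpolated logical matrix flagging cells filled by
#'   nearest-neighbour interpolation (thickness maps only), or 0-row matrix.
#'
#' @export
setClass("GridMap",
  representation(origin = "numeric", binSize = "numeric", values = "matrix",
                 kind = "character", frames = "numeric",
                 interpolated = "matrix"),
  prototype(kind = "density", frames = 1,
            interpolated = matrix(logical(0), 0, 0)))

setValidity("GridMap", function(object) {
  msg <- character()
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be length 2")
  if (object@binSize <= 0) msg <- c(msg, "binSize must be > 0")
  if (!object@kind %in% c("density", "thickness", "crack_depth"))
    msg <- c(msg, "unknown map kind")
  if (nrow(object@interpolated) > 0 &&
      !identical(dim(object@interpolated), dim(object@values)))
    msg <- c(msg, "interpolated flags must match value dimensions")
  if (length(msg)) msg else TRUE
})

#' OccupancyGrid: vdW-sphere occupancy between the bilayer surfaces
#'
#' Voxelised occupancy of the slab between the two leaflet surfaces: a
#' voxel is occupied iff its centre lies within the van der Waals radius of
#' at least one membrane atom. The complement is the empty space searched
#' for surface cracks.
#'
#' @slot occupied 3D logical array (nx, ny, nz).
#' @slot voxel voxel edge length, Angstrom.
#' @slot origin numeric(3): coordinates of the centre of voxel (1,1,1).
#' @slot zBounds numeric(2): z of the bottom and top bilayer surfaces.
#' @slot box numeric(2): lateral box lengths used for minimum image.
#'
#' @export
setClass("OccupancyGrid",
  representation(occupied = "array", voxel = "numeric", origin = "numeric",
                 zBounds = "numeric", box = "numeric"))

setValidity("OccupancyGrid", function(object) {
  msg <- character()
  if (length(dim(object@occupied)) != 3L)
    msg <- c(msg, "occupancy must be a 3D array")
  if (object@voxel <= 0) msg <- c(msg, "voxel size must be > 0")
  if (diff(object@zBounds) <= 0)
    msg <- c(msg, "zBounds must be increasing (bottom, top)")
  if (length(msg)) msg else TRUE
})

#' CrackSet: connected empty-space components open to the top surface
#'
#' @slot cracks data.frame with one row per crack: \code{id},
#'   \code{depth} (Angstrom, distance from the top surface to the crack
#'   bottom), \code{footprint} (lateral area, Angstrom^2), \code{n_voxels},
#'   \code{channel} (logical: reaches the bottom surface).
#' @slot voxels list of integer matrices (n x 3 voxel indices) per crack.
#' @slot gridDim integer(3) dimensions of the parent grid.
#' @slot voxel voxel size of the parent grid (Angstrom).
#' @slot zBounds z range of the parent grid.
#'
#' @export
setClass("CrackSet",
  representation(cracks = "data.frame", voxels = "list",
                 gridDim = "integer", voxel = "numeric", zBounds = "numeric"))

setValidity("CrackSet", function(object) {
  msg <- character()
  if (nrow(object@cracks) != length(object@voxels))
    msg <- c(msg, "one voxel set per crack row required")
  thick <- diff(object@zBounds)
  if (nrow(object@cracks) &&
      (any(object@cracks$depth <= 0) ||
       any(object@cracks$depth > thick + object@voxel)))
    msg <- c(msg, "crack depths must lie in (0, slab thickness]")
  if (length(msg)) msg else TRUE
})
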