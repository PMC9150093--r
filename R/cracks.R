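#' Build the vdW occupancy grid between the bilayer surfaces
#'
#' The slab between the two leaflet surfaces is voxelised; a voxel is
#' occupied iff its centre lies within the van der Waals radius of at
#' least one membrane atom (spheres rasterised with lateral minimum
#' image). The complement of the occupancy is the empty space searched
#' for surface cracks.
#'
#' @param traj a SystemTrajectory.
#' @param frame frame index.
#' @param sel membrane atom indices.
#' @param voxel voxel edge length, Angstrom (must be <= 2 for adequate
#'   resolution).
#' @param zBounds numeric(2) z of the bottom and top surfaces; defaults to
#'   \code{metadata$zBounds} or, failing that, the leaflet head-atom mean
#'   z values.
#' @param radii per-atom vdW radii; defaults to the atom table's
#'   \code{radius} column, else the element table \code{\link{mtVdwRadii}}.
#' @return an \linkS4class{OccupancyGrid}.
#' @export
buildOccupancy <- function(traj, frame = 1L,
                           sel = selection(traj, "membrane"),
                           voxel = 1.0, zBounds = NULL, radii = NULL) {
  if (voxel > 2) stop("voxel size must be <= 2 Angstrom")
  if (length(sel) == 0L) stop("empty membrane selection")
  if (is.null(zBounds)) {
    zBounds <- traj@metadata$zBounds
    if (is.null(zBounds)) {
      la <- assignLeaflets(traj, frame)
      zBounds <- c(mean(la$head_z[la$leaflet == "lower"]),
                   mean(la$head_z[la$leaflet == "upper"]))
    }
  }
  at <- atoms(traj)
  if (is.null(radii)) {
    radii <- if ("radius" %in% names(at)) at$radius[sel]
             else unname(mtVdwRadii[at$element[sel]])
    radii[is.na(radii)] <- 1.7
  }
  b <- boxLengths(traj, frame)
  xyz <- frameCoords(traj, frame)[sel, , drop = FALSE]
  nx <- max(1L, round(b[1] / voxel)); ny <- max(1L, round(b[2] / voxel))
  hx <- b[1] / nx; hy <- b[2] / ny
  nz <- max(1L, floor((zBounds[2] - zBounds[1]) / voxel))
  occ <- array(FALSE, c(nx, ny, nz))
  cx <- (seq_len(nx) - 0.5) * hx
  cy <- (seq_len(ny) - 0.5) * hy
  cz <- zBounds[1] + (seq_len(nz) - 0.5) * voxel
  wx <- wrapCoord(xyz[, 1], b[1]); wy <- wrapCoord(xyz[, 2], b[2])
  for (i in seq_along(radii)) {
    r <- radii[i]
    kx0 <- floor((wx[i] - r) / hx); kx1 <- ceiling((wx[i] + r) / hx)
    ky0 <- floor((wy[i] - r) / hy); ky1 <- ceiling((wy[i] + r) / hy)
    ixs <- unique(((kx0:kx1) %% nx) + 1L)
    iys <- unique(((ky0:ky1) %% ny) + 1L)
    izs <- which(abs(cz - xyz[i, 3]) <= r)
    if (length(izs) == 0L) next
    dx <- cx[ixs] - wx[i]; dx <- dx - round(dx / b[1]) * b[1]
    dy <- cy[iys] - wy[i]; dy <- dy - round(dy / b[2]) * b[2]
    dz <- cz[izs] - xyz[i, 3]
    hit <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= r^2
    if (any(hit)) {
      blk <- occ[ixs, iys, izs, drop = FALSE]
      occ[ixs, iys, izs] <- blk | hit
    }
  }
  new("OccupancyGrid", occupied = occ, voxel = voxel,
      origin = c(hx / 2, hy / 2, zBounds[1] + voxel / 2),
      zBounds = as.numeric(zBounds), box = b[1:2])
}

# 6-connected adjacency edges among empty voxels, periodic in x and y.
emptyVoxelGraph <- function(occ) {
  d <- dim(occ)
  empty <- which(!occ)
  if (length(empty) == 0L) return(NULL)
  id <- array(0L, d)
  id[empty] <- seq_along(empty)
  edges <- list()
  addEdges <- function(a, b) {
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <<- rbind(a[keep], b[keep])
  }
  # +x neighbour with wrap
  addEdges(id, id[c(2:d[1], 1L), , , drop = FALSE])
  # +y neighbour with wrap
  addEdges(id, id[, c(2:d[2], 1L), , drop = FALSE])
  # +z neighbour, non-periodic
  if (d[3] > 1L)
    addEdges(id[, , 1:(d[3] - 1L), drop = FALSE],
             id[, , 2:d[3], drop = FALSE])
  list(empty = empty, edges = if (length(edges))
    do.call(cbind, edges) else matrix(integer(), 2, 0))
}

#' Detect surface cracks in an occupancy grid
#'
#' Connected components (6-connectivity, lateral connectivity periodic)
#' of the empty voxels. A crack is a component containing at least one
#' voxel in the top surface layer; its depth is the distance from the top
#' surface to the bottom of its lowest voxel. Components touching both
#' surfaces are flagged as channels. Internal cavities that do not open
#' to the top surface are not reported.
#'
#' @param grid an \linkS4class{OccupancyGrid}.
#' @return a \linkS4class{CrackSet}.
#' @export
detectCracks <- function(grid) {
  occ <- grid@occupied
  d <- dim(occ)
  g <- emptyVoxelGraph(occ)
  emptyRows <- data.frame(id = integer(), depth = numeric(),
                          footprint = numeric(), n_voxels = integer(),
                          channel = logical())
  if (is.null(g))
    return(new("CrackSet", cracks = emptyRows, voxels = list(),
               gridDim = d, voxel = grid@voxel, zBounds = grid@zBounds))
  gr <- igraph::make_graph(edges = as.vector(g$edges), directed = FALSE,
                           n = length(g$empty))
  comp <- igraph::components(gr)$membership
  vox <- arrayInd(g$empty, d)
  rows <- list(); voxlist <- list(); cid <- 0L
  for (cc in seq_len(max(comp))) {
    m <- comp == cc
    vz <- vox[m, 3]
    if (!any(vz == d[3])) next  # not open to the top surface
    cid <- cid + 1L
    # centre of the lowest voxel: unbiased location of the crack bottom
    zmin <- grid@zBounds[1] + (min(vz) - 0.5) * grid@voxel
    depth <- grid@zBounds[2] - zmin
    lat <- unique(vox[m, 1:2, drop = FALSE])
    rows[[cid]] <- data.frame(
      id = cid, depth = depth,
      footprint = nrow(lat) * grid@voxel^2,
      n_voxels = sum(m), channel = any(vz == 1L))
    voxlist[[cid]] <- vox[m, , drop = FALSE]
  }
  cracks <- if (cid) do.call(rbind, rows) else emptyRows
  new("CrackSet", cracks = cracks, voxels = voxlist, gridDim = d,
      voxel = grid@voxel, zBounds = grid@zBounds)
}

#' Lateral map of maximum crack depth
#'
#' Per lateral cell, the depth of the deepest crack voxel column beneath
#' it (0 where no crack opens). Cell geometry matches the occupancy grid.
#'
#' @param crackSet a \linkS4class{CrackSet}.
#' @return a \linkS4class{GridMap} of kind "crack_depth" (Angstrom).
#' @export
crackDepthMap <- function(crackSet) {
  d <- crackSet@gridDim
  vals <- matrix(0, d[1], d[2])
  for (k in seq_along(crackSet@voxels)) {
    vox <- crackSet@voxels[[k]]
    zmin <- tapply(vox[, 3], list(factor(vox[, 1], levels = seq_len(d[1])),
                                  factor(vox[, 2], levels = seq_len(d[2]))),
                   min)
    has <- !is.na(zmin)
    depth <- matrix(0, d[1], d[2])
    depth[has] <- crackSet@zBounds[2] -
      (crackSet@zBounds[1] + (zmin[has] - 0.5) * crackSet@voxel)
    vals <- pmax(vals, depth)
  }
  new("GridMap", origin = c(0, 0), binSize = crackSet@voxel, values = vals,
      kind = "crack_depth", frames = 1)
}

#' Summarise a CrackSet as a per-crack CSV
#' @param crackSet a CrackSet.
#' @param path output CSV.
#' @param frame frame label written into the first column.
#' @return \code{path}, invisibly.
#' @export
writeCrackCSV <- function(crackSet, path, frame = 1L) {
  tab <- crackTable(crackSet)
  out <- cbind(frame = rep(frame, nrow(tab)), tab)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
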