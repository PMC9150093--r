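# Wrap lateral coordinates into [0, L).
wrapCoord <- function(x, L) x - floor(x / L) * L

# Bin index in 1..n for coordinates wrapped into [0, L).
binIndex <- function(x, L, n) pmin(pmax(1L, ceiling(wrapCoord(x, L) / (L / n))), n)

#' Lateral density map of lipid anchors
#'
#' Time-averaged 2D histogram of anchor-atom (x, y) positions over the
#' membrane plane, normalised per frame and bin area, so that
#' sum(density) * bin_area = anchors per frame.
#'
#' @param traj a SystemTrajectory.
#' @param anchors integer atom indices to histogram (e.g. the P atoms of
#'   one lipid type); see \code{\link{anchorSelection}}.
#' @param frames frame indices.
#' @param bins number of bins per lateral axis.
#' @return a \linkS4class{GridMap} of kind "density" (counts/Angstrom^2).
#' @export
densityMap <- function(traj, anchors, frames = seq_len(nFrames(traj)),
                       bins = 48L) {
  if (length(anchors) == 0L) stop("empty anchor selection")
  b <- boxLengths(traj, frames[1])
  counts <- matrix(0, bins, bins)
  for (f in frames) {
    xyz <- frameCoords(traj, f)[anchors, , drop = FALSE]
    ix <- binIndex(xyz[, 1], b[1], bins)
    iy <- binIndex(xyz[, 2], b[2], bins)
    tab <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
    counts <- counts + unclass(tab)
  }
  binArea <- (b[1] / bins) * (b[2] / bins)
  new("GridMap", origin = c(0, 0), binSize = b[1] / bins,
      values = counts / (length(frames) * binArea), kind = "density",
      frames = length(frames))
}

#' Anchor atom indices of one lipid type
#'
#' The density anchor is the head (P) atom for phospholipids and O3 (or
#' the first defined atom) for cholesterol; configurable per lipid
#' definition.
#'
#' @param traj a SystemTrajectory.
#' @param resname lipid type.
#' @param lipidDefs lipid definitions.
#' @return integer atom indices.
#' @export
anchorSelection <- function(traj, resname,
                            lipidDefs = defaultLipidDefinitions()) {
  def <- lipidDefs[[resname]]
  if (is.null(def)) stop("no lipid definition for ", resname)
  at <- atoms(traj)
  which(at$resname == resname & at$name == def$densityAnchor)
}

#' Membrane thickness map from phosphorus sheets
#'
#' Per lateral cell, thickness = mean z of upper-leaflet head atoms minus
#' mean z of lower-leaflet head atoms, accumulated over frames. Cells that
#' never receive atoms from both leaflets are filled from the nearest
#' populated cell and flagged in the \code{interpolated} slot.
#'
#' @param traj a SystemTrajectory.
#' @param lipidDefs lipid definitions (head atoms define the sheets).
#' @param frames frame indices.
#' @param bins bins per lateral axis.
#' @return a \linkS4class{GridMap} of kind "thickness" (Angstrom).
#' @export
thicknessMap <- function(traj, lipidDefs = defaultLipidDefinitions(),
                         frames = seq_len(nFrames(traj)), bins = 48L) {
  b <- boxLengths(traj, frames[1])
  sumU <- matrix(0, bins, bins); nU <- matrix(0, bins, bins)
  sumL <- matrix(0, bins, bins); nL <- matrix(0, bins, bins)
  for (f in frames) {
    la <- assignLeaflets(traj, f, lipidDefs)
    at <- atoms(traj)
    xyz <- frameCoords(traj, f)
    heads <- unlist(lapply(lipidDefs, function(def)
      which(at$resname == def$resname & at$name == def$headAtom)))
    if (length(heads) == 0L) stop("no head atoms found")
    leaf <- la$leaflet[match(at$resid[heads], la$resid)]
    if (!any(leaf == "upper") || !any(leaf == "lower"))
      stop("a leaflet has zero head atoms")
    ix <- binIndex(xyz[heads, 1], b[1], bins)
    iy <- binIndex(xyz[heads, 2], b[2], bins)
    for (side in c("upper", "lower")) {
      s <- leaf == side
      acc <- tapply(xyz[heads[s], 3], list(factor(ix[s], levels = 1:bins),
                                           factor(iy[s], levels = 1:bins)),
                    sum)
      cnt <- table(factor(ix[s], levels = 1:bins),
                   factor(iy[s], levels = 1:bins))
      acc[is.na(acc)] <- 0
      if (side == "upper") { sumU <- sumU + acc; nU <- nU + unclass(cnt) }
      else { sumL <- sumL + acc; nL <- nL + unclass(cnt) }
    }
  }
  ok <- nU > 0 & nL > 0
  vals <- matrix(NA_real_, bins, bins)
  vals[ok] <- sumU[ok] / nU[ok] - sumL[ok] / nL[ok]
  interp <- !ok
  if (any(interp) && any(ok)) {
    okIdx <- which(ok, arr.ind = TRUE)
    for (cell in which(interp)) {
      ij <- arrayInd(cell, dim(vals))
      # nearest populated cell on the periodic lattice
      di <- abs(okIdx[, 1] - ij[1]); di <- pmin(di, bins - di)
      dj <- abs(okIdx[, 2] - ij[2]); dj <- pmin(dj, bins - dj)
      nb <- which.min(di^2 + dj^2)
      vals[cell] <- vals[okIdx[nb, 1], okIdx[nb, 2]]
    }
  }
  new("GridMap", origin = c(0, 0), binSize = b[1] / bins, values = vals,
      kind = "thickness", frames = length(frames), interpolated = interp)
}

#' Radial distribution function of lateral (or 3D) positions
#'
#' Pair-distance histogram under the minimum-image convention, normalised
#' by the ideal-gas expectation: annulus area 2 pi r dr times the surface
#' density (N-1)/A in lateral mode, spherical shell 4 pi r^2 dr times
#' (N-1)/V in 3D mode. For a homogeneous system g(r) tends to 1 at large r.
#'
#' @param positions n x 2 (lateral) or n x 3 matrix, or a list of such
#'   matrices (one per frame).
#' @param box box lengths matching the mode.
#' @param mode "lateral" or "3d".
#' @param rMax histogram range; must be at most half the smallest box edge.
#' @param dr bin width, Angstrom.
#' @return data.frame (r, g) with attribute \code{mode}.
#' @export
radialDistribution <- function(positions, box, mode = c("lateral", "3d"),
                               rMax = NULL, dr = 0.2) {
  mode <- match.arg(mode)
  if (is.matrix(positions)) positions <- list(positions)
  ndim <- if (mode == "lateral") 2L else 3L
  box <- box[1:ndim]
  if (is.null(rMax)) rMax <- min(box) / 2
  if (rMax > min(box) / 2 + 1e-9)
    stop("rMax exceeds half the smallest box edge")
  n <- nrow(positions[[1]])
  if (n < 2L) stop("need at least 2 particles")
  edges <- seq(0, rMax, by = dr)
  if (edges[length(edges)] < rMax) edges <- c(edges, rMax)
  counts <- numeric(length(edges) - 1L)
  blk <- 400L
  for (pts in positions) {
    for (i0 in seq(1L, n - 1L, by = blk)) {
      i1 <- min(i0 + blk - 1L, n - 1L)
      rows <- i0:i1
      d2 <- matrix(0, length(rows), n)
      for (k in seq_len(ndim)) {
        dk <- outer(pts[rows, k], pts[, k], `-`)
        dk <- dk - round(dk / box[k]) * box[k]
        d2 <- d2 + dk^2
      }
      tri <- outer(rows, seq_len(n), `<`)
      d <- sqrt(d2[tri])
      d <- d[d <= rMax]
      if (length(d))
        counts <- counts + graphics::hist(d, breaks = edges,
                                          plot = FALSE)$counts
    }
  }
  nfr <- length(positions)
  vol <- prod(box)
  rho <- (n - 1) / vol
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- if (mode == "lateral")
    pi * (edges[-1]^2 - edges[-length(edges)]^2)
  else 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  expected <- nfr * n / 2 * rho * shell
  out <- data.frame(r = mid, g = counts / expected)
  attr(out, "mode") <- mode
  out
}

#' Write a GridMap as a CSV matrix
#' @param map a GridMap.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeGridMapCSV <- function(map, path) {
  utils::write.table(mapValues(map), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
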