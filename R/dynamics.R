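#' Lateral mean-square displacement with sliding time origins
#'
#' MSD(tau) = < |r(t + tau) - r(t)|^2 > averaged over all particles and
#' all time origins t, on the lateral (x, y) coordinates only. Input must
#' be unwrapped; a jump larger than half the box in one step trips a
#' wrapped-coordinate error when \code{box} is given.
#'
#' @param pos array (n_frames, n_particles, 2) of unwrapped lateral
#'   positions (Angstrom).
#' @param maxLag largest lag in frames (default half the trajectory).
#' @param dt frame spacing, ps.
#' @param box optional numeric(2) used only for the wrapped-input check.
#' @return data.frame (lag_ps, msd_A2) with MSD(0) = 0 in the first row.
#' @export
meanSquareDisplacement <- function(pos, maxLag = NULL, dt = 1,
                                   box = NULL) {
  nf <- dim(pos)[1]
  if (nf < 2L) stop("need at least 2 frames")
  if (!is.null(box)) {
    for (k in 1:2) {
      step <- abs(diff(pos[, , k, drop = FALSE][, , 1]))
      if (any(step > box[k] / 2))
        stop("jump larger than box/2 detected: unwrap coordinates first ",
             "(see unwrapLateral)")
    }
  }
  if (is.null(maxLag)) maxLag <- floor(nf / 2)
  maxLag <- min(maxLag, nf - 1L)
  x <- pos[, , 1, drop = FALSE][, , 1, drop = FALSE]
  y <- pos[, , 2, drop = FALSE][, , 1, drop = FALSE]
  dim(x) <- dim(pos)[1:2]; dim(y) <- dim(pos)[1:2]
  msd <- numeric(maxLag)
  for (lag in seq_len(maxLag)) {
    dxm <- x[(1 + lag):nf, , drop = FALSE] - x[1:(nf - lag), , drop = FALSE]
    dym <- y[(1 + lag):nf, , drop = FALSE] - y[1:(nf - lag), , drop = FALSE]
    msd[lag] <- mean(dxm * dxm + dym * dym)
  }
  data.frame(lag_ps = c(0, seq_len(maxLag)) * dt, msd_A2 = c(0, msd))
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Least-squares line over the fit window; D = slope / (2 d) with d = 2
#' for lateral diffusion (a d = 3 option exists for 3D MSD curves). The
#' default window is [10\%, 50\%] of the maximum lag, where the MSD of an
#' equilibrated lipid trajectory is linear. A negative slope yields D < 0,
#' returned with a warning rather than masked.
#'
#' @param msd data.frame (lag_ps, msd_A2) from
#'   \code{\link{meanSquareDisplacement}}.
#' @param fitWindow numeric(2) lag window in ps; NULL for the default.
#' @param dimensions 2 (lateral) or 3.
#' @return list: \code{D_cm2s}, \code{D_A2ps}, \code{slope},
#'   \code{r2}, \code{fitWindow}.
#' @export
diffusionCoefficient <- function(msd, fitWindow = NULL, dimensions = 2) {
  tmax <- max(msd$lag_ps)
  if (is.null(fitWindow)) fitWindow <- c(0.1, 0.5) * tmax
  use <- msd$lag_ps >= fitWindow[1] & msd$lag_ps <= fitWindow[2]
  if (sum(use) < 3L) stop("fewer than 3 MSD points in the fit window")
  fit <- stats::lm(msd_A2 ~ lag_ps, data = msd[use, ])
  slope <- unname(stats::coef(fit)[2])
  if (all(msd$msd_A2 == 0)) slope <- 0
  if (slope < 0) warning("negative MSD slope; reporting D < 0 as is")
  D_A2ps <- slope / (2 * dimensions)
  list(D_cm2s = D_A2ps * mtConstants$A2ps_to_cm2s, D_A2ps = D_A2ps,
       slope = slope,
       r2 = if (slope == 0) 1 else
         suppressWarnings(summary(fit)$r.squared),
       fitWindow = fitWindow)
}

#' Deuterium order parameter of C-H bond vectors
#'
#' S_CD = < (3 cos^2 theta - 1) / 2 > with theta the angle between each
#' C-H vector and the membrane normal (z). Figures conventionally plot
#' -S_CD; this function returns S_CD itself and
#' \code{\link{orderParameterProfile}} carries the sign flip.
#'
#' @param vectors n x 3 matrix of C-H bond vectors (need not be unit).
#' @return S_CD in [-0.5, 1].
#' @export
orderParameter <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, 1)
  if (nrow(vectors) == 0L) stop("empty vector set")
  n2 <- rowSums(vectors^2)
  if (any(n2 < 1e-24)) stop("zero-length C-H vector")
  cos2 <- vectors[, 3]^2 / n2
  mean((3 * cos2 - 1) / 2)
}

#' Per-carbon order-parameter profile of a lipid type
#'
#' Collects the C-H vectors of every lipid of one type over the requested
#' frames, grouped by carbon position along the chain, and reports -S_CD
#' per position (the plotting convention).
#'
#' @param traj a SystemTrajectory.
#' @param resname lipid type.
#' @param lipidDefs lipid definitions supplying the C-H name pairs.
#' @param frames frame indices.
#' @return data.frame (carbon_index, carbon, minus_SCD, n).
#' @export
orderParameterProfile <- function(traj, resname,
                                  lipidDefs = defaultLipidDefinitions(),
                                  frames = seq_len(nFrames(traj))) {
  def <- lipidDefs[[resname]]
  if (is.null(def)) stop("no lipid definition for ", resname)
  if (length(def$chPairs) == 0L) stop(resname, " defines no C-H pairs")
  at <- atoms(traj)
  sub <- which(at$resname == resname)
  rows <- lapply(seq_along(def$chPairs), function(k) {
    pr <- def$chPairs[[k]]
    ci <- sub[at$name[sub] == pr[1]]
    hi <- sub[at$name[sub] == pr[2]]
    hi <- hi[match(at$resid[ci], at$resid[hi])]
    vecs <- do.call(rbind, lapply(frames, function(f) {
      xyz <- frameCoords(traj, f)
      xyz[hi, , drop = FALSE] - xyz[ci, , drop = FALSE]
    }))
    data.frame(carbon_index = k, carbon = pr[1],
               minus_SCD = -orderParameter(vecs), n = nrow(vecs))
  })
  do.call(rbind, rows)
}

#' Extract unwrapped lateral anchor tracks from a trajectory
#'
#' Head-atom (x, y) positions per frame for every membrane lipid, unwrapped
#' across the periodic box, suitable for
#' \code{\link{meanSquareDisplacement}}.
#'
#' @param traj a SystemTrajectory.
#' @param lipidDefs lipid definitions.
#' @param frames frame indices.
#' @return array (n_frames, n_lipids, 2).
#' @export
lateralTracks <- function(traj, lipidDefs = defaultLipidDefinitions(),
                          frames = seq_len(nFrames(traj))) {
  at <- atoms(traj)
  heads <- integer()
  for (def in lipidDefs) {
    idx <- which(at$resname == def$resname & at$name == def$headAtom)
    heads <- c(heads, idx)
  }
  heads <- sort(heads)
  if (length(heads) == 0L) stop("no head atoms found")
  pos <- array(0, c(length(frames), length(heads), 2L))
  for (f in seq_along(frames))
    pos[f, , ] <- frameCoords(traj, frames[f])[heads, 1:2]
  unwrapLateral(pos, boxLengths(traj, frames[1])[1:2])
}
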