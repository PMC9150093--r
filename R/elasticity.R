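#' Per-lipid director vectors
#'
#' For PC, SM and glycolipids the director is the unit vector from the
#' midpoint of the P and C2 atoms to the centre of mass of the last three
#' carbon atoms of the two acyl chains; for cholesterol it is the C3 -> C17
#' unit vector. The convention is head -> tail, so upper-leaflet directors
#' of a flat bilayer point along -z. Only same-leaflet director pairs enter
#' the splay statistics, so a global sign flip cancels.
#'
#' @param traj a SystemTrajectory.
#' @param frame frame index.
#' @param leaflets data.frame from \code{\link{assignLeaflets}}.
#' @param lipidDefs lipid definitions.
#' @return data.frame (resid, resname, leaflet, x, y, dx, dy, dz) where
#'   (x, y) is the lateral anchor (head-atom) position and (dx, dy, dz) the
#'   unit director.
#' @export
computeDirectors <- function(traj, frame = 1L, leaflets = NULL,
                             lipidDefs = defaultLipidDefinitions()) {
  if (is.null(leaflets)) leaflets <- assignLeaflets(traj, frame, lipidDefs)
  at <- atoms(traj)
  xyz <- frameCoords(traj, frame)
  out <- vector("list", length(lipidDefs))
  for (k in seq_along(lipidDefs)) {
    def <- lipidDefs[[k]]
    rows <- leaflets[leaflets$resname == def$resname, ]
    if (nrow(rows) == 0L) next
    sub <- at$resname == def$resname
    atomPos <- function(name) {
      i <- which(sub & at$name == name)
      m <- xyz[i[match(rows$resid, at$resid[i])], , drop = FALSE]
      if (anyNA(m)) stop("missing atom '", name, "' in ", def$resname)
      m
    }
    if (def$scheme == "two_atom") {
      a <- atomPos(def$anchorAtoms[1]); b <- atomPos(def$anchorAtoms[2])
      v <- b - a
    } else {
      mid <- (atomPos(def$midpointAtoms[1]) +
              atomPos(def$midpointAtoms[2])) / 2
      tails <- lapply(def$tailAtoms, atomPos)
      com <- Reduce(`+`, tails) / length(tails)
      v <- com - mid
    }
    nv <- sqrt(rowSums(v^2))
    if (any(nv < 1e-12)) stop("zero-length director in ", def$resname)
    v <- v / nv
    anchor <- atomPos(def$headAtom)
    out[[k]] <- data.frame(resid = rows$resid, resname = rows$resname,
                           leaflet = rows$leaflet,
                           x = anchor[, 1], y = anchor[, 2],
                           dx = v[, 1], dy = v[, 2], dz = v[, 3],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$resid), ]
}

#' Laterally adjacent same-leaflet lipid pairs
#'
#' All unordered pairs of lipids in the same leaflet whose anchors are
#' within \code{cutoff} of each other in the membrane plane (minimum-image
#' in x and y).
#'
#' @param directors data.frame from \code{\link{computeDirectors}}.
#' @param cutoff lateral distance cutoff, Angstrom.
#' @param box numeric(2) lateral box lengths; NULL disables minimum image.
#' @return data.frame (i, j, pairType, dist) with i < j row indices into
#'   \code{directors}.
#' @export
neighborPairs <- function(directors, cutoff = 10, box = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- nrow(directors)
  dx <- outer(directors$x, directors$x, `-`)
  dy <- outer(directors$y, directors$y, `-`)
  if (!is.null(box)) {
    dx <- dx - round(dx / box[1]) * box[1]
    dy <- dy - round(dy / box[2]) * box[2]
  }
  d <- sqrt(dx^2 + dy^2)
  same <- outer(directors$leaflet, directors$leaflet, `==`)
  hit <- which(d <= cutoff & same & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(i = integer(), j = integer(),
                      pairType = character(), dist = numeric()))
  a <- pmin(directors$resname[hit[, 1]], directors$resname[hit[, 2]])
  b <- pmax(directors$resname[hit[, 1]], directors$resname[hit[, 2]])
  data.frame(i = hit[, 1], j = hit[, 2],
             pairType = paste(a, b, sep = "-"),
             dist = d[hit], stringsAsFactors = FALSE)
}

#' Splay angle between two directors
#'
#' alpha = arccos of the clamped dot product, in degrees. Vectorised over
#' rows when matrices are given; non-unit inputs are normalised with a
#' warning.
#'
#' @param d1,d2 unit 3-vectors or n x 3 matrices.
#' @return angle(s) in degrees, in [0, 180].
#' @export
splayAngle <- function(d1, d2) {
  if (is.null(dim(d1))) d1 <- matrix(d1, 1)
  if (is.null(dim(d2))) d2 <- matrix(d2, 1)
  n1 <- sqrt(rowSums(d1^2)); n2 <- sqrt(rowSums(d2^2))
  if (any(abs(n1 - 1) > 1e-6) || any(abs(n2 - 1) > 1e-6)) {
    warning("non-unit director(s) normalised")
    d1 <- d1 / n1; d2 <- d2 / n2
  }
  rad2deg(acos(pmin(1, pmax(-1, rowSums(d1 * d2)))))
}

#' Fit the splay modulus from a splay-angle sample
#'
#' Builds the splay potential of mean force
#' F(alpha)/kT = -ln(P(alpha) / sin(alpha)) from a histogram of the angle
#' sample and fits F = (chi/2) * alpha^2 + c (alpha in radians) by
#' unweighted least squares on the populated bin centres inside the fit
#' window, which defaults to [10, 30] degrees.
#'
#' @param anglesDeg splay-angle sample, degrees.
#' @param fitWindow numeric(2) window in degrees.
#' @param binWidth histogram bin width, degrees.
#' @return list (class "splayFit"): \code{chi} (kT/rad^2), \code{intercept},
#'   \code{r2}, \code{binsUsed}, \code{histogram}.
#' @export
fitSplayModulus <- function(anglesDeg, fitWindow = c(10, 30), binWidth = 1) {
  if (length(anglesDeg) == 0L || all(is.na(anglesDeg)))
    stop("empty angle sample")
  edges <- seq(0, 180 + binWidth, by = binWidth)
  h <- graphics::hist(anglesDeg, breaks = edges, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  use <- centers >= fitWindow[1] & centers <= fitWindow[2] & counts > 0
  if (sum(use) < 3L)
    stop("insufficient populated bins in the fit window")
  a_rad <- deg2rad(centers[use])
  Fk <- -log(counts[use] / sin(a_rad))
  fit <- stats::lm(Fk ~ I(a_rad^2))
  structure(list(chi = 2 * unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 binsUsed = sum(use),
                 histogram = data.frame(center_deg = centers,
                                        count = counts)),
            class = "splayFit")
}

#' Per-pair-type splay statistics
#'
#' Pools the splay angles of all adjacent same-leaflet pairs by unordered
#' lipid-type pair and fits one splay modulus per pair type. Pair types
#' whose fit window holds fewer than 3 populated bins get \code{NA} chi
#' (their counts still enter phi_total).
#'
#' @param directors data.frame from \code{\link{computeDirectors}}, or a
#'   list of them (one per frame, pooled before fitting).
#' @param cutoff lateral neighbour cutoff, Angstrom.
#' @param box numeric(2) lateral box for minimum image.
#' @param fitWindow,binWidth passed to \code{\link{fitSplayModulus}}.
#' @return data.frame (pairType, phi, chi, r2) with attribute
#'   \code{phi_total}.
#' @export
splayStats <- function(directors, cutoff = 10, box = NULL,
                       fitWindow = c(10, 30), binWidth = 1) {
  if (is.data.frame(directors)) directors <- list(directors)
  ang <- list(); typ <- list()
  for (d in directors) {
    pr <- neighborPairs(d, cutoff, box)
    if (nrow(pr) == 0L) next
    a <- splayAngle(as.matrix(d[pr$i, c("dx", "dy", "dz")]),
                    as.matrix(d[pr$j, c("dx", "dy", "dz")]))
    ang[[length(ang) + 1L]] <- a
    typ[[length(typ) + 1L]] <- pr$pairType
  }
  ang <- unlist(ang); typ <- unlist(typ)
  if (length(ang) == 0L) stop("no adjacent pairs found")
  types <- sort(unique(typ))
  rows <- lapply(types, function(tt) {
    s <- ang[typ == tt]
    fit <- tryCatch(fitSplayModulus(s, fitWindow, binWidth),
                    error = function(e) NULL)
    data.frame(pairType = tt, phi = length(s),
               chi = if (is.null(fit)) NA_real_ else fit$chi,
               r2 = if (is.null(fit)) NA_real_ else fit$r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "phi_total") <- length(ang)
  out
}

#' Combine per-pair splay moduli into the bending modulus
#'
#' Count-weighted harmonic combination:
#' 1/K_C = sum_ij (phi_ij / phi_total) / chi_ij. The result is bounded
#' between the smallest and largest pair modulus and is invariant under a
#' common rescaling of the counts. An arithmetic weighting is available as
#' a switch.
#'
#' @param stats data.frame (pairType, phi, chi) as from
#'   \code{\link{splayStats}}; rows with NA chi are dropped from both the
#'   numerator and phi_total.
#' @param temperature K, for the conversion of kT to J.
#' @param weighting "harmonic" (default) or "arithmetic".
#' @return list: \code{KC_kT}, \code{KC_J}, \code{KC_1e20J}.
#' @export
combineBendingModulus <- function(stats, temperature = 323,
                                  weighting = c("harmonic", "arithmetic")) {
  weighting <- match.arg(weighting)
  ok <- !is.na(stats$chi) & stats$phi > 0
  if (!any(ok)) stop("no pair type with a valid splay modulus")
  if (any(stats$chi[ok] <= 0)) stop("non-positive splay modulus")
  phi <- stats$phi[ok]; chi <- stats$chi[ok]
  w <- phi / sum(phi)
  KC_kT <- if (weighting == "harmonic") 1 / sum(w / chi) else sum(w * chi)
  KC_J <- KC_kT * mtConstants$kB_J * temperature
  list(KC_kT = KC_kT, KC_J = KC_J, KC_1e20J = KC_J * 1e20)
}

#' Area per lipid of one frame
#'
#' Lateral box area divided by the number of lipids in a leaflet, averaged
#' over the two leaflets.
#'
#' @param traj a SystemTrajectory.
#' @param frame frame index.
#' @param leaflets data.frame from \code{\link{assignLeaflets}}.
#' @return area per lipid, Angstrom^2.
#' @export
areaPerLipid <- function(traj, frame = 1L,
                         leaflets = assignLeaflets(traj, frame)) {
  b <- boxLengths(traj, frame)
  nu <- sum(leaflets$leaflet == "upper")
  nl <- sum(leaflets$leaflet == "lower")
  if (nu == 0L || nl == 0L) stop("empty leaflet")
  mean(b[1] * b[2] / c(nu, nl))
}

#' Area compressibility modulus from area-per-lipid fluctuations
#'
#' K_A = kB * T * <A> / (N * Var(A)) with A the per-lipid area and N the
#' lipids per leaflet, converted to dyn/cm. Passing the total box area as
#' the series with \code{nLipids = 1} gives the box-area variant
#' K_A = kB * T * <A_box> / Var(A_box); both agree exactly when
#' A_box = N * A.
#'
#' @param series per-frame area per lipid, Angstrom^2.
#' @param nLipids lipids per leaflet.
#' @param temperature K.
#' @return K_A in dyn/cm.
#' @export
areaCompressibility <- function(series, nLipids, temperature = 323) {
  if (length(series) < 2L) stop("need at least 2 frames")
  v <- stats::var(series)
  if (v == 0) stop("zero variance in the area series")
  mtConstants$kB_erg * temperature * mean(series) / (nLipids * v) *
    mtConstants$dyncm_factor
}

#' Elasticity summary for one trajectory
#'
#' Convenience wrapper: directors and splay statistics pooled over frames,
#' K_C from the count-weighted harmonic combination, K_A and mean area per
#' lipid from the per-frame area series.
#'
#' @param traj a SystemTrajectory.
#' @param frames frame indices (default: all).
#' @param lipidDefs lipid definitions.
#' @param cutoff lateral neighbour cutoff, Angstrom.
#' @param temperature K.
#' @return list: \code{splay} (per-pair table), \code{KC} (list),
#'   \code{KA} (dyn/cm or NA for a single frame), \code{A} (Angstrom^2),
#'   \code{framesUsed}.
#' @export
elasticitySummary <- function(traj, frames = seq_len(nFrames(traj)),
                              lipidDefs = defaultLipidDefinitions(),
                              cutoff = 10, temperature = 323) {
  b <- boxLengths(traj, frames[1])
  dirs <- lapply(frames, function(f)
    computeDirectors(traj, f, lipidDefs = lipidDefs))
  st <- splayStats(dirs, cutoff = cutoff, box = b[1:2])
  KC <- combineBendingModulus(st, temperature)
  apl <- vapply(frames, function(f) areaPerLipid(traj, f), numeric(1))
  nleaf <- round(nrow(dirs[[1]]) / 2)
  KA <- if (length(frames) >= 2 && stats::var(apl) > 0)
    areaCompressibility(apl, nleaf, temperature) else NA_real_
  list(splay = st, KC = KC, KA = KA, A = mean(apl),
       framesUsed = length(frames))
}
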