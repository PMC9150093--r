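#' Minimum |z| distance of a selection to the membrane centre
#'
#' @param traj a SystemTrajectory.
#' @param sel atom indices (e.g. the protein selection).
#' @param z0 membrane centre z.
#' @param frame frame index.
#' @return minimum over the selection of |z - z0|, Angstrom.
#' @export
minZDistance <- function(traj, sel = selection(traj, "protein"),
                         z0 = membraneCenter(traj, frame), frame = 1L) {
  if (length(sel) == 0L) stop("empty selection")
  min(abs(frameCoords(traj, frame)[sel, 3] - z0))
}

#' Membrane surface threshold: half the mean head-to-head thickness
#'
#' The inside/outside classification of a protein against the membrane
#' surface uses half of the trajectory's own mean P-P thickness, recomputed
#' per input rather than hard-coded.
#'
#' @param traj a SystemTrajectory.
#' @param lipidDefs lipid definitions.
#' @param frames frame indices.
#' @return threshold in Angstrom.
#' @export
surfaceThreshold <- function(traj, lipidDefs = defaultLipidDefinitions(),
                             frames = seq_len(nFrames(traj))) {
  th <- vapply(frames, function(f) {
    la <- assignLeaflets(traj, f, lipidDefs)
    mean(la$head_z[la$leaflet == "upper"]) -
      mean(la$head_z[la$leaflet == "lower"])
  }, numeric(1))
  mean(th) / 2
}

#' Minimum interatomic distance between two atom sets (cell list)
#'
#' Exact nearest-pair distance found with a uniform cell grid and an
#' expanding shell search: shells of cells are examined in order of their
#' Chebyshev index distance, and the search stops as soon as the best
#' distance found is provably smaller than anything an unexamined shell
#' can contain. Lateral (x, y) minimum image is applied when \code{box}
#' is given; z is non-periodic. Results equal the brute-force O(N^2) scan.
#'
#' @param A,B n x 3 coordinate matrices.
#' @param box optional numeric(2) lateral box lengths.
#' @param cell cell edge length (Angstrom); a data-driven default is used
#'   when NULL.
#' @return minimum distance, Angstrom.
#' @export
minInteratomicDistance <- function(A, B, box = NULL, cell = NULL) {
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty coordinate set")
  if (is.null(cell)) {
    span <- apply(rbind(A, B), 2, function(v) diff(range(v)))
    cell <- max(2, (prod(pmax(span, 1)) / (nrow(A) + nrow(B)))^(1 / 3) * 2)
  }
  lo <- pmin(apply(A, 2, min), apply(B, 2, min))
  periodic <- !is.null(box)
  ncell <- integer(3)
  for (k in 1:3) {
    if (periodic && k <= 2) ncell[k] <- max(1L, floor(box[k] / cell))
    else ncell[k] <- max(1L, ceiling((max(A[, k], B[, k]) - lo[k]) /
                                       cell) + 1L)
  }
  h <- c(if (periodic) box[1] / ncell[1] else cell,
         if (periodic) box[2] / ncell[2] else cell, cell)
  idx <- function(M) {
    out <- matrix(0L, nrow(M), 3)
    for (k in 1:3) {
      v <- M[, k] - lo[k]
      if (periodic && k <= 2) {
        v <- v - floor(v / box[k]) * box[k]
        out[, k] <- as.integer(floor(v / h[k])) %% ncell[k]
      } else out[, k] <- pmin(as.integer(floor(v / h[k])), ncell[k] - 1L)
    }
    out
  }
  ia <- idx(A); ib <- idx(B)
  keyOf <- function(m) m[, 1] + ncell[1] * (m[, 2] + ncell[2] * m[, 3])
  bBuckets <- split(seq_len(nrow(B)), keyOf(ib))
  aCells <- split(seq_len(nrow(A)), keyOf(ia))
  ukeys <- as.integer(names(aCells))
  aCellIdx <- cbind(ukeys %% ncell[1],
                    (ukeys %/% ncell[1]) %% ncell[2],
                    ukeys %/% (ncell[1] * ncell[2]))
  rownames(aCellIdx) <- names(aCells)
  pairDist <- function(ai, bi) {
    d2 <- matrix(0, length(ai), length(bi))
    for (k in 1:3) {
      dk <- outer(A[ai, k], B[bi, k], `-`)
      if (periodic && k <= 2) dk <- dk - round(dk / box[k]) * box[k]
      d2 <- d2 + dk^2
    }
    sqrt(min(d2))
  }
  best <- Inf
  maxShell <- max(ncell)
  for (sh in 0:maxShell) {
    offs <- as.matrix(expand.grid(dx = -sh:sh, dy = -sh:sh, dz = -sh:sh))
    offs <- offs[pmax(abs(offs[, 1]), abs(offs[, 2]),
                      abs(offs[, 3])) == sh, , drop = FALSE]
    found_any <- FALSE
    for (cn in rownames(aCellIdx)) {
      ci <- aCellIdx[cn, ]
      nb <- t(t(offs) + ci)
      if (periodic) {
        nb[, 1] <- nb[, 1] %% ncell[1]; nb[, 2] <- nb[, 2] %% ncell[2]
      } else {
        ok <- nb[, 1] >= 0 & nb[, 1] < ncell[1] &
              nb[, 2] >= 0 & nb[, 2] < ncell[2]
        nb <- nb[ok, , drop = FALSE]
      }
      ok <- nb[, 3] >= 0 & nb[, 3] < ncell[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0L) next
      keys <- unique(nb[, 1] + ncell[1] * (nb[, 2] + ncell[2] * nb[, 3]))
      cand <- unlist(bBuckets[as.character(keys)], use.names = FALSE)
      if (length(cand) == 0L) next
      found_any <- TRUE
      best <- min(best, pairDist(aCells[[cn]], cand))
    }
    # nothing in an unexamined shell can beat sh * min(h)
    if (best <= sh * min(h)) break
    # every cell pair has been visited once the shell spans the whole grid
    if (sh >= max(ncell) - 1L) break
  }
  best
}

#' Per-frame protein-membrane proximity series
#'
#' For every frame in the window: the minimum interatomic protein-membrane
#' distance and the minimum |z| distance of the protein to the membrane
#' centre.
#'
#' @param traj a SystemTrajectory.
#' @param protSel,memSel atom index selections.
#' @param frames frame indices (the analysis window).
#' @return data.frame (frame, min_dist, min_z).
#' @export
contactSeries <- function(traj, protSel = selection(traj, "protein"),
                          memSel = selection(traj, "membrane"),
                          frames = seq_len(nFrames(traj))) {
  if (length(protSel) == 0L || length(memSel) == 0L)
    stop("empty selection")
  rows <- lapply(frames, function(f) {
    xyz <- frameCoords(traj, f)
    b <- boxLengths(traj, f)
    data.frame(frame = f,
               min_dist = minInteratomicDistance(
                 xyz[protSel, , drop = FALSE], xyz[memSel, , drop = FALSE],
                 box = b[1:2]),
               min_z = minZDistance(traj, protSel,
                                    membraneCenter(traj, f), f))
  })
  do.call(rbind, rows)
}

#' Contact population: percentage of frames within a cutoff
#'
#' 100 x (frames whose minimum interatomic distance is <= cutoff) /
#' (frames in the window). The comparator is inclusive (<=); the strict
#' variant used for "approach" statistics is available via
#' \code{inclusive = FALSE}.
#'
#' @param traj a SystemTrajectory.
#' @param protSel,memSel atom index selections.
#' @param cutoff Angstrom.
#' @param frames analysis window (frame indices).
#' @param inclusive use <= (default) or <.
#' @return percentage in [0, 100].
#' @export
contactPopulation <- function(traj, protSel = selection(traj, "protein"),
                              memSel = selection(traj, "membrane"),
                              cutoff = 10,
                              frames = seq_len(nFrames(traj)),
                              inclusive = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(frames) == 0L) stop("empty analysis window")
  cs <- contactSeries(traj, protSel, memSel, frames)
  hit <- if (inclusive) cs$min_dist <= cutoff else cs$min_dist < cutoff
  100 * sum(hit) / length(frames)
}

#' Side-chain contact map between two residue sets
#'
#' Two residues are in contact when the distance between the centres of
#' mass of their side chains is <= cutoff (6.5 Angstrom by default,
#' boundary inclusive). Backbone N, CA, C and O atoms are excluded from
#' the side chain; glycine falls back to its CA.
#'
#' @param traj a SystemTrajectory.
#' @param selA,selB atom index selections covering the residues to compare.
#' @param frame frame index.
#' @param cutoff Angstrom.
#' @return list: \code{contacts} (logical matrix residues A x residues B),
#'   \code{count} (total contacts), \code{interChain} (contacts whose two
#'   residues sit on different chains), \code{residuesA}, \code{residuesB}.
#' @export
sideChainContactMap <- function(traj, selA, selB, frame = 1L,
                                cutoff = 6.5) {
  scCOM <- function(sel) {
    at <- atoms(traj)[sel, ]
    xyz <- frameCoords(traj, frame)[sel, , drop = FALSE]
    key <- paste(at$chain, at$resid)
    res <- unique(key)
    com <- matrix(NA_real_, length(res), 3)
    for (i in seq_along(res)) {
      rows <- key == res[i]
      side <- rows & !(at$name %in% c("N", "CA", "C", "O"))
      if (!any(side)) side <- rows & at$name == "CA"
      if (!any(side))
        stop("residue ", res[i], " has no side-chain atoms and no CA")
      m <- mtMasses[at$element[side]]
      m[is.na(m)] <- mtMasses["C"]
      com[i, ] <- colSums(xyz[side, , drop = FALSE] * m) / sum(m)
    }
    list(res = res, com = com,
         chain = at$chain[match(res, key)])
  }
  a <- scCOM(selA); b <- scCOM(selB)
  d2 <- outer(a$com[, 1], b$com[, 1], `-`)^2 +
        outer(a$com[, 2], b$com[, 2], `-`)^2 +
        outer(a$com[, 3], b$com[, 3], `-`)^2
  contacts <- sqrt(d2) <= cutoff
  dimnames(contacts) <- list(a$res, b$res)
  inter <- contacts & outer(a$chain, b$chain, `!=`)
  list(contacts = contacts, count = sum(contacts),
       interChain = sum(inter), residuesA = a$res, residuesB = b$res)
}

# CHARMM-style cubic potential switching function on [ron, roff].
switchFunction <- function(r, ron, roff) {
  s <- rep(1, length(r))
  s[r >= roff] <- 0
  mid <- r > ron & r < roff
  if (any(mid)) {
    r2 <- r[mid]^2
    s[mid] <- (roff^2 - r2)^2 * (roff^2 + 2 * r2 - 3 * ron^2) /
      (roff^2 - ron^2)^3
  }
  s
}

#' Cutoff-based nonbonded interaction energy between two atom sets
#'
#' Electrostatics: sum of k_e q_i q_j / r_ij over cross pairs with
#' r <= coulombCutoff (12 Angstrom default). Van der Waals: Lennard-Jones
#' 4 eps [(sigma/r)^12 - (sigma/r)^6] with Lorentz-Berthelot combination
#' and a cubic switching function on [switchOn, switchOff] (10-12
#' Angstrom). This is a plain real-space re-scoring facility; it does not
#' reproduce Ewald (PME) electrostatics, whose long-range part a cutoff
#' scheme systematically misses.
#'
#' @param coordsA,coordsB n x 3 matrices.
#' @param chargesA,chargesB per-atom charges, e.
#' @param ljA,ljB data.frames with columns \code{sigma} (Angstrom) and
#'   \code{epsilon} (kcal/mol), or NULL to skip the vdW term.
#' @param scheme list(coulombCutoff, switchOn, switchOff), Angstrom.
#' @param box optional lateral box for minimum image.
#' @return list (class "energyBreakdown"): \code{elec}, \code{vdw},
#'   \code{total}, all kcal/mol; \code{nOverlap} counts pairs closer than
#'   0.1 Angstrom (also warned about).
#' @export
nonbondedEnergy <- function(coordsA, coordsB, chargesA, chargesB,
                            ljA = NULL, ljB = NULL,
                            scheme = list(coulombCutoff = 12,
                                          switchOn = 10, switchOff = 12),
                            box = NULL) {
  if (is.null(dim(coordsA))) coordsA <- matrix(coordsA, 1)
  if (is.null(dim(coordsB))) coordsB <- matrix(coordsB, 1)
  d2 <- matrix(0, nrow(coordsA), nrow(coordsB))
  for (k in 1:3) {
    dk <- outer(coordsA[, k], coordsB[, k], `-`)
    if (!is.null(box) && k <= 2) dk <- dk - round(dk / box[k]) * box[k]
    d2 <- d2 + dk^2
  }
  r <- sqrt(d2)
  nOverlap <- sum(r < 0.1)
  if (nOverlap > 0) warning(nOverlap, " atom pair(s) closer than 0.1 A")
  qq <- outer(chargesA, chargesB)
  elec <- sum(mtConstants$ke_kcal * qq[r <= scheme$coulombCutoff] /
                r[r <= scheme$coulombCutoff & r > 0])
  vdw <- 0
  if (!is.null(ljA) && !is.null(ljB)) {
    sig <- outer(ljA$sigma, ljB$sigma, `+`) / 2
    eps <- sqrt(outer(ljA$epsilon, ljB$epsilon))
    inside <- r < scheme$switchOff & r > 0
    if (any(inside)) {
      sr6 <- (sig[inside] / r[inside])^6
      lj <- 4 * eps[inside] * (sr6^2 - sr6)
      vdw <- sum(lj * switchFunction(r[inside], scheme$switchOn,
                                     scheme$switchOff))
    }
  }
  structure(list(elec = elec, vdw = vdw, total = elec + vdw,
                 nOverlap = nOverlap, scheme = scheme),
            class = "energyBreakdown")
}

#' Inter-chain nonbonded energy
#'
#' Sum of \code{\link{nonbondedEnergy}} over all unordered chain pairs;
#' intra-chain terms are excluded.
#'
#' @param traj a SystemTrajectory.
#' @param sel atom indices covering the chains (default: protein).
#' @param charges per-atom charges for \code{sel} (default: the atom
#'   table's charge column).
#' @param lj data.frame (sigma, epsilon) rows matching \code{sel}, or NULL.
#' @param scheme cutoff scheme, see \code{\link{nonbondedEnergy}}.
#' @param frame frame index.
#' @return list: \code{elec}, \code{vdw}, \code{total} (kcal/mol),
#'   \code{pairs} (per-chain-pair data.frame).
#' @export
interchainEnergy <- function(traj, sel = selection(traj, "protein"),
                             charges = atoms(traj)$charge[sel],
                             lj = NULL,
                             scheme = list(coulombCutoff = 12,
                                           switchOn = 10, switchOff = 12),
                             frame = 1L) {
  at <- atoms(traj)[sel, ]
  chains <- unique(at$chain)
  if (length(chains) < 2L) stop("need at least 2 chains")
  xyz <- frameCoords(traj, frame)[sel, , drop = FALSE]
  combos <- utils::combn(chains, 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    ia <- at$chain == combos[1, k]; ib <- at$chain == combos[2, k]
    e <- nonbondedEnergy(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                         charges[ia], charges[ib],
                         if (is.null(lj)) NULL else lj[ia, , drop = FALSE],
                         if (is.null(lj)) NULL else lj[ib, , drop = FALSE],
                         scheme)
    data.frame(chainA = combos[1, k], chainB = combos[2, k],
               elec = e$elec, vdw = e$vdw, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(elec = sum(tab$elec), vdw = sum(tab$vdw),
       total = sum(tab$elec) + sum(tab$vdw), pairs = tab)
}

#' Read a plain-text nonbonded parameter table
#'
#' Whitespace- or comma-separated columns: atom name (or type), charge
#' (e), sigma (Angstrom), epsilon (kcal/mol).
#'
#' @param path parameter file.
#' @return data.frame (name, charge, sigma, epsilon).
#' @export
readParameterTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (grepl(",", readLines(path, n = 1)))
                             "," else "")
  names(tab)[1:4] <- c("name", "charge", "sigma", "epsilon")
  tab
}
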