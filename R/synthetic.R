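# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic bilayer specification
#'
#' Bundles the study conditions emulated by the generators: the
#' five-component neuronal membrane composition (DPPC:POPC:PSM:CHL1:GM1 at
#' molar ratios 36.5:35.2:9.7:17.8:0.8), 484 lipids per leaflet, a mean
#' P-P thickness of 41.2 Angstrom, an area per lipid of 52.7 Angstrom^2,
#' and per-stage ground-truth parameters (splay modulus, area
#' compressibility, lateral diffusion, simulation temperature 323 K).
#'
#' @param composition named mole fractions (must sum to 1 within 1e-6).
#' @param lipidsPerLeaflet lipids in one leaflet.
#' @param thickness target P-P distance, Angstrom.
#' @param areaPerLipid target area per lipid, Angstrom^2.
#' @param jitter sd of the per-lipid rigid positional jitter, Angstrom.
#' @param temperature K.
#' @param chi ground-truth splay modulus, kT/rad^2.
#' @param KA ground-truth area compressibility modulus, dyn/cm.
#' @param D ground-truth lateral diffusion coefficient, cm^2/s.
#' @return a "SyntheticSpec" list.
#' @export
syntheticSpec <- function(composition = c(DPPC = 0.365, POPC = 0.352,
                                          PSM = 0.097, CHL1 = 0.178,
                                          GM1 = 0.008),
                          lipidsPerLeaflet = 484L,
                          thickness = 41.2, areaPerLipid = 52.7,
                          jitter = 0.3, temperature = 323,
                          chi = 15, KA = 236, D = 2.16e-7) {
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mole fractions must sum to 1")
  if (any(c(lipidsPerLeaflet, thickness, areaPerLipid, temperature,
            chi, KA, D) <= 0) || jitter < 0)
    stop("all physical parameters must be positive")
  structure(list(composition = composition,
                 lipidsPerLeaflet = as.integer(lipidsPerLeaflet),
                 thickness = thickness, areaPerLipid = areaPerLipid,
                 jitter = jitter, temperature = temperature,
                 chi = chi, KA = KA, D = D),
            class = "SyntheticSpec")
}

#' Integer lipid counts from mole fractions (largest-remainder rounding)
#'
#' Preserves the leaflet total exactly; ties broken by input order.
#'
#' @param fractions named mole fractions summing to 1.
#' @param total integer total to distribute.
#' @return named integer vector summing to \code{total}.
#' @export
compositionCounts <- function(fractions, total) {
  q <- fractions * total
  base <- floor(q)
  extra <- as.integer(round(total - sum(base)))
  if (extra > 0) {
    take <- order(-(q - base), seq_along(q))[seq_len(extra)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# Atom template for one pseudo-lipid, upper leaflet, head at z = zhead.
# Tails are exactly straight along -z so the director test geometry is
# known; C-H bonds are placed in-plane. Lower leaflet is mirrored.
pseudoLipidAtoms <- function(resname, category, zhead) {
  if (category == "cholesterol") {
    df <- data.frame(
      name = c("O3", "C3", "C17"),
      dx = c(0, 0, 0), dy = 0,
      z = c(zhead, zhead - 2, zhead - 10))
  } else {
    df <- data.frame(
      name = c("P", "C2", "C14", "H14", "C15", "H15", "C16", "H16",
               "C24", "C25", "C26"),
      dx = c(0, 0, 0, 1.09, 0, 1.09, 0, 1.09, 0, 0, 0), dy = 0,
      z = c(zhead, zhead - 2, zhead - 15, zhead - 15, zhead - 16,
            zhead - 16, zhead - 17, zhead - 17, zhead - 15, zhead - 16,
            zhead - 17))
  }
  df$resname <- resname
  df
}

#' Generate a flat two-leaflet pseudo-bilayer
#'
#' Pseudo-lipids are placed on a jittered lattice at the target area per
#' lipid, with P sheets at +/- thickness/2 about z = 0 (plus \code{z0}).
#' Each pseudo-lipid carries the atoms the downstream stages need (P, C2,
#' terminal tail carbons, C-H pairs; O3/C3/C17 for cholesterol), with tails
#' exactly straight so directors are +/- z by construction. The jitter is a
#' rigid per-lipid displacement, so it perturbs positions and thickness but
#' not director orientations. Ground truth (per-lipid leaflet labels,
#' composition counts, thickness, area per lipid) is stored in
#' \code{metadata$truth}.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param nFrames frames to generate (independent jitter per frame).
#' @param seed RNG seed.
#' @param z0 z of the membrane centre (default 0).
#' @return a \linkS4class{SystemTrajectory}.
#' @export
genBilayer <- function(spec = syntheticSpec(), nFrames = 1L, seed = 1L,
                       z0 = 0) {
  n <- spec$lipidsPerLeaflet
  counts <- compositionCounts(spec$composition, n)
  L <- sqrt(n * spec$areaPerLipid)
  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  sx <- L / nx; sy <- L / ny
  site <- seq_len(n) - 1L
  lx <- (site %% nx + 0.5) * sx
  ly <- (site %/% nx + 0.5) * sy
  defs <- defaultLipidDefinitions()
  types <- rep(names(counts), counts)
  withSeed(seed, {
    typesU <- sample(types); typesL <- sample(types)
    resid <- 0L
    blocks <- list()
    for (leaf in c("upper", "lower")) {
      tv <- if (leaf == "upper") typesU else typesL
      sgn <- if (leaf == "upper") 1 else -1
      for (i in seq_len(n)) {
        resid <- resid + 1L
        tmpl <- pseudoLipidAtoms(tv[i], defs[[tv[i]]]$category,
                                 spec$thickness / 2)
        blocks[[resid]] <- data.frame(
          name = tmpl$name, resname = tmpl$resname, resid = resid,
          chain = "M", x0 = lx[i] + tmpl$dx, y0 = ly[i] + tmpl$dy,
          z0 = z0 + sgn * tmpl$z, leaflet = leaf,
          stringsAsFactors = FALSE)
      }
    }
    at <- do.call(rbind, blocks)
    nlip <- resid
    coords <- vector("list", nFrames)
    for (f in seq_len(nFrames)) {
      jit <- matrix(stats::rnorm(nlip * 3, sd = spec$jitter), nlip, 3)
      coords[[f]] <- cbind(at$x0, at$y0, at$z0) + jit[at$resid, ]
    }
  })
  atoms <- data.frame(id = seq_len(nrow(at)), name = at$name,
                      resname = at$resname, resid = at$resid,
                      chain = at$chain, stringsAsFactors = FALSE)
  truth_leaf <- unique(data.frame(resid = at$resid, resname = at$resname,
                                  leaflet = at$leaflet,
                                  stringsAsFactors = FALSE))
  sel <- list(membrane = seq_len(nrow(atoms)))
  for (tn in names(counts))
    sel[[tn]] <- which(atoms$resname == tn)
  systemTrajectory(atoms, coords, c(L, L, spec$thickness + 40),
                   selections = sel,
                   metadata = list(truth = list(
                     leaflets = truth_leaf, counts = counts,
                     thickness = spec$thickness,
                     areaPerLipid = spec$areaPerLipid, z0 = z0,
                     spec = spec)))
}

#' Sample lipid splay angles from a Boltzmann splay distribution
#'
#' Draws angles from the density p(alpha) proportional to
#' sin(alpha) * exp(-chi * alpha^2 / 2) on [0, pi/2] by inverse-CDF lookup
#' on a fine quadrature grid. The sin(alpha) geometric factor is included
#' because the PMF estimator divides it out, making generator and
#' estimator an exact inverse pair.
#'
#' @param chiTrue splay modulus, kT/rad^2 (> 0).
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of angles in radians.
#' @export
genSplaySample <- function(chiTrue, n, seed = 1L) {
  if (chiTrue <= 0 || n < 1) stop("chiTrue and n must be positive")
  grid <- seq(0, pi / 2, length.out = 20001L)
  dens <- sin(grid) * exp(-chiTrue * grid^2 / 2)
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  withSeed(seed, stats::approx(cdf[keep], grid[keep],
                               xout = stats::runif(n))$y)
}

#' Generate an equilibrium area-per-lipid fluctuation series
#'
#' Gaussian series with mean \code{meanArea} and variance
#' kB*T*meanArea / (nLipids * KA) — the equilibrium fluctuation law that
#' the area-compressibility estimator inverts.
#'
#' @param KATrue area compressibility modulus, dyn/cm.
#' @param meanArea mean area per lipid, Angstrom^2.
#' @param nLipids lipids per leaflet.
#' @param temperature K.
#' @param nFrames series length.
#' @param seed RNG seed.
#' @return numeric series of per-frame area per lipid (Angstrom^2).
#' @export
genAreaSeries <- function(KATrue, meanArea, nLipids, temperature,
                          nFrames, seed = 1L) {
  if (any(c(KATrue, meanArea, nLipids, temperature, nFrames) <= 0))
    stop("all parameters must be positive")
  v <- mtConstants$kB_erg * temperature * meanArea /
    (nLipids * KATrue) * mtConstants$dyncm_factor
  withSeed(seed, stats::rnorm(nFrames, mean = meanArea, sd = sqrt(v)))
}

#' Generate 2D Brownian lateral tracks
#'
#' Independent Gaussian steps with per-axis variance 2*D*dt, the
#' fluctuation law whose ensemble MSD is 4*D*tau.
#'
#' @param DTrue diffusion coefficient, cm^2/s (>= 0).
#' @param dt time step, ps.
#' @param nSteps number of steps (output has nSteps + 1 frames).
#' @param nParticles number of independent walkers.
#' @param seed RNG seed.
#' @return array (nSteps + 1, nParticles, 2) of positions, Angstrom.
#' @export
genRandomWalk <- function(DTrue, dt, nSteps, nParticles, seed = 1L) {
  if (DTrue < 0 || dt <= 0 || nSteps < 1 || nParticles < 1)
    stop("parameter out of range")
  D_A2ps <- DTrue / mtConstants$A2ps_to_cm2s
  sdstep <- sqrt(2 * D_A2ps * dt)
  withSeed(seed, {
    pos <- array(0, c(nSteps + 1L, nParticles, 2L))
    for (k in 1:2) {
      steps <- matrix(stats::rnorm(nSteps * nParticles, sd = sdstep),
                      nSteps, nParticles)
      pos[-1L, , k] <- apply(steps, 2, cumsum)
    }
    pos
  })
}

#' Generate C-H bond unit vectors with a known orientational law
#'
#' @param mode "all_z" (all along +z), "all_xy" (uniform azimuth in the
#'   membrane plane), "isotropic" (uniform on the sphere) or "fixed_theta"
#'   (polar angle \code{theta}, uniform azimuth).
#' @param n number of vectors.
#' @param seed RNG seed.
#' @param theta polar angle in degrees (fixed_theta mode).
#' @return n x 3 matrix of unit vectors.
#' @export
genChVectors <- function(mode = c("all_z", "all_xy", "isotropic",
                                  "fixed_theta"),
                         n, seed = 1L, theta = 54.7356) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  withSeed(seed, {
    phi <- stats::runif(n, 0, 2 * pi)
    switch(mode,
      all_z = matrix(rep(c(0, 0, 1), each = n), n, 3),
      all_xy = cbind(cos(phi), sin(phi), 0),
      isotropic = {
        cz <- stats::runif(n, -1, 1)
        s <- sqrt(1 - cz^2)
        cbind(s * cos(phi), s * sin(phi), cz)
      },
      fixed_theta = {
        th <- deg2rad(theta)
        cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th), n))
      })
  })
}

#' Generate a dense atom slab with planted cylindrical surface cracks
#'
#' Pseudo-atoms on a cubic lattice (spacing \code{atomSpacing}, per-atom
#' radius \code{atomRadius} stored in the atom table) fill the slab
#' z in [0, thickness]. Each crack removes every atom whose sphere
#' intersects the open cylinder \{lateral distance <= radius,
#' z > thickness - depth\} below (x, y), so the planted void spans exactly
#' [thickness - depth, thickness] at the cylinder axis. A depth equal to
#' the thickness produces a through-hole. Overlapping crack specifications
#' are reported with a warning but still carved.
#'
#' @param thickness slab thickness, Angstrom.
#' @param atomSpacing lattice spacing, Angstrom.
#' @param cracks data.frame (x, y, radius, depth) or list of numeric(4).
#' @param lateral lateral box edge, Angstrom.
#' @param atomRadius pseudo-atom occupancy radius, Angstrom; must exceed
#'   atomSpacing * sqrt(3)/2 so a pristine slab is fully occupied.
#' @param seed RNG seed (reserved; the slab itself is deterministic).
#' @return a \linkS4class{SystemTrajectory} with \code{metadata$zBounds}.
#' @export
genCrackedSlab <- function(thickness, atomSpacing = 1.0, cracks = NULL,
                           lateral = 24, atomRadius = 1.3, seed = 1L) {
  if (!is.null(cracks)) {
    if (is.list(cracks) && !is.data.frame(cracks))
      cracks <- as.data.frame(do.call(rbind, cracks))
    names(cracks) <- c("x", "y", "radius", "depth")
    if (any(cracks$depth > thickness + 1e-9))
      stop("crack depth exceeds slab thickness")
    if (any(cracks$radius <= atomSpacing))
      stop("crack radius must exceed the atom spacing")
    if (nrow(cracks) > 1) {
      d <- as.matrix(stats::dist(cracks[, c("x", "y")]))
      rsum <- outer(cracks$radius, cracks$radius, `+`)
      if (any(d[upper.tri(d)] < rsum[upper.tri(rsum)]))
        warning("overlapping crack specifications")
    }
  }
  if (atomRadius < atomSpacing * sqrt(3) / 2)
    stop("atomRadius too small to fill the slab between lattice sites")
  g1 <- seq(atomSpacing / 2, lateral - atomSpacing / 4, by = atomSpacing)
  gz <- seq(atomSpacing / 2, thickness, by = atomSpacing)
  pts <- as.matrix(expand.grid(x = g1, y = g1, z = gz))
  keep <- rep(TRUE, nrow(pts))
  if (!is.null(cracks) && nrow(cracks)) {
    zfloor <- thickness - cracks$depth
    for (i in seq_len(nrow(cracks))) {
      dlat <- sqrt((pts[, 1] - cracks$x[i])^2 + (pts[, 2] - cracks$y[i])^2)
      dreg <- sqrt(pmax(0, dlat - cracks$radius[i])^2 +
                   pmax(0, zfloor[i] - pts[, 3])^2)
      keep <- keep & (dreg >= atomRadius)
    }
  }
  pts <- pts[keep, , drop = FALSE]
  atoms <- data.frame(id = seq_len(nrow(pts)), name = "SLB",
                      resname = "SLB", resid = seq_len(nrow(pts)),
                      chain = "S", element = "C",
                      radius = atomRadius, stringsAsFactors = FALSE)
  systemTrajectory(atoms, unname(pts), c(lateral, lateral, thickness + 10),
                   selections = list(membrane = seq_len(nrow(pts))),
                   metadata = list(zBounds = c(0, thickness),
                                   cracks = cracks))
}
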