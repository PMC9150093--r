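# djb2-style hash of a serialised R object, as a provenance fingerprint.
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)])
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a run configuration (YAML)
#'
#' Fields: \code{input} (topology/trajectory paths) or \code{synthetic}
#' (arguments of \code{\link{syntheticSpec}} plus \code{n_frames},
#' \code{replicates}), \code{stages}, \code{window}
#' (first/last/stride), \code{params} (per-stage blocks), \code{seed},
#' \code{temperature}.
#'
#' @param path YAML file.
#' @return config list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Write a run configuration (YAML)
#' @param config config list.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Resolve the analysis window: explicit frames, or the final 3/8 of the
# trajectory (the equilibrated tail used for production statistics).
resolveWindow <- function(config, nf) {
  w <- config$window
  if (is.null(w)) {
    first <- max(1L, nf - floor(nf * 3 / 8) + 1L)
    return(seq(first, nf))
  }
  first <- w$first %||% 1L
  last <- w$last %||% nf
  stride <- w$stride %||% 1L
  if (first > last || stride < 1L) stop("invalid analysis window")
  seq(first, min(last, nf), by = stride)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order on one trajectory or
#' on several synthetic replicates, recording per-stage failures without
#' aborting independent stages, and aggregates metrics across
#' trajectories as mean, sd and n. Deterministic given config + seed.
#'
#' @param config list (see \code{\link{readRunConfig}}) or a YAML path.
#' @return list (class "membraneReport"): \code{perTrajectory} (long
#'   data.frame: trajectory, stage, metric, value, unit), \code{summary}
#'   (metric, mean, sd, n, unit), \code{failures}, \code{provenance}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stages <- config$stages %||% c("thickness", "area")
  seed <- config$seed %||% 1L
  temperature <- config$temperature %||% 323
  params <- config$params %||% list()
  lipidDefs <- if (!is.null(config$lipid_definitions))
    readLipidDefinitions(config$lipid_definitions)
  else defaultLipidDefinitions()

  trajs <- list()
  if (!is.null(config$synthetic)) {
    s <- config$synthetic
    spec <- syntheticSpec(
      lipidsPerLeaflet = s$lipids_per_leaflet %||% 484L,
      thickness = s$thickness %||% 41.2,
      areaPerLipid = s$area_per_lipid %||% 52.7,
      jitter = s$jitter %||% 0.3,
      temperature = temperature)
    reps <- s$replicates %||% 1L
    for (rset in seq_len(reps))
      trajs[[sprintf("synthetic_%02d", rset)]] <-
        genBilayer(spec, nFrames = s$n_frames %||% 1L,
                   seed = seed + rset - 1L)
  } else if (!is.null(config$input)) {
    trajs[[basename(config$input$topology)]] <-
      loadSystem(config$input$topology, config$input$trajectory, lipidDefs)
  } else stop("config needs either `synthetic` or `input`")

  rows <- list(); failures <- list()
  emit <- function(tr, stage, metric, value, unit)
    rows[[length(rows) + 1L]] <<- data.frame(
      trajectory = tr, stage = stage, metric = metric, value = value,
      unit = unit, stringsAsFactors = FALSE)
  for (tn in names(trajs)) {
    traj <- trajs[[tn]]
    frames <- resolveWindow(config, nFrames(traj))
    for (stage in stages) {
      res <- tryCatch({
        switch(stage,
          thickness = {
            tm <- thicknessMap(traj, lipidDefs, frames,
                               bins = params$thickness$bins %||% 16L)
            emit(tn, stage, "thickness", mean(mapValues(tm)), "Angstrom")
          },
          area = {
            apl <- vapply(frames, function(f)
              areaPerLipid(traj, f, assignLeaflets(traj, f, lipidDefs)),
              numeric(1))
            emit(tn, stage, "area_per_lipid", mean(apl), "Angstrom^2")
            if (length(apl) >= 2 && stats::var(apl) > 0) {
              la <- assignLeaflets(traj, frames[1], lipidDefs)
              emit(tn, stage, "KA",
                   areaCompressibility(apl, sum(la$leaflet == "upper"),
                                       temperature), "dyn/cm")
            }
          },
          elasticity = {
            es <- elasticitySummary(traj, frames, lipidDefs,
                                    cutoff = params$elasticity$cutoff %||% 10,
                                    temperature = temperature)
            emit(tn, stage, "KC", es$KC$KC_1e20J, "1e-20 J")
          },
          density = {
            for (ln in intersect(selection(traj), names(lipidDefs))) {
              dm <- densityMap(traj, anchorSelection(traj, ln, lipidDefs),
                               frames, bins = params$density$bins %||% 16L)
              emit(tn, stage, paste0("density_", ln),
                   mean(mapValues(dm)), "atoms/Angstrom^2")
            }
          },
          cracks = {
            og <- buildOccupancy(traj, frames[1],
                                 voxel = params$cracks$voxel %||% 1.0)
            cs <- detectCracks(og)
            tab <- crackTable(cs)
            emit(tn, stage, "n_cracks", nrow(tab), "count")
            emit(tn, stage, "max_crack_depth",
                 if (nrow(tab)) max(tab$depth) else 0, "Angstrom")
          },
          diffusion = {
            pos <- lateralTracks(traj, lipidDefs, frames)
            msd <- meanSquareDisplacement(pos,
                                          dt = params$diffusion$dt %||% 1)
            dc <- diffusionCoefficient(msd)
            emit(tn, stage, "D", dc$D_cm2s, "cm^2/s")
          },
          stop("unknown stage: ", stage))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        failures[[paste(tn, stage, sep = "/")]] <- res
    }
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory = character(), stage = character(),
               metric = character(), value = numeric(), unit = character())
  if (nrow(per) == 0L && length(failures) == length(trajs) * length(stages))
    stop("all stages failed")
  summ <- do.call(rbind, lapply(split(per, per$metric), function(g)
    data.frame(metric = g$metric[1], mean = mean(g$value),
               sd = if (nrow(g) > 1) stats::sd(g$value) else NA_real_,
               n = nrow(g), unit = g$unit[1], stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(perTrajectory = per, summary = summ, failures = failures,
                 provenance = list(
                   configHash = configHash(config),
                   package = as.character(utils::packageVersion("membraneTools")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "membraneReport")
}

#' @export
print.membraneReport <- function(x, ...) {
  cat("membraneTools report (", nrow(x$perTrajectory), " metric rows, ",
      length(x$failures), " stage failure(s))\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Generator-estimator validation suite
#'
#' Runs every synthetic generator -> estimator round trip at its default
#' ground-truth values and reports recovered vs planted quantities with
#' pass/fail against the stated tolerances: splay modulus within 5%,
#' K_A within 5%, D within 3%, order-parameter closed forms within 1e-6
#' (isotropic |S_CD| < 0.01), crack depth within one voxel, thickness and
#' energy/contact closed forms exact to stated bounds, cell-list minimum
#' distances identical to brute force, ideal-gas lateral RDF within 2%.
#'
#' @param seed integer seed for every stochastic fixture.
#' @param tolScale multiplier applied to all tolerances (a harness
#'   sanity knob: 0 makes every stochastic row fail).
#' @return data.frame (check, planted, recovered, tolerance, pass).
#' @export
validateSynthetic <- function(seed = 1L, tolScale = 1) {
  rows <- list()
  add <- function(check, planted, recovered, tol)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, planted = planted, recovered = recovered,
      tolerance = tol,
      pass = is.finite(recovered) && abs(recovered - planted) <= tol,
      stringsAsFactors = FALSE)

  # splay modulus recovery, chi in kT/rad^2
  for (chi in c(5, 15, 30)) {
    ang <- genSplaySample(chi, 1e6, seed = seed + chi)
    fit <- fitSplayModulus(rad2deg(ang))
    add(sprintf("splay_chi_%g", chi), chi, fit$chi, 0.05 * chi * tolScale)
  }
  # bending-modulus combination closed forms
  kc <- combineBendingModulus(data.frame(pairType = c("a", "b"),
                                         phi = c(1, 1), chi = c(8, 24)))
  add("KC_harmonic_8_24", 12, kc$KC_kT, 1e-9 * tolScale)
  kc1 <- combineBendingModulus(data.frame(pairType = "a", phi = 5,
                                          chi = 12))
  add("KC_single_pair", 12, kc1$KC_kT, 1e-9 * tolScale)
  # area compressibility recovery, dyn/cm
  for (ka in c(100, 236, 400)) {
    s <- genAreaSeries(ka, 52.7, 484, 323, 1e5, seed = seed + ka)
    add(sprintf("KA_%g", ka), ka, areaCompressibility(s, 484, 323),
        0.05 * ka * tolScale)
  }
  # lateral diffusion recovery, cm^2/s
  Dtrue <- 2.16e-7
  walk <- genRandomWalk(Dtrue, dt = 10, nSteps = 1000, nParticles = 1000,
                        seed = seed)
  msd <- meanSquareDisplacement(walk, dt = 10)
  Drec <- diffusionCoefficient(msd)$D_cm2s
  add("D_recovery", Dtrue, Drec, 0.03 * Dtrue * tolScale)
  # order-parameter closed forms
  add("SCD_all_z", 1, orderParameter(genChVectors("all_z", 100, seed)),
      1e-6 * tolScale)
  add("SCD_all_xy", -0.5,
      orderParameter(genChVectors("all_xy", 100, seed)), 1e-6 * tolScale)
  add("SCD_magic", 0,
      orderParameter(genChVectors("fixed_theta", 100, seed)),
      1e-6 * tolScale)
  add("SCD_isotropic", 0,
      orderParameter(genChVectors("isotropic", 1e6, seed)),
      0.01 * tolScale)
  # crack detection on planted defects
  slab <- genCrackedSlab(41.2, cracks = list(c(12, 12, 4, 17)))
  cs <- detectCracks(buildOccupancy(slab, voxel = 1.0))
  add("crack_depth_17", 17,
      if (nrow(crackTable(cs))) max(crackTable(cs)$depth) else NA_real_,
      1.0 * tolScale)
  pristine <- genCrackedSlab(41.2)
  add("crack_pristine_zero", 0,
      nrow(crackTable(detectCracks(buildOccupancy(pristine, voxel = 1.0)))),
      0.5 * tolScale)
  hole <- genCrackedSlab(41.2, cracks = list(c(12, 12, 4, 41.2)))
  ch <- crackTable(detectCracks(buildOccupancy(hole, voxel = 1.0)))
  add("crack_through_hole_channel", 1,
      as.numeric(nrow(ch) > 0 && any(ch$channel)), 0.5 * tolScale)
  # contact machinery: cell list vs brute force
  worst <- 0
  withSeed(seed + 7, {
    for (f in 1:100) {
      A <- cbind(stats::runif(500, 0, 60), stats::runif(500, 0, 60),
                 stats::runif(500, 0, 30))
      B <- cbind(stats::runif(500, 0, 60), stats::runif(500, 0, 60),
                 stats::runif(500, 30, 60))
      box <- c(60, 60)
      dcell <- minInteratomicDistance(A, B, box = box)
      dbrute <- bruteMinDistance(A, B, box = box)
      worst <- max(worst, abs(dcell - dbrute))
    }
  })
  add("min_dist_cell_vs_brute", 0, worst, 1e-9 * tolScale)
  # energy closed forms
  e1 <- nonbondedEnergy(c(0, 0, 0), c(10, 0, 0), 1, 1)
  add("coulomb_unit_charges_10A", 33.20636, e1$elec, 1e-4 * tolScale)
  e2 <- nonbondedEnergy(c(0, 0, 0), c(13, 0, 0), 1, 1,
                        ljA = data.frame(sigma = 3, epsilon = 0.1),
                        ljB = data.frame(sigma = 3, epsilon = 0.1))
  add("energy_beyond_cutoff", 0, e2$total, 1e-12 * tolScale)
  e3 <- nonbondedEnergy(c(0, 0, 0), c(3.5, 0, 0), 0, 0,
                        ljA = data.frame(sigma = 3.5, epsilon = 0.2),
                        ljB = data.frame(sigma = 3.5, epsilon = 0.2))
  add("lj_zero_at_sigma", 0, e3$vdw, 1e-12 * tolScale)
  # spatial maps on a flat fixture
  spec <- syntheticSpec(jitter = 0)
  flat <- genBilayer(spec, seed = seed)
  tm <- thicknessMap(flat, frames = 1L, bins = 16L)
  add("thickness_flat_41.2", 41.2, mean(mapValues(tm)), 1e-9 * tolScale)
  dm <- densityMap(flat, anchorSelection(flat, "DPPC"), frames = 1L,
                   bins = 16L)
  b <- boxLengths(flat)
  add("density_mass_conservation",
      length(anchorSelection(flat, "DPPC")),
      sum(mapValues(dm)) * (b[1] / 16) * (b[2] / 16), 1e-6 * tolScale)
  pts <- withSeed(seed + 11,
    cbind(stats::runif(1e4, 0, 200), stats::runif(1e4, 0, 200)))
  gr <- radialDistribution(pts, box = c(200, 200), mode = "lateral",
                           rMax = 50, dr = 1)
  dev <- max(abs(gr$g[gr$r >= 5] - 1))
  add("rdf_ideal_gas_flatness", 0, dev, 0.02 * tolScale)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Brute-force minimum interatomic distance (reference implementation)
#'
#' Direct O(N^2) scan with optional lateral minimum image; the oracle
#' against which the cell-list search is validated.
#'
#' @param A,B n x 3 coordinate matrices.
#' @param box optional numeric(2) lateral box.
#' @return minimum distance, Angstrom.
#' @export
bruteMinDistance <- function(A, B, box = NULL) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], `-`)
    if (!is.null(box) && k <= 2) dk <- dk - round(dk / box[k]) * box[k]
    d2 <- d2 + dk^2
  }
  sqrt(min(d2))
}
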