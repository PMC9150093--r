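test_that("loadSystem reads a toy GRO topology with a multi-frame trajectory", {
  tr <- tinyBilayer(4)
  top <- withr::local_tempfile(fileext = ".gro")
  writeGRO(tr, top)
  trj <- genBilayer(syntheticSpec(lipidsPerLeaflet = 4, jitter = 0.3),
                    nFrames = 2, seed = 2)
  trjf <- withr::local_tempfile(fileext = ".gro")
  writeGRO(trj, trjf)
  sys <- loadSystem(top, trjf)
  expect_s4_class(sys, "SystemTrajectory")
  expect_equal(nFrames(sys), 2)
  la <- assignLeaflets(sys)
  expect_equal(nrow(la), 8)  # 4 lipids per leaflet
  expect_true(all(c("membrane") %in% selection(sys)))
})

test_that("loadSystem rejects an atom-count mismatch and drops solvent", {
  tr <- tinyBilayer(4)
  top <- withr::local_tempfile(fileext = ".gro")
  writeGRO(tr, top)
  small <- genBilayer(syntheticSpec(lipidsPerLeaflet = 3), seed = 1)
  trjf <- withr::local_tempfile(fileext = ".gro")
  writeGRO(small, trjf)
  expect_error(loadSystem(top, trjf), "atom-count mismatch")

  # solvent residues are dropped with a count, unknown ones reported
  at <- atoms(tr)
  sol <- data.frame(id = 0L, name = "OW", resname = "SOL",
                    resid = max(at$resid) + 1L, chain = "W",
                    element = "O", stringsAsFactors = FALSE)
  at2 <- rbind(at[, names(sol)], sol)
  at2$id <- seq_len(nrow(at2))
  mixed <- systemTrajectory(at2, rbind(frameCoords(tr), c(1, 1, 50)),
                            boxLengths(tr))
  g <- withr::local_tempfile(fileext = ".gro")
  writeGRO(mixed, g)
  sys <- loadSystem(g)
  expect_equal(nAtoms(sys), nAtoms(tr))
  expect_equal(sys@metadata$n_dropped_solvent, 1)
})

test_that("writer/loader round trips preserve names, order and coordinates", {
  tr <- genBilayer(syntheticSpec(lipidsPerLeaflet = 10), nFrames = 2,
                   seed = 7)
  for (writer in list(writeGRO, writeMultiPDB)) {
    ext <- if (identical(writer, writeGRO)) ".gro" else ".pdb"
    f <- withr::local_tempfile(fileext = ext)
    writer(tr, f)
    sys <- loadSystem(f)
    expect_equal(atoms(sys)$name, atoms(tr)$name)
    expect_equal(atoms(sys)$resname, atoms(tr)$resname)
    for (fr in 1:2)
      expect_lt(max(abs(frameCoords(sys, fr) - frameCoords(tr, fr))), 1e-3)
  }
})

test_that("membraneCenter: symmetry, translation equivariance, ground truth", {
  tr <- bareTraj(cbind(0, 0, c(-20, 20)),
                 selections = list(membrane = 1:2))
  expect_equal(membraneCenter(tr), 0)
  tr2 <- bareTraj(cbind(0, 0, c(0, 10)), selections = list(membrane = 1:2))
  expect_equal(membraneCenter(tr2), 5)
  # translation equivariance on a random cloud
  set.seed(1)
  xyz <- matrix(runif(300, 0, 50), ncol = 3)
  t1 <- bareTraj(xyz, selections = list(membrane = 1:100))
  t2 <- bareTraj(sweep(xyz, 2, c(0, 0, 13.7), `+`),
                 selections = list(membrane = 1:100))
  expect_equal(membraneCenter(t2), membraneCenter(t1) + 13.7)
  # generator ground truth: bilayer built about z0 = 7.5
  off <- genBilayer(syntheticSpec(lipidsPerLeaflet = 16, jitter = 0),
                    seed = 3, z0 = 7.5)
  expect_equal(membraneCenter(off), 7.5, tolerance = 1e-6)
  expect_error(membraneCenter(tr, sel = integer()), "empty")
})

test_that("leaflet assignment partitions lipids and honours the tie rule", {
  tr <- tinyBilayer(10)
  la <- assignLeaflets(tr)
  expect_equal(sum(la$leaflet == "upper"), 10)
  expect_equal(sum(la$leaflet == "lower"), 10)
  # partition property across jittered replicates
  for (s in 1:5) {
    trj <- tinyBilayer(8, jitter = 0.5, seed = s)
    laj <- assignLeaflets(trj)
    expect_equal(nrow(laj), 16)
    expect_setequal(laj$leaflet, c("upper", "lower"))
    truth <- trj@metadata$truth$leaflets
    expect_equal(laj$leaflet[match(truth$resid, laj$resid)], truth$leaflet)
  }
  # head exactly at z0 goes to the upper leaflet
  at <- data.frame(id = 1:2, name = "P", resname = "DPPC", resid = 1:2,
                   chain = "X", stringsAsFactors = FALSE)
  tie <- systemTrajectory(at, cbind(0, 0, c(0, -5)), c(10, 10, 10),
                          selections = list(membrane = 1:2))
  lat <- assignLeaflets(tie, z0 = 0,
                        lipidDefs = list(DPPC = defaultLipidDefinitions()$DPPC))
  expect_equal(lat$leaflet, c("upper", "lower"))
})

test_that("radius of gyration matches closed forms and the direct sum", {
  one <- bareTraj(matrix(c(1, 2, 3), 1))
  expect_equal(radiusOfGyration(one, 1), 0)
  two <- bareTraj(cbind(c(0, 2), 0, 0), name = c("H1", "H2"))
  expect_equal(radiusOfGyration(two, 1:2), 1.0)
  set.seed(42)
  xyz <- matrix(rnorm(3000), ncol = 3)
  cloud <- bareTraj(xyz, name = sample(c("C1", "O1", "N1", "P"), 1000,
                                       replace = TRUE))
  m <- mtMasses[atoms(cloud)$element]
  expect_equal(radiusOfGyration(cloud, 1:1000), oracleRg(xyz, m),
               tolerance = 1e-9)
  expect_error(radiusOfGyration(cloud, integer()), "empty")
})

test_that("lateral unwrapping removes box jumps", {
  box <- c(10, 10)
  # a walker drifting +1 per frame, wrapped into [0, 10)
  true_x <- seq(0, 25, by = 1)
  pos <- array(0, c(length(true_x), 1, 2))
  pos[, 1, 1] <- true_x %% 10
  un <- unwrapLateral(pos, box)
  expect_equal(un[, 1, 1], true_x)
})
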