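makeProteinBilayer <- function(zProt, nPerLeaflet = 16, seed = 1) {
  # bilayer plus a 3-atom "protein" placed at height zProt above centre
  tr <- tinyBilayer(nPerLeaflet, jitter = 0, seed = seed)
  at <- atoms(tr)
  n0 <- nrow(at)
  prot <- data.frame(id = n0 + (1:3), name = c("N", "CA", "CB"),
                     resname = "ALA", resid = max(at$resid) + 1L,
                     chain = "A", element = c("N", "C", "C"),
                     stringsAsFactors = FALSE)
  allAt <- rbind(at, prot)
  allAt$id <- seq_len(nrow(allAt))
  xyz <- rbind(frameCoords(tr),
               cbind(c(10, 11, 12), 10, zProt))
  systemTrajectory(allAt, xyz, boxLengths(tr),
                   selections = list(membrane = seq_len(n0),
                                     protein = n0 + (1:3)))
}

test_that("minimum z distance and the surface threshold classification", {
  tr <- makeProteinBilayer(zProt = c(25, 30, 40))
  expect_equal(minZDistance(tr, z0 = 0), 25)
  below <- makeProteinBilayer(zProt = -18)
  expect_equal(minZDistance(below, z0 = 0), 18)
  # surface threshold = half the mean P-P thickness (20.6 A here):
  # a protein atom at 19 A is inside the surface
  thr <- surfaceThreshold(tr)
  expect_equal(thr, 20.6, tolerance = 1e-9)
  expect_true(19 < thr)
  expect_false(25 < thr)
})

test_that("cell-list minimum distance equals brute force everywhere", {
  set.seed(41)
  worst <- 0
  for (f in 1:30) {
    nA <- sample(50:300, 1); nB <- sample(50:300, 1)
    A <- cbind(runif(nA, 0, 70), runif(nA, 0, 70), runif(nA, 0, 35))
    B <- cbind(runif(nB, 0, 70), runif(nB, 0, 70), runif(nB, 20, 60))
    box <- c(70, 70)
    worst <- max(worst, abs(minInteratomicDistance(A, B, box = box) -
                              bruteMinDistance(A, B, box = box)))
    # non-periodic variant
    worst <- max(worst, abs(minInteratomicDistance(A, B) -
                              bruteMinDistance(A, B)))
  }
  expect_equal(worst, 0)
  # far-apart clusters exercise the expanding-shell termination
  A <- matrix(rnorm(30, sd = 0.5), ncol = 3)
  B <- matrix(rnorm(30, sd = 0.5), ncol = 3) + 55
  expect_equal(minInteratomicDistance(A, B), bruteMinDistance(A, B))
})

test_that("contact population counts frames at or under the cutoff", {
  # 10 frames: protein descends 30 -> 21.5 above the P sheet at 20.6;
  # min distance to membrane crosses 6.5 A between frames
  base <- tinyBilayer(16, jitter = 0, seed = 2)
  n0 <- nAtoms(base)
  prot <- data.frame(id = n0 + 1L, name = "CA", resname = "GLY",
                     resid = 9999L, chain = "A", element = "C",
                     stringsAsFactors = FALSE)
  at <- rbind(atoms(base), prot)
  at$id <- seq_len(nrow(at))
  heights <- 20.6 + c(10, 9, 8, 7, 6.51, 6.5, 5, 4, 3, 2)
  coords <- lapply(heights, function(h) {
    xy <- frameCoords(base)[at$resid[seq_len(n0)] == 1 &
                              atoms(base)$name == "P", 1:2, drop = FALSE]
    rbind(frameCoords(base), c(xy[1, 1], xy[1, 2], h))
  })
  tr <- systemTrajectory(at, coords,
                         matrix(rep(boxLengths(base), 10), 10, 3,
                                byrow = TRUE),
                         selections = list(membrane = seq_len(n0),
                                           protein = n0 + 1L))
  # directly above a P atom: min distance = height - 20.6
  pop <- contactPopulation(tr, cutoff = 6.5)
  expect_equal(pop, 50)   # frames at 6.5 (inclusive) and below
  popStrict <- contactPopulation(tr, cutoff = 6.5, inclusive = FALSE)
  expect_equal(popStrict, 40)
  expect_equal(contactPopulation(tr, cutoff = 1), 0)
  cs <- contactSeries(tr)
  expect_equal(cs$min_dist, heights - 20.6, tolerance = 1e-9)
  expect_error(contactPopulation(tr, frames = integer()), "empty")
})

test_that("side-chain contacts use COM distance with inclusive boundary", {
  mkRes <- function(resid, chain, x, resname = "ALA") {
    data.frame(id = 0L, name = c("N", "CA", "C", "O", "CB"),
               resname = resname, resid = resid, chain = chain,
               element = c("N", "C", "C", "O", "C"),
               stringsAsFactors = FALSE)
  }
  at <- rbind(mkRes(1, "A", 0), mkRes(2, "B", 0))
  at$id <- seq_len(nrow(at))
  # side chains are the CB atoms (rows 5 and 10)
  xyz <- matrix(0, 10, 3)
  xyz[1:4, 1] <- c(-3, -2, -3, -2)
  xyz[5, ] <- c(0, 0, 0)
  xyz[6:9, 1] <- c(9, 10, 9, 10)
  xyz[10, ] <- c(6.5, 0, 0)
  tr <- systemTrajectory(at, xyz, c(50, 50, 50))
  cm <- sideChainContactMap(tr, 1:5, 6:10)
  expect_true(cm$contacts[1, 1])
  expect_equal(cm$interChain, 1)
  xyz2 <- xyz; xyz2[10, 1] <- 6.6
  tr2 <- systemTrajectory(at, xyz2, c(50, 50, 50))
  expect_false(sideChainContactMap(tr2, 1:5, 6:10)$contacts[1, 1])
  # glycine falls back to CA
  gly <- rbind(data.frame(id = 1:4, name = c("N", "CA", "C", "O"),
                          resname = "GLY", resid = 1L, chain = "A",
                          element = c("N", "C", "C", "O"),
                          stringsAsFactors = FALSE))
  trg <- systemTrajectory(rbind(gly, transform(mkRes(2, "B", 0),
                                               id = 5:9)),
                          rbind(matrix(0, 4, 3),
                                matrix(c(rep(3, 4), 5, rep(0, 10)),
                                       5, 3)),
                          c(50, 50, 50))
  expect_silent(sideChainContactMap(trg, 1:4, 5:9))
})

test_that("side-chain contact matrix equals the brute-force COM loop", {
  set.seed(55)
  nres <- 50
  blocks <- lapply(seq_len(nres), function(r) {
    data.frame(id = 0L, name = c("N", "CA", "C", "O", "CB", "CG"),
               resname = "LEU", resid = r,
               chain = ifelse(r <= 25, "A", "B"),
               element = c("N", "C", "C", "O", "C", "C"),
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, blocks)
  at$id <- seq_len(nrow(at))
  xyz <- matrix(runif(nrow(at) * 3, 0, 40), ncol = 3)
  tr <- systemTrajectory(at, xyz, c(100, 100, 100))
  selA <- which(at$chain == "A"); selB <- which(at$chain == "B")
  cm <- sideChainContactMap(tr, selA, selB, cutoff = 6.5)
  # brute force: mass-weighted COM of CB+CG per residue
  m <- mtMasses["C"]
  want <- matrix(FALSE, 25, 25)
  for (i in 1:25) for (j in 26:50) {
    ci <- colMeans(xyz[at$resid == i & at$name %in% c("CB", "CG"), ])
    cj <- colMeans(xyz[at$resid == j & at$name %in% c("CB", "CG"), ])
    want[i, j - 25] <- sqrt(sum((ci - cj)^2)) <= 6.5
  }
  expect_equal(unname(cm$contacts), want)
  expect_equal(cm$count, sum(want))
})

test_that("nonbonded energy closed forms and cutoffs", {
  # unit charges at 10 A
  e <- nonbondedEnergy(c(0, 0, 0), c(10, 0, 0), 1, 1)
  expect_equal(e$elec, 33.20636, tolerance = 1e-7)
  expect_equal(e$vdw, 0)
  # beyond 12 A both terms vanish
  lj <- data.frame(sigma = 3.5, epsilon = 0.2)
  far <- nonbondedEnergy(c(0, 0, 0), c(13, 0, 0), 1, -1, lj, lj)
  expect_equal(far$total, 0)
  # LJ root at r = sigma (inside the switch-free region)
  root <- nonbondedEnergy(c(0, 0, 0), c(3.5, 0, 0), 0, 0, lj, lj)
  expect_equal(root$vdw, 0)
  # switching function is continuous and monotone to zero on [10, 12]
  r <- seq(9.5, 12.5, by = 0.1)
  vdw <- vapply(r, function(rr)
    nonbondedEnergy(c(0, 0, 0), c(rr, 0, 0), 0, 0, lj, lj)$vdw,
    numeric(1))
  expect_equal(vdw[r > 12], rep(0, sum(r > 12)))
  expect_true(all(abs(diff(vdw)) < 0.05))
  expect_warning(nonbondedEnergy(c(0, 0, 0), c(0.05, 0, 0), 0, 0),
                 "closer than 0.1")
})

test_that("nonbonded energy is symmetric and additive over partitions", {
  set.seed(66)
  A <- matrix(runif(30, 0, 15), ncol = 3)
  B <- matrix(runif(60, 0, 15), ncol = 3)
  qA <- runif(10, -1, 1); qB <- runif(20, -1, 1)
  ljA <- data.frame(sigma = runif(10, 2, 4), epsilon = runif(10, 0.05, 0.3))
  ljB <- data.frame(sigma = runif(20, 2, 4), epsilon = runif(20, 0.05, 0.3))
  eAB <- nonbondedEnergy(A, B, qA, qB, ljA, ljB)
  eBA <- nonbondedEnergy(B, A, qB, qA, ljB, ljA)
  expect_equal(eAB$total, eBA$total)
  half <- 1:10
  e1 <- nonbondedEnergy(A, B[half, ], qA, qB[half], ljA, ljB[half, ])
  e2 <- nonbondedEnergy(A, B[-half, ], qA, qB[-half], ljA, ljB[-half, ])
  expect_equal(e1$total + e2$total, eAB$total)
  # energy decays to zero under rigid separation beyond the cutoff
  offsets <- c(0, 5, 10, 14)
  mags <- vapply(offsets, function(o)
    abs(nonbondedEnergy(A, sweep(B, 2, c(0, 0, 20 + o), `+`), qA, qB,
                        ljA, ljB)$total), numeric(1))
  expect_equal(mags[4], 0)
})

test_that("interchain energy excludes intra-chain terms and is additive", {
  at <- data.frame(id = 1:3, name = "CA", resname = "GLY", resid = 1:3,
                   chain = c("A", "B", "C"), element = "C",
                   charge = c(1, -1, 1), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  tr <- systemTrajectory(at, xyz, c(50, 50, 50),
                         selections = list(protein = 1:3))
  two <- interchainEnergy(tr, sel = 1:2)
  expect_equal(two$elec, -33.20636, tolerance = 1e-7)
  three <- interchainEnergy(tr)
  pair <- function(i, j) nonbondedEnergy(xyz[i, ], xyz[j, ],
                                         at$charge[i], at$charge[j])$elec
  expect_equal(three$elec, pair(1, 2) + pair(1, 3) + pair(2, 3))
  single <- systemTrajectory(at[1, ], xyz[1, , drop = FALSE],
                             c(50, 50, 50),
                             selections = list(protein = 1L))
  expect_error(interchainEnergy(single), "2 chains")
})

test_that("plain-text nonbonded parameter tables are read", {
  f <- system.file("extdata", "example-parameters.txt",
                   package = "membraneTools")
  tab <- readParameterTable(f)
  expect_named(tab, c("name", "charge", "sigma", "epsilon"))
  expect_equal(tab$charge[tab$name == "P"], 1.5)
  expect_equal(tab$sigma[tab$name == "CB"], 3.5)
})
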