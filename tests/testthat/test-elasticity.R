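test_that("directors follow the head-to-tail and cholesterol conventions", {
  defs <- defaultLipidDefinitions()
  # phospholipid: midpoint(P, C2) -> tail COM
  at <- data.frame(id = 1:9,
                   name = c("P", "C2", "C14", "C15", "C16",
                            "C24", "C25", "C26", "H14"),
                   resname = "DPPC", resid = 1L, chain = "X",
                   stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 20), c(0, 0, 18),
               c(0, 0, 6), c(0, 0, 5), c(0, 0, 4),
               c(0, 0, 6), c(0, 0, 5), c(0, 0, 4), c(1, 0, 6))
  tr <- systemTrajectory(at, xyz, c(50, 50, 50),
                         selections = list(membrane = 1:9))
  d <- computeDirectors(tr, 1, lipidDefs = defs["DPPC"])
  expect_equal(unlist(d[1, c("dx", "dy", "dz")], use.names = FALSE),
               c(0, 0, -1))
  # cholesterol: C3 -> C17
  atc <- data.frame(id = 1:3, name = c("O3", "C3", "C17"),
                    resname = "CHL1", resid = 1L, chain = "X",
                    stringsAsFactors = FALSE)
  xc <- rbind(c(0, 0, 10), c(0, 0, 0), c(0, 0, 8))
  trc <- systemTrajectory(atc, xc, c(50, 50, 50),
                          selections = list(membrane = 1:3))
  dc <- computeDirectors(trc, 1, lipidDefs = defs["CHL1"])
  expect_equal(unlist(dc[1, c("dx", "dy", "dz")], use.names = FALSE),
               c(0, 0, 1))
  # generator fixture with straight tails: all directors parallel to z
  tr2 <- tinyBilayer(16, jitter = 0.4, seed = 2)
  d2 <- computeDirectors(tr2)
  expect_equal(abs(d2$dz), rep(1, nrow(d2)), tolerance = 1e-9)
})

test_that("neighbour pairs respect leaflets, cutoff and minimum image", {
  dirs <- data.frame(resid = 1:2, resname = "DPPC",
                     leaflet = c("upper", "upper"),
                     x = c(0, 5), y = 0, dx = 0, dy = 0, dz = 1)
  expect_equal(nrow(neighborPairs(dirs, 10)), 1)
  dirs$leaflet <- c("upper", "lower")
  expect_equal(nrow(neighborPairs(dirs, 10)), 0)
  # minimum image: 2 apart across the boundary of a 100 A box
  wrap <- data.frame(resid = 1:2, resname = "DPPC", leaflet = "upper",
                     x = c(1, 99), y = 0, dx = 0, dy = 0, dz = 1)
  expect_equal(nrow(neighborPairs(wrap, 10, box = c(100, 100))), 1)
  # 200 random lipids: identical pair set to the double loop
  set.seed(21)
  rnd <- data.frame(resid = 1:200, resname = "X",
                    leaflet = sample(c("upper", "lower"), 200, TRUE),
                    x = runif(200, 0, 80), y = runif(200, 0, 80),
                    dx = 0, dy = 0, dz = 1)
  got <- neighborPairs(rnd, 10, box = c(80, 80))
  want <- oraclePairs(rnd, 10, box = c(80, 80))
  expect_equal(nrow(got), nrow(want))
  expect_equal(got[order(got$i, got$j), c("i", "j")],
               as.data.frame(want)[order(want[, 1], want[, 2]), ],
               ignore_attr = TRUE)
})

test_that("splay angle closed forms, symmetry and rotation invariance", {
  expect_equal(splayAngle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(splayAngle(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_equal(splayAngle(c(0, 0, 1),
                          c(0, sin(pi / 9), cos(pi / 9))), 20,
               tolerance = 1e-9)
  set.seed(5)
  for (k in 1:10) {
    v1 <- rnorm(3); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- rnorm(3); v2 <- v2 / sqrt(sum(v2^2))
    expect_equal(splayAngle(v1, v2), splayAngle(v2, v1))
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    expect_equal(splayAngle(as.numeric(R %*% v1), as.numeric(R %*% v2)),
                 splayAngle(v1, v2), tolerance = 1e-9)
  }
  expect_warning(splayAngle(c(0, 0, 2), c(0, 0, 1)), "normalised")
})

test_that("splay-modulus fit inverts the generator", {
  for (chi in c(5, 30)) {
    ang <- genSplaySample(chi, 1e6, seed = 100 + chi)
    fit <- fitSplayModulus(ang * 180 / pi)
    expect_equal(fit$chi, chi, tolerance = 0.05)
    expect_gt(fit$r2, 0.9)
  }
  # near-free membrane: flat PMF, chi ~ 0
  soft <- genSplaySample(0.001, 1e6, seed = 3)
  expect_lt(abs(fitSplayModulus(soft * 180 / pi)$chi), 0.5)
  expect_error(fitSplayModulus(c(5, 6, 40, 50, 60)), "insufficient")
})

test_that("bending-modulus combination is the count-weighted harmonic mean", {
  single <- data.frame(pairType = "a", phi = 7, chi = 12)
  expect_equal(combineBendingModulus(single)$KC_kT, 12)
  two <- data.frame(pairType = c("a", "b"), phi = c(3, 3), chi = c(8, 24))
  expect_equal(combineBendingModulus(two)$KC_kT, 12)
  three <- data.frame(pairType = c("a", "b", "c"), phi = c(2, 1, 1),
                      chi = c(10, 10, 10))
  expect_equal(combineBendingModulus(three)$KC_kT, 10)
  # invariant under common count rescaling; bounded by min/max chi
  set.seed(8)
  for (k in 1:10) {
    st <- data.frame(pairType = letters[1:4], phi = sample(1:50, 4),
                     chi = runif(4, 2, 40))
    kc <- combineBendingModulus(st)$KC_kT
    st2 <- st; st2$phi <- st$phi * 17
    expect_equal(combineBendingModulus(st2)$KC_kT, kc)
    expect_gte(kc, min(st$chi) - 1e-12)
    expect_lte(kc, max(st$chi) + 1e-12)
  }
  # kT -> J conversion at 323 K
  expect_equal(combineBendingModulus(single, temperature = 323)$KC_J,
               12 * 1.380649e-23 * 323)
  expect_error(combineBendingModulus(data.frame(pairType = "a", phi = 0,
                                                chi = NA_real_)),
               "no pair type")
})

test_that("area per lipid averages the two leaflets", {
  tr <- tinyBilayer(16)
  la <- assignLeaflets(tr)
  b <- boxLengths(tr)
  expect_equal(areaPerLipid(tr, 1, la), b[1] * b[2] / 16)
  # asymmetric 180/220 in a 10^4 A^2 box
  la2 <- data.frame(leaflet = rep(c("upper", "lower"), c(180, 220)))
  trBox <- bareTraj(matrix(0, 1, 3), box = c(100, 100, 50))
  expect_equal(areaPerLipid(trBox, 1, la2), mean(c(1e4 / 180, 1e4 / 220)),
               tolerance = 1e-12)
})

test_that("area compressibility inverts the generator and scales exactly", {
  for (ka in c(100, 400)) {
    s <- genAreaSeries(ka, 52.7, 484, 323, 1e5, seed = ka)
    expect_equal(areaCompressibility(s, 484, 323), ka, tolerance = 0.05)
  }
  # doubling the variance at fixed mean halves K_A exactly
  s <- genAreaSeries(236, 52.7, 484, 323, 1e4, seed = 1)
  s2 <- mean(s) + (s - mean(s)) * sqrt(2)
  expect_equal(areaCompressibility(s2, 484, 323),
               areaCompressibility(s, 484, 323) / 2, tolerance = 1e-9)
  expect_error(areaCompressibility(rep(52.7, 10), 484, 323),
               "zero variance")
  expect_error(areaCompressibility(52.7, 484, 323), "at least 2")
})
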