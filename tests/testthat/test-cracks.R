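test_that("occupancy rasterises vdW spheres with lateral periodicity", {
  # single atom of radius 2 at a voxel centre
  at <- data.frame(id = 1L, name = "X", resname = "SLB", resid = 1L,
                   chain = "S", element = "C", radius = 2,
                   stringsAsFactors = FALSE)
  tr <- systemTrajectory(at, cbind(5.5, 5.5, 5.5), c(11, 11, 20),
                         selections = list(membrane = 1L))
  og <- buildOccupancy(tr, zBounds = c(0, 11), voxel = 1)
  occ <- mapValues(og)
  centers <- list(x = (1:11) - 0.5, y = (1:11) - 0.5, z = (1:11) - 0.5)
  want <- array(FALSE, dim(occ))
  for (i in 1:11) for (j in 1:11) for (k in 1:11)
    want[i, j, k] <- sum((c(centers$x[i], centers$y[j], centers$z[k]) -
                            5.5)^2) <= 4
  expect_equal(occ, want)
  # occupancy is invariant under translation by a whole box length
  tr2 <- systemTrajectory(at, cbind(5.5 + 11, 5.5, 5.5), c(11, 11, 20),
                          selections = list(membrane = 1L))
  og2 <- buildOccupancy(tr2, zBounds = c(0, 11), voxel = 1)
  expect_equal(mapValues(og2), occ)
  expect_error(buildOccupancy(tr, zBounds = c(0, 11), voxel = 3),
               "voxel")
})

test_that("planted cracks are recovered with depth within one voxel", {
  slab <- genCrackedSlab(41.2, cracks = list(c(12, 12, 4, 17)))
  cs <- detectCracks(buildOccupancy(slab, voxel = 1.0))
  tab <- crackTable(cs)
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$depth - 17.0), 1.0)
  expect_false(tab$channel)
  # pristine slab: no cracks at all
  expect_equal(nrow(crackTable(detectCracks(
    buildOccupancy(genCrackedSlab(41.2), voxel = 1.0)))), 0)
  # through-hole: flagged as channel, depth ~ full thickness
  hole <- genCrackedSlab(41.2, cracks = list(c(12, 12, 4, 41.2)))
  th <- crackTable(detectCracks(buildOccupancy(hole, voxel = 1.0)))
  expect_true(any(th$channel))
  expect_lt(abs(max(th$depth) - 41.2), 1.0)
  # two cracks at distinct sites: the map maximum sits at the deeper one
  two <- genCrackedSlab(41.2, cracks = list(c(6, 6, 3, 5),
                                            c(18, 18, 3, 17)))
  cs2 <- detectCracks(buildOccupancy(two, voxel = 1.0))
  expect_equal(nrow(crackTable(cs2)), 2)
  dm <- crackDepthMap(cs2)
  v <- mapValues(dm)
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  expect_equal(max(v), max(crackTable(cs2)$depth))
  expect_lt(sqrt(sum((peak - 0.5 - c(18, 18))^2)), 4)
  # footprint of a single crack stays near its cylinder
  one <- crackDepthMap(detectCracks(buildOccupancy(slab, voxel = 1.0)))
  nz <- which(mapValues(one) > 0, arr.ind = TRUE)
  expect_true(all(sqrt((nz[, 1] - 0.5 - 12)^2 +
                         (nz[, 2] - 0.5 - 12)^2) <= 4 + 2.5))
})

test_that("internal cavities not open to the top are not cracks", {
  occ <- array(TRUE, c(8, 8, 10))
  occ[4:5, 4:5, 4:5] <- FALSE          # buried cavity
  g <- new("OccupancyGrid", occupied = occ, voxel = 1,
           origin = c(0.5, 0.5, 0.5), zBounds = c(0, 10), box = c(8, 8))
  expect_equal(nrow(crackTable(detectCracks(g))), 0)
  occ2 <- occ
  occ2[2, 2, 8:10] <- FALSE            # open surface notch
  g2 <- new("OccupancyGrid", occupied = occ2, voxel = 1,
            origin = c(0.5, 0.5, 0.5), zBounds = c(0, 10), box = c(8, 8))
  tab <- crackTable(detectCracks(g2))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$depth, 10 - 7.5)    # bottom voxel centre at z = 7.5
})

test_that("component labelling equals a queue flood fill on random grids", {
  set.seed(91)
  for (k in 1:5) {
    d <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
    occ <- array(runif(prod(d)) < 0.65, d)
    g <- new("OccupancyGrid", occupied = occ, voxel = 1,
             origin = c(0.5, 0.5, 0.5), zBounds = c(0, d[3]),
             box = c(d[1], d[2]))
    cs <- detectCracks(g)
    lab <- oracleFloodFill(occ)
    # oracle cracks: components with a voxel in the top layer
    topLabs <- setdiff(unique(as.vector(lab[, , d[3]])), 0L)
    tab <- crackTable(cs)
    expect_equal(nrow(tab), length(topLabs))
    oracleDepths <- sort(vapply(topLabs, function(l) {
      zmin <- min(arrayInd(which(lab == l), d)[, 3])
      d[3] - (zmin - 0.5)
    }, numeric(1)))
    expect_equal(sort(tab$depth), oracleDepths)
    expect_equal(sort(tab$n_voxels),
                 sort(vapply(topLabs, function(l) sum(lab == l),
                             numeric(1))))
  }
})

test_that("crack depth is monotone under atom deletion and voxel-stable", {
  slab <- genCrackedSlab(41.2, cracks = list(c(12, 12, 4, 10)))
  depthOf <- function(tr, voxel = 1.0) {
    tab <- crackTable(detectCracks(buildOccupancy(tr, voxel = voxel)))
    if (nrow(tab)) max(tab$depth) else 0
  }
  d0 <- depthOf(slab)
  # delete the atoms just under the crack floor: depth can only grow
  xyz <- frameCoords(slab)
  under <- sqrt((xyz[, 1] - 12)^2 + (xyz[, 2] - 12)^2) < 3 &
    xyz[, 3] > 41.2 - 16
  keep <- which(!under)
  at2 <- atoms(slab)[keep, ]
  at2$id <- seq_len(nrow(at2))
  deeper <- systemTrajectory(at2, xyz[keep, ], boxLengths(slab),
                             selections = list(membrane = seq_len(nrow(at2))),
                             metadata = slab@metadata)
  expect_gte(depthOf(deeper), d0)
  # halving the voxel moves the depth estimate by at most one coarse voxel
  expect_lte(abs(depthOf(slab, 0.5) - d0), 1.0)
})
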