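# Independent reference implementations used as oracles. These are kept
# deliberately naive (double loops, direct sums, queue-based flood fill)
# and separate from the package's optimised code paths.

# Direct-sum radius of gyration.
oracleRg <- function(xyz, m) {
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
}

# Double-loop same-leaflet neighbour pairs with lateral minimum image.
oraclePairs <- function(directors, cutoff, box = NULL) {
  n <- nrow(directors)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (directors$leaflet[i] != directors$leaflet[j]) next
    dx <- directors$x[i] - directors$x[j]
    dy <- directors$y[i] - directors$y[j]
    if (!is.null(box)) {
      dx <- dx - round(dx / box[1]) * box[1]
      dy <- dy - round(dy / box[2]) * box[2]
    }
    if (sqrt(dx^2 + dy^2) <= cutoff)
      out[[length(out) + 1]] <- c(i, j)
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(), 0, 2)
}

# Double-loop sliding-origin lateral MSD.
oracleMSD <- function(pos, maxLag) {
  nf <- dim(pos)[1]
  msd <- numeric(maxLag)
  for (lag in seq_len(maxLag)) {
    acc <- 0; cnt <- 0
    for (t0 in seq_len(nf - lag)) {
      d <- pos[t0 + lag, , ] - pos[t0, , ]
      if (is.null(dim(d))) d <- matrix(d, ncol = 2)
      acc <- acc + sum(d^2)
      cnt <- cnt + nrow(d)
    }
    msd[lag] <- acc / cnt
  }
  msd
}

# Queue-based flood fill of empty voxels (6-connectivity, periodic x/y).
# Returns an integer component-label array (0 = occupied).
oracleFloodFill <- function(occ) {
  d <- dim(occ)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(!occ)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                        c(0, 0, 1), c(0, 0, -1))) {
        nb <- ijk + step
        nb[1] <- ((nb[1] - 1) %% d[1]) + 1
        nb[2] <- ((nb[2] - 1) %% d[2]) + 1
        if (nb[3] < 1 || nb[3] > d[3]) next
        w <- nb[1] + d[1] * ((nb[2] - 1) + d[2] * (nb[3] - 1))
        if (!occ[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Largest-remainder apportionment, written independently via sorting.
oracleLargestRemainder <- function(frac, total) {
  exact <- frac * total
  fl <- floor(exact)
  left <- total - sum(fl)
  ord <- order(exact - fl, decreasing = TRUE)
  add <- rep(0, length(frac))
  if (left > 0) add[ord[seq_len(left)]] <- 1
  unname(fl + add)
}

# A tiny membrane-like fixture: two flat P sheets plus full pseudo-lipids,
# built through the generator at a small size.
tinyBilayer <- function(nPerLeaflet = 16, jitter = 0, seed = 1,
                        thickness = 41.2) {
  genBilayer(syntheticSpec(lipidsPerLeaflet = nPerLeaflet,
                           thickness = thickness, jitter = jitter),
             seed = seed)
}

# A SystemTrajectory holding bare atoms at given coordinates.
bareTraj <- function(xyz, box = c(100, 100, 100), resname = "DPPC",
                     name = NULL, resid = NULL, chain = "X",
                     selections = list()) {
  n <- nrow(xyz)
  atoms <- data.frame(id = seq_len(n),
                      name = name %||% rep("P", n),
                      resname = rep(resname, length.out = n),
                      resid = resid %||% seq_len(n),
                      chain = rep(chain, length.out = n),
                      stringsAsFactors = FALSE)
  systemTrajectory(atoms, xyz, box, selections = selections)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
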