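# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood fill is plain-R breadth-first search,
# the smoothing oracle is a direct dense convolution, and the rank-test
# oracles enumerate assignments explicitly.

# brute-force flood fill, labels in first-voxel scan order
floodFillOracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nxt <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k] || lab[i, j, k] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j, k), 1, 3)
    lab[i, j, k] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, as.numeric(cur), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (r in seq_len(nrow(nb))) {
        if (mask[nb[r, 1], nb[r, 2], nb[r, 3]] &&
            lab[nb[r, 1], nb[r, 2], nb[r, 3]] == 0L) {
          lab[nb[r, 1], nb[r, 2], nb[r, 3]] <- nxt
          queue <- rbind(queue, nb[r, , drop = FALSE])
        }
      }
    }
  }
  lab
}

# direct separable convolution with mirrored boundary and 4-sigma kernel,
# written as explicit per-line loops
gaussOracle <- function(arr, sigmaVox) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-0.5 * ((-r):r)^2 / s^2)
    k <- k / sum(k)
    len <- d[ax]
    mirror <- function(idx) {
      while (any(idx < 1 | idx > len)) {
        idx[idx < 1] <- 1 - idx[idx < 1]
        idx[idx > len] <- 2 * len + 1 - idx[idx > len]
      }
      idx
    }
    res <- out
    for (a in seq_len(d[ax])) {
      take <- mirror(a + (-r):r)
      sl <- switch(ax,
                   apply(out[take, , , drop = FALSE], c(2, 3),
                         function(v) sum(v * k)),
                   apply(out[, take, , drop = FALSE], c(1, 3),
                         function(v) sum(v * k)),
                   apply(out[, , take, drop = FALSE], c(1, 2),
                         function(v) sum(v * k)))
      switch(ax, res[a, , ] <- sl, res[, a, ] <- sl, res[, , a] <- sl)
    }
    out <- res
  }
  out
}

# all permutations of 1..n as a matrix (rows)
permsOracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permsOracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# Kruskal-Wallis H via rank sums of squares (independent formula), and
# exact p by full enumeration
kwOracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  stat <- function(xx) {
    r <- rank(xx)
    ssb <- sum(tapply(r, g, function(v) length(v) * (mean(v) - mean(r))^2))
    sst <- sum((r - mean(r))^2)
    if (sst == 0) 0 else (n - 1) * ssb / sst
  }
  H <- stat(x)
  pm <- permsOracle(n)
  ps <- apply(pm, 1, function(p) stat(x[p]))
  list(statistic = H, p.value = mean(ps >= H - 1e-12))
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
mwOracle <- function(a, b) {
  x <- c(a, b)
  m <- length(a); n <- length(b)
  U <- function(sel) sum(rank(x)[sel]) - m * (m + 1) / 2
  u <- U(seq_len(m))
  sels <- utils::combn(m + n, m)
  us <- apply(sels, 2, U)
  p <- min(1, 2 * min(mean(us <= u + 1e-12), mean(us >= u - 1e-12)))
  list(statistic = u, p.value = p)
}

# match segmented junction centroids to ledger synapses within a radius
matchJunctions <- function(junctions, truthLedger, radiusNm = 250) {
  syn <- truthLedger[truthLedger$kind == "synapse", , drop = FALSE]
  ji <- junctionInfo(junctions)
  hit <- vapply(seq_len(nrow(syn)), function(r) {
    d2 <- (ji$cx - syn$cx[r])^2 + (ji$cy - syn$cy[r])^2 + (ji$cz - syn$cz[r])^2
    i <- which.min(d2)
    if (length(i) && sqrt(d2[i]) < radiusNm) i else NA_integer_
  }, integer(1))
  list(synapses = syn, match = hit,
       detection = mean(!is.na(hit)),
       typeAccuracy = {
       ok <- !is.na(hit)
       if (any(ok)) mean(ji$type[hit[ok]] == syn$synapse_type[ok]) else NA_real_
    })
}

# compact generator settings used when a test needs a rendered stack at
# desk scale: default mixture parameters, thin-dendrite geometry
testStackSpec <- function(extent = c(3, 3, 1.5), intensity = 8, seed = 1L,
                          voxel = c(8, 8, 20)) {
  neuropilSpec(volumeExtent = extent, voxelSize = voxel,
               synapseIntensity = intensity,
               geometry = list(dendriteDiameter = c(0.3, 0.45),
                               spineSpacing = 300, minSynapseSep = 350),
               rngSeed = seed)
}
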