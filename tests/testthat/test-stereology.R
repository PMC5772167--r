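test_that("frame construction computes nominal and corrected volumes", {
  b <- rbind(c(0, 0, 0), c(10e3, 10e3, 5e3))
  fr <- makeCountingFrame(b, marginNm = 1e3)
  expect_equal(frameVolume(fr, corrected = FALSE), 8 * 8 * 3)
  expect_equal(frameVolume(fr), 8 * 8 * 3)   # s = 0: corrected = nominal
  fr1 <- makeCountingFrame(b, marginNm = 1e3, shrinkage = 0.1)
  expect_equal(frameVolume(fr1) / frameVolume(fr1, corrected = FALSE),
               1 / 0.9^3, tolerance = 1e-12)
  expect_error(makeCountingFrame(b, marginNm = 6e3), "consumes")
})

test_that("the counting rule respects inclusion and exclusion faces", {
  fr <- makeCountingFrame(rbind(c(0, 0, 0), c(4e3, 4e3, 4e3)), marginNm = 1e3)
  # bounds are [1000, 3000]^3
  pt <- function(x, y, z) matrix(c(x, y, z), 1, 3)
  expect_identical(countInFrame(pt(500, 500, 500), fr), 0L)      # wholly outside
  expect_identical(countInFrame(pt(2000, 2000, 2000), fr), 1L)   # inside
  # spans the low-x inclusion face: counted
  obj <- list(list(p = rbind(c(950, 2000, 2000), c(1050, 2000, 2000)),
                   h = c(60, 60, 60)))
  expect_identical(countInFrame(obj, fr), 1L)
  # spans the high-x exclusion face: not counted
  obj <- list(list(p = rbind(c(2950, 2000, 2000), c(3050, 2000, 2000)),
                   h = c(60, 60, 60)))
  expect_identical(countInFrame(obj, fr), 0L)
  # touches the extended forbidden plane beyond the frame corner
  obj <- list(list(p = rbind(c(2950, 3400, 2000), c(3050, 3400, 2000)),
                   h = c(60, 60, 60)))
  expect_identical(countInFrame(obj, fr), 0L)
})

test_that("tiling the brick counts every object exactly once", {
  set.seed(4)
  L <- c(1000, 1200, 900)
  o <- c(133.7, 271.1, 88.3)
  vx <- c(8, 8, 20)
  for (rep in 1:80) {
    n <- sample(1:12, 1)
    p <- matrix(0, 1, 3)
    while (nrow(p) < n)
      p <- unique(rbind(p, p[sample(nrow(p), 1), ] +
                          vx * sample(c(-1, 0, 1), 3, replace = TRUE)))
    obj <- sweep(p, 2, runif(3, 0, 4000), "+")
    lo0 <- floor((apply(obj, 2, min) - 60 - o) / L)
    hi0 <- ceiling((apply(obj, 2, max) + 60 - o) / L)
    tot <- 0L
    for (ix in lo0[1]:hi0[1]) for (iy in lo0[2]:hi0[2]) for (iz in lo0[3]:hi0[3]) {
      lo <- o + c(ix, iy, iz) * L
      fr <- makeCountingFrame(rbind(lo - 1, lo + L + 1), marginNm = 1)
      tot <- tot + countInFrame(list(list(p = obj, h = vx / 2)), fr)
    }
    expect_identical(tot, 1L)
  }
})

test_that("the density estimator is unbiased for a Poisson point process", {
  set.seed(17)
  lambda <- 0.89            # synapses per um^3
  ext <- c(8e3, 8e3, 6e3)   # nm
  fr <- makeCountingFrame(rbind(c(0, 0, 0), ext), marginNm = 700)
  nFrames <- 200
  dens <- numeric(nFrames)
  for (r in seq_len(nFrames)) {
    nPts <- rpois(1, lambda * prod(ext) / 1e9)
    pts <- cbind(runif(nPts, 0, ext[1]), runif(nPts, 0, ext[2]),
                 runif(nPts, 0, ext[3]))
    dens[r] <- synapseDensity(countInFrame(pts, fr), fr)
  }
  se <- sd(dens) / sqrt(nFrames)
  expect_lt(abs(mean(dens) - lambda), 3 * se)
})

test_that("density is count over corrected volume and scales linearly", {
  fr <- makeCountingFrame(rbind(c(0, 0, 0), c(10e3, 10e3, 5e3)), marginNm = 0,
                          shrinkage = 0.1)
  expect_identical(synapseDensity(0, fr), 0)
  expect_equal(synapseDensity(160, fr), 160 / (500 / 0.9^3))
  expect_equal(synapseDensity(80, fr) * 2, synapseDensity(160, fr))
  # the reference census mean frame: 160 junctions in 181.62 um^3
  fr2 <- makeCountingFrame(rbind(c(0, 0, 0), c(1e3 * 181.62, 1e3, 1e3)),
                           marginNm = 0)
  expect_equal(synapseDensity(160, fr2), 160 / 181.62, tolerance = 1e-12)
})

test_that("density survives reslicing of the underlying stack", {
  fx <- renderReferenceFixture("two_blobs")
  js <- segmentStack(fx$volume)
  fr <- makeCountingFrame(fx$volume, marginNm = 50)
  n1 <- countInFrame(js, fr)
  vr <- reslice(fx$volume, "z")
  jsr <- segmentStack(vr)
  frr <- makeCountingFrame(vr, marginNm = 50)
  expect_identical(countInFrame(jsr, frr), n1)
  expect_equal(frameVolume(frr), frameVolume(fr))
})
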