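test_that("zero synapse intensity yields dendrites only", {
  sp <- neuropilSpec(volumeExtent = c(2, 2, 1.6), voxelSize = c(10, 10, 25),
                     synapseIntensity = 0, rngSeed = 3L)
  out <- generateStack(sp)
  led <- ledger(out$truth)
  expect_true(all(led$kind == "dendrite"))
  expect_identical(sum(led$kind == "synapse"), 0L)
  expect_gt(max(labelVolume(out$truth)), 0)
})

test_that("generation is bit-identical under a fixed spec and seed", {
  sp <- testStackSpec(extent = c(2, 2, 1.2), intensity = 6, seed = 11L)
  a <- generateStack(sp)
  b <- generateStack(sp)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(labelVolume(a$truth), labelVolume(b$truth))
  expect_identical(ledger(a$truth), ledger(b$truth))
})

test_that("a volume too small for a dendrite is a degenerate input", {
  sp <- neuropilSpec(volumeExtent = c(0.4, 0.4, 0.4), rngSeed = 1L)
  expect_error(generateStack(sp), "too small")
})

test_that("ledger and label volume are mutually consistent", {
  sp <- testStackSpec(extent = c(2.5, 2.5, 1.2), intensity = 8, seed = 5L)
  out <- generateStack(sp)
  led <- ledger(out$truth)
  lab <- labelVolume(out$truth)
  present <- sort(unique(as.vector(lab[lab != 0L])))
  expect_true(all(present %in% led$id))
  counts <- table(factor(lab[lab != 0L], levels = led$id))
  # every non-dendrite ledger object is rendered; dendrites are laid with
  # in-volume length so they are too
  expect_true(all(counts > 0))
})

test_that("border-touch flags agree with an exhaustive voxel scan", {
  sp <- testStackSpec(extent = c(2.5, 2.5, 1.2), intensity = 8, seed = 9L)
  out <- generateStack(sp)
  led <- ledger(out$truth)
  lab <- labelVolume(out$truth)
  d <- dim(lab)
  faceIds <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                      lab[, , 1], lab[, , d[3]]))
  faceIds <- faceIds[faceIds != 0L]
  expect_setequal(led$id[led$touches_border], faceIds)
})

test_that("synapse voxels are darker than background minus two noise sd", {
  sp0 <- testStackSpec(extent = c(2, 2, 1.2), intensity = 8, seed = 13L)
  clean <- neuropilSpec(volumeExtent = sp0@volumeExtent, voxelSize = sp0@voxelSize,
                        synapseIntensity = sp0@synapseIntensity,
                        noise = c(0, 0),
                        geometry = sp0@geometry, rngSeed = sp0@rngSeed)
  out <- generateStack(clean)
  led <- ledger(out$truth)
  lab <- labelVolume(out$truth)
  img <- voxelData(out$volume)
  synIds <- led$id[led$kind == "synapse"]
  expect_gt(length(synIds), 0)
  synVox <- img[lab %in% synIds]
  bg <- clean@geometry$background
  expect_true(all(synVox < bg - 2 * 12))
})

test_that("generator mixtures calibrate to the configured fractions", {
  # ledger-only draws across seeds; bands are 3 SE of the pooled totals
  nAS <- 0; nSyn <- 0; nSpineTarget <- 0; nMulti <- 0; nSpines <- 0
  for (seed in 1:20) {
    sp <- neuropilSpec(volumeExtent = c(10, 10, 4), rngSeed = seed)
    led <- ledger(generateStack(sp, render = FALSE)$truth)
    syn <- led[led$kind == "synapse", ]
    nSyn <- nSyn + nrow(syn)
    nAS <- nAS + sum(syn$synapse_type == "AS")
    nSpineTarget <- nSpineTarget + sum(syn$target %in% c("head", "neck"))
    spineIds <- unique(syn$parent_spine_id[!is.na(syn$parent_spine_id)])
    nSpines <- nSpines + length(spineIds)
    tab <- table(syn$parent_spine_id)
    nMulti <- nMulti + sum(tab > 1)
  }
  se <- function(p) sqrt(p * (1 - p) / nSyn)
  expect_lt(abs(nAS / nSyn - 0.9028), 3 * se(0.9028))
  pSpine <- 0.9028 * 0.8361 + (1 - 0.9028) * 0.2547
  expect_lt(abs(nSpineTarget / nSyn - pSpine), 3 * se(pSpine) + 0.01)
  seSp <- sqrt(0.0557 * (1 - 0.0557) / nSpines)
  expect_lt(abs(nMulti / nSpines - 0.0557), 3 * seSp + 0.005)
})

test_that("reference fixtures carry the advertised ground truth", {
  fx <- renderReferenceFixture("single_AS_on_head")
  led <- ledger(fx$truth)
  syn <- led[led$kind == "synapse", ]
  expect_identical(nrow(syn), 1L)
  expect_identical(syn$synapse_type, "AS")
  expect_identical(syn$target, "head")

  fx <- renderReferenceFixture("two_blobs")
  lab <- labelVolume(fx$truth)
  expect_setequal(unique(as.vector(lab[lab != 0])), c(1L, 2L))

  fx <- renderReferenceFixture("truncated_spine")
  led <- ledger(fx$truth)
  expect_true(led$touches_border[led$kind == "spine"])

  fx <- renderReferenceFixture("multi_synapse_spine")
  led <- ledger(fx$truth)
  expect_identical(sum(led$kind == "synapse"), 2L)
  expect_setequal(led$synapse_type[led$kind == "synapse"], c("AS", "SS"))

  expect_error(renderReferenceFixture("no_such_fixture"))
})

test_that("stack TIFF round trip preserves image and metadata", {
  fx <- renderReferenceFixture("two_blobs")
  path <- file.path(tempdir(), "fixture.tif")
  writeStack(fx$volume, path)
  back <- readStack(path)
  expect_equal(voxelSize(back), voxelSize(fx$volume))
  expect_equal(dim(voxelData(back)), dim(voxelData(fx$volume)))
  expect_lt(max(abs(voxelData(back) - voxelData(fx$volume))), 1.01)
  unlink(c(path, sub("\\.tif$", ".json", path)))
})
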