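test_that("constructed fixtures annotate as built", {
  fx <- renderReferenceFixture("single_AS_on_head")
  at <- assignTargets(fx$truth)
  expect_identical(at$target, "head")
  expect_identical(at$dendrite_class, "spiny")
  expect_identical(at$parent_dendrite_id, 1L)

  fx <- renderReferenceFixture("single_SS_on_shaft")
  at <- assignTargets(fx$truth)
  expect_identical(at$target, "shaft")
  expect_identical(at$dendrite_class, "not_determined")

  fx <- renderReferenceFixture("truncated_spine")
  at <- assignTargets(fx$truth)
  expect_identical(at$target, "truncated")
  expect_true(is.na(at$parent_spine_id))
  expect_true(is.na(at$parent_dendrite_id))
  expect_true(is.na(at$dendrite_class))
})

test_that("trace resolves interior spines and truncates clipped ones", {
  fx <- renderReferenceFixture("single_AS_on_head")
  expect_identical(traceToParent(2L, fx$truth), 1L)
  fx <- renderReferenceFixture("truncated_spine")
  expect_identical(traceToParent(2L, fx$truth), "truncated")
  expect_error(traceToParent(999L, fx$truth), "unknown")
})

test_that("dendrite spininess requires an attached in-volume spine", {
  fx <- renderReferenceFixture("single_AS_on_head")
  expect_identical(classifyDendrite(1L, fx$truth), "spiny")
  fx <- renderReferenceFixture("single_SS_on_shaft")
  expect_identical(classifyDendrite(1L, fx$truth), "not_determined")
  # a dendrite whose only spine cannot be traced inside the stack is not
  # proven spiny
  fx <- renderReferenceFixture("truncated_spine")
  expect_identical(classifyDendrite(1L, fx$truth), "not_determined")
})

test_that("every synapse receives exactly one target and counts add up", {
  sp <- testStackSpec(extent = c(2.5, 2.5, 1.2), intensity = 8, seed = 31L)
  gen <- generateStack(sp)
  at <- assignTargets(gen$truth)
  led <- ledger(gen$truth)
  expect_identical(nrow(at), sum(led$kind == "synapse"))
  expect_true(all(at$target %in% c("head", "neck", "shaft", "truncated")))
  expect_identical(sum(table(at$target)), nrow(at))
})

test_that("annotation of generator output is faithful bookkeeping", {
  sp <- testStackSpec(extent = c(3, 3, 1.5), intensity = 8, seed = 42L)
  gen <- generateStack(sp)
  led <- ledger(gen$truth)
  syn <- led[led$kind == "synapse", ]
  at <- assignTargets(gen$truth)
  m <- merge(at, syn[, c("id", "target", "parent_dendrite_id", "parent_spine_id")],
             by.x = "synapse_id", by.y = "id", suffixes = c(".ann", ".led"))
  nt <- m[m$target.ann != "truncated", ]
  expect_identical(nt$target.ann, nt$target.led)
  expect_identical(as.integer(nt$parent_dendrite_id.ann),
                   as.integer(nt$parent_dendrite_id.led))
  # truncated assignments occur only for border-touching spines
  tr <- m[m$target.ann == "truncated", ]
  if (nrow(tr)) {
    spRows <- match(syn$parent_spine_id[match(tr$synapse_id, syn$id)], led$id)
    expect_true(all(led$touches_border[spRows]))
  }
})

test_that("truncation frequency falls as the stack grows", {
  sizes <- c(2.0, 3.0, 4.4)
  seedsOf <- list(1:12, 1:6, 1:3)   # comparable spine totals per size
  frac <- vapply(seq_along(sizes), function(i) {
    hits <- 0; tot <- 0
    for (seed in seedsOf[[i]]) {
      sp <- neuropilSpec(volumeExtent = rep(sizes[i], 3), voxelSize = c(8, 8, 20),
                         synapseIntensity = 8,
                         geometry = list(dendriteDiameter = c(0.3, 0.45),
                                         spineSpacing = 300, minSynapseSep = 350),
                         rngSeed = seed)
      led <- ledger(generateStack(sp, render = FALSE)$truth)
      spn <- led[led$kind == "spine", ]
      hits <- hits + sum(!spn$neck_attached); tot <- tot + nrow(spn)
    }
    hits / tot
  }, numeric(1))
  expect_lt(frac[2], frac[1])
  expect_lt(frac[3], frac[1])
})

test_that("spine profiles reproduce the single/multiple categories", {
  fx <- renderReferenceFixture("multi_synapse_spine")
  pr <- profileSpines(assignTargets(fx$truth))
  expect_identical(nrow(pr), 1L)
  expect_identical(pr$category, "one_AS_one_SS")
  expect_true(pr$multiple)

  fx <- renderReferenceFixture("single_AS_on_head")
  pr <- profileSpines(assignTargets(fx$truth))
  expect_identical(pr$category, "one_AS")
  expect_false(pr$multiple)

  # direct construction: categories and the overflow warning
  mk <- function(spine, type) data.frame(
    synapse_id = seq_along(type), synapse_type = type, target = "head",
    parent_spine_id = spine, parent_dendrite_id = 1L,
    dendrite_class = "spiny", stringsAsFactors = FALSE)
  pr <- profileSpines(mk(rep(1L, 3), c("AS", "AS", "SS")))
  expect_identical(pr$category, "two_AS_one_SS")
  expect_warning(profileSpines(mk(rep(1L, 4), rep("AS", 4))), "overflow")
  counts <- spineProfileCounts(profileSpines(mk(c(1L, 1L, 2L), c("AS", "SS", "SS"))))
  expect_identical(counts[["one_AS_one_SS"]], 1L)
  expect_identical(counts[["one_SS"]], 1L)
})

test_that("reference profile counts rebuild the published shares", {
  t4 <- buildTable4(referenceCounts("spine_profiles"))
  expect_equal(t4["single", "percent"], 94.43, tolerance = 0.005)
  expect_equal(t4["one_AS", "percent"], 98.65, tolerance = 0.005)
  expect_equal(t4["two_AS", "percent"], 57.48, tolerance = 0.005)
})
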