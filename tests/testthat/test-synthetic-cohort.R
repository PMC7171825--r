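# connectivity check: every region must form one 6-connected component
regionsAreContiguous <- function(atlas) {
  labs <- regionLabels(atlas)
  dims <- dim(labs)
  for (id in regionIds(atlas)) {
    vox <- which(labs == id)
    coords <- arrayInd(vox, dims)
    seen <- logical(length(vox))
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (f in frontier) {
        d <- abs(coords - rep(coords[f, ], each = nrow(coords)))
        nb <- which(rowSums(d) == 1L & !seen)
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    if (!all(seen)) return(FALSE)
  }
  TRUE
}

test_that("atlas partitions the grid into non-empty contiguous regions", {
  atl <- makeAtlas(c(10, 10, 10), 246, seed = 3)
  labs <- regionLabels(atl)
  expect_equal(nRegions(atl), 246)
  expect_true(all(tabulate(labs, 246) >= 1))
  expect_true(all(labs >= 1))               # every voxel labelled
  expect_true(regionsAreContiguous(atl))

  # forced partition: one voxel per region
  tiny <- makeAtlas(c(2, 2, 1), 4, seed = 1)
  expect_equal(sort(as.integer(regionLabels(tiny))), 1:4)

  expect_identical(regionLabels(makeAtlas(c(5, 4, 3), 17, seed = 9)),
                   regionLabels(makeAtlas(c(5, 4, 3), 17, seed = 9)))
  expect_error(makeAtlas(c(2, 2, 1), 5), "cannot partition")
})

test_that("cohort generation honours group sizes, determinism and planted decline", {
  cht <- smallCohort()
  expect_s4_class(cht, "SyntheticCohort")
  expect_equal(nrow(cht@subjects), 14)
  expect_equal(as.integer(table(cht@subjects$group)[c("sMCI", "pMCI")]),
               c(8L, 6L))
  expect_equal(length(cht@controlImages), 6)
  expect_true(all(vapply(cht@images, length, 1L) == 4L))

  # study-sized subject table
  big <- cohortConfig(gridDims = c(7, 6, 6), nRegions = 30,
                      nAffectedRegions = 5, nReferenceRegions = 4)
  expect_equal(nrow(generateCohort(big)@subjects), 79)

  # bit-identical regeneration under the same seed
  cht2 <- generateCohort(smallCohortConfig())
  expect_identical(cht@subjects, cht2@subjects)
  expect_identical(
    voxelValues(cht@images[[3]][["m12"]]),
    voxelValues(cht2@images[[3]][["m12"]]))

  # pMCI mean intensity in affected regions declines monotonically,
  # checked by brute-force voxel averaging per region per timepoint
  pmci <- cht@subjects$subject_id[cht@subjects$group == "pMCI"]
  aff <- cht@truth$affectedRegions
  tpMeans <- sapply(timepointNames(4), function(tp) {
    perSubj <- sapply(pmci, function(sid)
      mean(bruteForceRegionMeans(cht@images[[sid]][[tp]], cht@atlas)[aff]))
    mean(perSubj)
  })
  expect_true(all(diff(tpMeans) < 0))
})

test_that("zero decline and zero noise yield identical images over time", {
  cfg <- smallCohortConfig(declinePerTpPmci = 0, declinePerTpSmci = 0,
                           backgroundDecline = 0, noiseSd = 0)
  cht <- generateCohort(cfg)
  s <- cht@images[[1]]
  for (tp in c("m6", "m12", "m18"))
    expect_identical(voxelValues(s[[tp]]), voxelValues(s[["bl"]]))
  # all downstream differences vanish
  st <- lapply(timepointNames(4), function(tp)
    parcellate(s[[tp]], cht@atlas))
  dyn <- dynamicFeatures(st)
  expect_true(all(vapply(dyn$D, function(d) all(d == 0), TRUE)))
})

test_that("with zero noise the tp1-baseline change is nonzero exactly on affected regions", {
  cfg <- smallCohortConfig(backgroundDecline = 0, noiseSd = 0)
  cht <- generateCohort(cfg)
  for (sid in cht@subjects$subject_id[c(1, nrow(cht@subjects))]) {
    bl <- parcellate(cht@images[[sid]][["bl"]], cht@atlas)
    m6 <- parcellate(cht@images[[sid]][["m6"]], cht@atlas)
    changed <- which(abs(bl - m6) > 1e-9)
    expect_equal(sort(unname(changed)), cht@truth$affectedRegions)
  }
})

test_that("regressing intensity on age recovers the planted age effect", {
  cfg <- cohortConfig(gridDims = c(6, 6, 4), nRegions = 12,
                      nAffectedRegions = 3, nReferenceRegions = 2,
                      noiseSd = 2, seed = 5)
  cht <- generateCohort(cfg)
  y <- vapply(cht@images, function(s) {
    im <- s[["bl"]]
    mean(voxelValues(im)[brainMask(im)])
  }, 0)
  fit <- summary(lm(y ~ age + gender, data = cht@subjects))
  est <- fit$coefficients["age", ]
  expect_lt(abs(est["Estimate"] - cfg@ageEffect), 2 * est["Std. Error"])
})

test_that("config invariants are enforced", {
  expect_error(cohortConfig(nRegions = 5, nAffectedRegions = 4,
                            nReferenceRegions = 3), "<= nRegions")
  expect_error(cohortConfig(noiseSd = -1), "noiseSd")
  expect_error(cohortConfig(nTimepoints = 1), "nTimepoints")
  expect_error(cohortConfig(gridDims = c(2, 2, 2), nRegions = 20,
                            nAffectedRegions = 3, nReferenceRegions = 2),
               "fewer voxels")
})
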