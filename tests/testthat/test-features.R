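test_that("parcellation averages in-mask voxels per region", {
  atl <- makeAtlas(c(4, 4, 2), 8, seed = 1)
  expect_equal(parcellate(voxelImage(array(3.5, c(4, 4, 2))), atl),
               rep(3.5, 8), ignore_attr = TRUE)

  # single-region atlas: value equals global in-mask mean
  one <- new("AtlasLabelMap", labels = array(1L, c(3, 3, 3)))
  set.seed(1)
  img <- voxelImage(array(rnorm(27, 100, 10), c(3, 3, 3)))
  expect_equal(parcellate(img, one), mean(voxelValues(img)),
               ignore_attr = TRUE)

  # random 6-voxel image with 2 planted labels, hand-summed oracle
  labs <- array(c(1L, 1L, 2L, 2L, 2L, 1L), c(6, 1, 1))
  atl2 <- new("AtlasLabelMap", labels = labs)
  vals <- array(c(4, 8, 1, 3, 5, 6), c(6, 1, 1))
  got <- parcellate(voxelImage(vals), atl2)
  expect_equal(got, c((4 + 8 + 6) / 3, (1 + 3 + 5) / 3),
               ignore_attr = TRUE)
  expect_equal(got, bruteForceRegionMeans(voxelImage(vals), atl2),
               ignore_attr = TRUE)

  # region fully outside the brain mask is an explicit, named error
  mask <- array(TRUE, c(6, 1, 1)); mask[c(3, 4, 5)] <- FALSE
  expect_error(parcellate(voxelImage(vals, mask), atl2), "2")
})

test_that("confound residualization is exact least squares", {
  set.seed(2)
  cov <- data.frame(age = runif(20, 55, 85), gender = rbinom(20, 1, 0.5))
  x <- cbind(lin = 3 * cov$age - 7,
             ind = rnorm(20),
             mix = 0.5 * cov$age + 2 * cov$gender + rnorm(20))
  res <- residualizeConfounds(x, cov)
  expect_lt(max(abs(res[, "lin"])), 1e-9)
  expect_equal(res[, "ind"],
               unname(resid(lm(x[, "ind"] ~ cov$age + cov$gender))),
               tolerance = 1e-10, ignore_attr = TRUE)
  # residuals orthogonal to the covariate columns (normal-equations oracle)
  for (j in colnames(res)) {
    expect_lt(abs(sum(res[, j] * cov$age)), 1e-8)
    expect_lt(abs(sum(res[, j] * cov$gender)), 1e-8)
    expect_lt(abs(sum(res[, j])), 1e-8)
  }
  # variable independent of covariates: residual ~ centered variable
  expect_equal(cor(res[, "ind"], x[, "ind"] - mean(x[, "ind"])), 1,
               tolerance = 0.2)

  expect_error(residualizeConfounds(x, transform(cov, gender = 1)),
               "rank-deficient")
  expect_error(residualizeConfounds(x[1:2, ], cov[1:2, ]), "3 subjects")
})

test_that("voxel-level and region-level residualization commute with parcellation", {
  cht <- smallCohort()
  tp <- "m6"
  imgs <- lapply(cht@images, `[[`, tp)
  mask <- brainMask(imgs[[1]])
  vox <- t(vapply(imgs, function(im) voxelValues(im)[mask], numeric(sum(mask))))
  cov <- cht@subjects[, c("age", "gender")]
  voxRes <- residualizeConfounds(vox, cov)
  # rebuild images from voxel residuals, then parcellate
  regFromVox <- t(vapply(seq_len(nrow(voxRes)), function(i) {
    arr <- array(0, dim(mask)); arr[mask] <- voxRes[i, ]
    parcellate(voxelImage(arr, mask), cht@atlas)
  }, numeric(nRegions(cht@atlas))))
  reg <- t(vapply(imgs, function(im) parcellate(im, cht@atlas),
                  numeric(nRegions(cht@atlas))))
  regRes <- residualizeConfounds(reg, cov)
  expect_equal(regFromVox, regRes, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("dynamic features obey the difference and ratio definitions", {
  # equal timepoints: D = R = 0
  same <- dynamicFeatures(list(bl = c(a = 2, b = 3), m6 = c(a = 2, b = 3)))
  expect_equal(unname(same$D[["1"]]), c(0, 0))
  expect_equal(unname(same$R[["1"]]), c(0, 0))

  # direct substitution: T_bl = 2.0, T_1 = 1.5 -> D = 0.5, R = 0.25
  d <- dynamicFeatures(list(bl = c(r = 2.0), m6 = c(r = 1.5)))
  expect_equal(unname(d$D[["1"]]), 0.5)
  expect_equal(unname(d$R[["1"]]), 0.25)

  # random positive vectors: R by independent scalar division, and the
  # identity R_i * T_bl = D_i element-wise
  set.seed(3)
  tpls <- lapply(1:4, function(i) runif(30, 0.5, 1.5))
  names(tpls) <- timepointNames(4)
  dyn <- dynamicFeatures(tpls)
  for (i in 1:3) {
    manual <- vapply(seq_len(30), function(j)
      (tpls[[1]][j] - tpls[[i + 1]][j]) / tpls[[1]][j], 0)
    expect_equal(dyn$R[[as.character(i)]], manual, tolerance = 1e-14)
    expect_equal(dyn$R[[as.character(i)]] * tpls[[1]],
                 dyn$D[[as.character(i)]], tolerance = 1e-14)
  }

  # permutation equivariance over regions
  perm <- sample(30)
  dynP <- dynamicFeatures(lapply(tpls, `[`, perm))
  expect_equal(dynP$D[["2"]], dyn$D[["2"]][perm])

  expect_error(dynamicFeatures(list(bl = c(0), m6 = c(1))), "eps")
  expect_error(dynamicFeatures(list(bl = c(1, 2), m6 = c(1))), "region set")
})

test_that("noise-free multiplicative decline gives R_i = 1 - (1-d)^i", {
  cfg <- smallCohortConfig(noiseSd = 0, backgroundDecline = 0,
                           ageEffect = 0, genderEffect = 0)
  cht <- generateCohort(cfg)
  sid <- cht@subjects$subject_id[cht@subjects$group == "pMCI"][1]
  st <- lapply(timepointNames(4), function(tp)
    parcellate(cht@images[[sid]][[tp]], cht@atlas))
  dyn <- dynamicFeatures(st)
  d <- cfg@declinePerTpPmci
  for (i in 1:3)
    expect_equal(unname(dyn$R[[as.character(i)]][cht@truth$affectedRegions]),
                 rep(1 - (1 - d)^i, length(cht@truth$affectedRegions)),
                 tolerance = 1e-10)
})

test_that("cognitive block is an exact pass-through with fixed column order", {
  cht <- generateCohort(cohortConfig(gridDims = c(6, 6, 4), nRegions = 12,
                                     nAffectedRegions = 3,
                                     nReferenceRegions = 2, seed = 8))
  cg <- assembleCognitive(cht@subjects)
  expect_equal(dim(cg), c(79, 8))
  expect_equal(colnames(cg),
               c("mmse_bl", "mmse_m6", "mmse_m12", "mmse_m18",
                 "adas_bl", "adas_m6", "adas_m12", "adas_m18"))

  one <- data.frame(subject_id = "X", mmse_bl = 30, mmse_m6 = 30,
                    mmse_m12 = 30, mmse_m18 = 30, adas_bl = 0,
                    adas_m6 = 0, adas_m12 = 0, adas_m18 = 0)
  expect_equal(unname(assembleCognitive(one)[1, ]),
               c(30, 30, 30, 30, 0, 0, 0, 0))

  bad <- cht@subjects; bad$adas_m12[3] <- NA
  expect_error(assembleCognitive(bad), bad$subject_id[3])

  # planted trajectory: pMCI mean ADAS slope exceeds sMCI mean slope
  slope <- (cht@subjects$adas_m18 - cht@subjects$adas_bl) / 3
  expect_gt(mean(slope[cht@subjects$group == "pMCI"]),
            mean(slope[cht@subjects$group == "sMCI"]))
})

test_that("feature blocks concatenate with block bookkeeping intact", {
  set.seed(5)
  n <- 10
  subj <- data.frame(subject_id = sprintf("S%02d", 1:n),
                     group = rep(c("sMCI", "pMCI"), each = 5),
                     age = runif(n, 55, 85), gender = rbinom(n, 1, 0.5))
  mk <- function(p) matrix(rnorm(n * p), n, p)
  statics <- setNames(lapply(1:4, function(i) mk(246)),
                      c("Static_mbl", "Static_m6", "Static_m12", "Static_m18"))
  dyns <- setNames(lapply(1:3, function(i) mk(246)),
                   paste0("Dynamic_", 1:3))
  fs <- FeatureSet(c(statics, dyns, list(Cognitive = mk(8))), subj)

  sAll <- selectBlocks(fs, standardFeatureCombinations()$Static_all)
  expect_equal(nrow(sAll), 4 * 246)
  dAll <- selectBlocks(fs, standardFeatureCombinations()$Dynamic_all)
  expect_equal(nrow(dAll), 738)  # D blocks only, rates excluded
  expect_equal(names(featureBlocks(dAll)), paste0("Dynamic_", 1:3))
  expect_equal(ncol(featureMatrix(sAll)), 984)

  expect_error(selectBlocks(fs, c("Dynamic_1", "Dynamic_1")), "duplicated")
  expect_error(selectBlocks(fs, "NoSuchBlock"), "unknown")
  expect_error(FeatureSet(list(A = mk(3), A = mk(3)), subj), "uniquely named")
  expect_error(FeatureSet(list(A = mk(3), B = mk(3)[1:5, ]), subj),
               "subject ordering")

  combos <- standardFeatureCombinations()
  expect_setequal(
    c("Static_mbl", "Static_m6", "Static_m12", "Static_m18", "Static_all",
      "Dynamic_1", "Dynamic_2", "Dynamic_3", "R1", "R2", "R3",
      "Dynamic_all", "Cognitive", "Static & Dynamic", "Static & Cognitive",
      "Dynamic & Cognitive", "All"),
    names(combos))
  expect_true(all(c("R1", "R2", "R3") %in%
                    standardFeatureCombinations(TRUE)$Dynamic_all))
})
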