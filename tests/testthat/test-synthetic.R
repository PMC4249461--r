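test_that("identical config and seed give bit-identical cohorts", {
    cfg <- syntheticConfig(nSubjects = 12, seed = 42)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(a$cohort, b$cohort)
    expect_identical(a$images@intensities, b$images@intensities)
    expect_identical(a$truth, b$truth)
    n <- generateNullCohort(cfg)
    expect_identical(n$cohort, generateNullCohort(cfg)$cohort)
    expect_null(n$truth)
})

test_that("invalid configurations are rejected naming the field", {
    expect_error(syntheticConfig(nSubjects = 3), "nSubjects")
    expect_error(syntheticConfig(10, imageShape = c(3, 14, 12)),
                 "imageShape")
    expect_error(syntheticConfig(10, femaleFraction = 1.2),
                 "femaleFraction")
    expect_error(syntheticConfig(10, apoePrevalence = -0.1),
                 "apoePrevalence")
    expect_error(syntheticConfig(10, noiseSd = -1), "noiseSd")
})

test_that("cohort marginals follow the configured distributions", {
    sim <- generateCohort(syntheticConfig(nSubjects = 120, seed = 7))
    co <- sim$cohort
    expect_true(all(co$age >= 66 & co$age <= 75))
    expect_true(all(co$fchdr >= 0))
    expect_true(all(co$fchdr == round(co$fchdr)))
    # carrier count inside the central 99% binomial interval for
    # Binomial(120, 0.22): [15, 39] (frozen from qbinom)
    expect_gte(sum(co$apoe4), 15)
    expect_lte(sum(co$apoe4), 39)
    # gender-specific score distributions must populate all three groups
    expect_true(all(table(riskGroup(co$fchdr, co$gender)) > 0))
    # intensities clipped to [0, 1]
    rng <- range(sim$images@intensities)
    expect_gte(rng[1], 0)
    expect_lte(rng[2], 1)
})

test_that("zero effect sizes remove all image-score association", {
    sim <- generateNullCohort(syntheticConfig(nSubjects = 80, seed = 11))
    X <- featureValues(vectorizeImages(sim$images,
                                       buildMask(sim$images)))
    rs <- suppressWarnings(abs(cor(X, sim$cohort$fchdr)))
    rs <- rs[is.finite(rs)]
    lim <- 3 / sqrt(nrow(X))
    expect_lt(mean(rs), 2 / sqrt(nrow(X)))
    expect_lt(mean(rs > lim), 0.02)  # ~0.3% expected by chance
})

test_that("noiseless female signal is an exact affine function of score", {
    cfg <- syntheticConfig(nSubjects = 100, noiseSd = 0,
                           effectSizeFemale = 0.05,
                           apoeEffectMultiplier = 0, seed = 5)
    sim <- generateCohort(cfg)
    fem <- sim$cohort$gender == "female"
    sig <- which(sim$truth$weightPattern > 0.1)
    vox <- matrix(sim$images@intensities[fem, , , ],
                  nrow = sum(fem))[, sig, drop = FALSE]
    rs <- cor(vox, sim$cohort$fchdr[fem])
    expect_true(all(rs < -1 + 1e-8))
})

test_that("pattern sparsity and contiguity hold as configured", {
    cfg <- syntheticConfig(nSubjects = 10, patternSparsity = 0.08,
                           seed = 3)
    sim <- generateCohort(cfg)
    w <- sim$truth$weightPattern
    expect_equal(sum(w > 0), round(0.08 * prod(dim(w))))
    # blobs: every signal voxel has a signal neighbour (26-connectivity)
    idx <- which(w > 0, arr.ind = TRUE)
    hasNb <- vapply(seq_len(nrow(idx)), function(i) {
        d <- abs(sweep(idx, 2, idx[i, ]))
        any(rowSums(d) > 0 & apply(d, 1, max) <= 1)
    }, logical(1))
    expect_true(all(hasNb))
})

test_that("stronger female effect sizes increase signal-voxel correlation", {
    vals <- vapply(c(0.02, 0.05, 0.1), function(es) {
        sim <- generateCohort(syntheticConfig(nSubjects = 60,
                                              femaleFraction = 1,
                                              effectSizeFemale = es,
                                              seed = 9))
        sig <- sim$truth$weightPattern > 0.2
        vox <- matrix(sim$images@intensities, nrow = 60)[, sig]
        mean(abs(cor(vox, sim$cohort$fchdr)))
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
})

test_that("truth patterns persist to NIfTI losslessly", {
    sim <- cachedSim("img6", function()
        generateCohort(syntheticConfig(nSubjects = 6, seed = 8)))
    path <- file.path(withr::local_tempdir(), "truth.nii.gz")
    writeTruthPattern(sim$truth, path)
    back <- RNifti::readNifti(path)
    expect_identical(array(as.numeric(back), dim(back)),
                     sim$truth$weightPattern)
})

test_that("cohort table round-trips through delimited text", {
    sim <- defaultSim()
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCohortTable(sim$cohort, path)
    back <- readCohortTable(path)
    expect_equal(back, sim$cohort)
    expect_error(readCohortTable(writeCohortTable(
        sim$cohort[, 1:3], withr::local_tempfile(fileext = ".tsv"))),
        "lacks required columns")
})
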