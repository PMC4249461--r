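# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cachedSim <- function(key, maker) {
    if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
    .fixtures[[key]]
}

# Mid-size mixed-gender cohort with planted signal (default config).
defaultSim <- function() {
    cachedSim("default40", function()
        generateCohort(syntheticConfig(nSubjects = 40, seed = 2)))
}

# Kernel workflow applied to a simulated cohort: mask at 0.15 (mean rule),
# linear kernel, APOE4+intercept confound removal, trace normalization.
kernelWorkflow <- function(sim, confounds = "apoe4") {
    fm <- vectorizeImages(sim$images, buildMask(sim$images))
    K <- linearKernel(fm)
    Kres <- normalizeKernel(
        removeConfounds(K, confoundMatrix(sim$cohort, confounds)))
    list(features = fm, K = K, Kres = Kres)
}

# Balanced within-gender split with age-matched pairs, for calibration
# studies on null cohorts; returns kernel rows, labels and fold pairs.
riskSplitDesign <- function(sim) {
    lab <- medianRiskSplit(sim$cohort)
    keep <- which(!is.na(lab))
    cohort <- sim$cohort[keep, ]
    lab <- lab[keep]
    mt <- matchGroups(cohort, cohort$subject_id[lab == 1],
                      cohort$subject_id[lab == -1], ageCaliper = Inf)
    ids <- c(mt$pairs$idA, mt$pairs$idB)
    rows <- match(ids, sim$cohort$subject_id)
    np <- nrow(mt$pairs)
    list(rows = rows, labels = c(rep(1, np), rep(-1, np)),
         pairs = cbind(seq_len(np), np + seq_len(np)))
}

# Tiny deterministic cohort table for matching tests.
toyCohort <- function(gender, age, fchdr = 0L, apoe4 = 0L) {
    n <- length(gender)
    data.frame(subject_id = sprintf("T%02d", seq_len(n)), gender = gender,
               age = age, fchdr = rep_len(fchdr, n),
               glucose = 90, hypoglycemic_meds = 0L,
               bp1_sys = 130, bp2_sys = 128, bp3_sys = 126,
               total_chol = 200, hdl = 50, ldl = 120, smoker = 0L,
               apoe4 = rep_len(apoe4, n), stringsAsFactors = FALSE)
}
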