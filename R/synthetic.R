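#' Configuration for the synthetic cohort generator
#'
#' Collects and validates all parameters of the synthetic study generator.
#' Defaults emulate the marginal structure of the cohort the pipeline is
#' designed for: elderly subjects aged 66-75, about 56% female, roughly 22%
#' APOE epsilon-4 carriers, integer Framingham coronary heart disease risk
#' (FCHDR) scores whose gender-specific distributions populate all three
#' risk groups, and a spatially smooth gray-matter signal whose expression
#' decreases with the risk score in females but not males.
#'
#' @param nSubjects number of subjects (>= 4).
#' @param imageShape integer vector of three voxel-grid dimensions (each
#'   >= 4).
#' @param femaleFraction probability that a subject is female.
#' @param effectSizeFemale,effectSizeMale gray-matter probability units lost
#'   per within-gender standard deviation of the FCHDR score at the peak of
#'   the planted pattern. The male default of 0 encodes the qualitative
#'   gender difference the pipeline is meant to detect.
#' @param apoePrevalence probability of carrying at least one APOE epsilon-4
#'   allele.
#' @param apoeEffectMultiplier unitless >= 0; carriers express the signal
#'   slope multiplied by \code{1 + apoeEffectMultiplier}.
#' @param noiseSd marginal standard deviation (gray-matter units) of the
#'   spatially smooth noise field added to each image.
#' @param patternSparsity fraction of voxels carrying signal (contiguous
#'   blobs).
#' @param smoothSd Gaussian blur standard deviation in voxels applied to
#'   the noise field (and used to shape the pattern blobs); emulates the
#'   8 mm FWHM smoothing of the real maps at toy scale (FWHM about 2
#'   voxels).
#' @param seed integer RNG seed; identical configurations generate
#'   bit-identical cohorts.
#' @return a validated list of class \code{"syntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(nSubjects = 30, seed = 1)
#' @export
syntheticConfig <- function(nSubjects,
                            imageShape = c(12L, 14L, 12L),
                            femaleFraction = 0.56,
                            effectSizeFemale = 0.05,
                            effectSizeMale = 0,
                            apoePrevalence = 0.22,
                            apoeEffectMultiplier = 0.5,
                            noiseSd = 0.05,
                            patternSparsity = 0.08,
                            smoothSd = 0.85,
                            seed = 1L) {
    cfg <- list(nSubjects = as.integer(nSubjects),
                imageShape = as.integer(imageShape),
                femaleFraction = femaleFraction,
                effectSizeFemale = effectSizeFemale,
                effectSizeMale = effectSizeMale,
                apoePrevalence = apoePrevalence,
                apoeEffectMultiplier = apoeEffectMultiplier,
                noiseSd = noiseSd,
                patternSparsity = patternSparsity,
                smoothSd = smoothSd,
                seed = as.integer(seed))
    class(cfg) <- "syntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

validateSyntheticConfig <- function(cfg) {
    bad <- function(field, why)
        stop("invalid synthetic configuration: field '", field, "' ", why,
             call. = FALSE)
    prop <- function(field) {
        v <- cfg[[field]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
            bad(field, "must be a proportion in [0, 1]")
    }
    if (!is.numeric(cfg$nSubjects) || length(cfg$nSubjects) != 1L ||
        is.na(cfg$nSubjects) || cfg$nSubjects < 4L)
        bad("nSubjects", "must be at least 4")
    if (length(cfg$imageShape) != 3L || anyNA(cfg$imageShape) ||
        any(cfg$imageShape < 4L))
        bad("imageShape", "must be three integers, each at least 4")
    prop("femaleFraction"); prop("apoePrevalence"); prop("patternSparsity")
    for (f in c("effectSizeFemale", "effectSizeMale", "apoeEffectMultiplier",
                "noiseSd", "smoothSd")) {
        v <- cfg[[f]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
            bad(f, "must be a nonnegative number")
    }
    invisible(cfg)
}

# Smooth baseline gray-matter template: high probability centrally
# (about 0.8), falling below the 0.15 mask threshold towards the grid
# corners, emulating brain tissue against background.
baselineTemplate <- function(shape) {
    ctr <- (shape + 1) / 2
    g <- function(axis) (seq_len(shape[axis]) - ctr[axis]) / (shape[axis] / 2)
    d2 <- outer(outer(g(1L)^2, g(2L)^2, "+"), g(3L)^2, "+")
    0.05 + 0.75 * exp(-d2 / 0.9)
}

# Plant contiguous signal blobs: pick blob centres away from the border,
# take the k voxels nearest any centre, and load them with a Gaussian
# profile of the distance (peak 1 at the centres).
makeWeightPattern <- function(shape, sparsity) {
    k <- round(sparsity * prod(shape))
    if (k < 1L) return(array(0, shape))
    nBlobs <- max(1L, round(k / 60))
    lo <- pmin(3L, shape - 1L)
    centers <- cbind(
        sample(seq(lo[1L], shape[1L] - lo[1L] + 1L), nBlobs, replace = TRUE),
        sample(seq(lo[2L], shape[2L] - lo[2L] + 1L), nBlobs, replace = TRUE),
        sample(seq(lo[3L], shape[3L] - lo[3L] + 1L), nBlobs, replace = TRUE))
    grid <- as.matrix(expand.grid(i = seq_len(shape[1L]),
                                  j = seq_len(shape[2L]),
                                  k = seq_len(shape[3L])))
    d2 <- matrix(Inf, nrow(grid), 1L)
    for (b in seq_len(nBlobs)) {
        db <- rowSums((grid - matrix(centers[b, ], nrow(grid), 3L,
                                     byrow = TRUE))^2)
        d2 <- pmin(d2, db)
    }
    keep <- order(d2, seq_len(nrow(grid)))[seq_len(k)]
    w <- numeric(nrow(grid))
    w[keep] <- exp(-d2[keep] / (2 * 2^2))
    w <- w / max(w)
    array(w, shape)
}

# Spatially smooth noise field with marginal sd `noiseSd`: blur white
# noise, then rescale so the nominal sd is preserved after smoothing.
smoothNoise <- function(shape, noiseSd, smoothSd) {
    if (noiseSd == 0) return(array(0, shape))
    z <- gaussianBlur3d(array(stats::rnorm(prod(shape)), shape), smoothSd)
    z <- z / stats::sd(as.vector(z))
    z * noiseSd
}

#' Generate a synthetic cohort with a planted gray-matter risk pattern
#'
#' Draws a clinical table and a stack of gray-matter probability maps with
#' the statistical structure the downstream analysis assumes: integer FCHDR
#' scores from gender-specific distributions (males centered near 6.5,
#' females near 11.5, so the gender-specific risk-group cutoffs populate
#' all three groups), single risk factors with mild positive correlation
#' with the score, and images equal to a smooth baseline template minus a
#' gender- and APOE4-dependent multiple of the standardized score times a
#' smooth sparse weight pattern, plus spatially smooth noise, clipped to
#' \eqn{[0, 1]}. The signal direction is gray-matter loss with rising risk.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements \code{cohort} (data.frame), \code{images}
#'   ([GMImageSet-class]) and \code{truth} (list with the voxel
#'   \code{weightPattern} array, per-subject \code{latentScore} and
#'   \code{realizedEffect}).
#' @examples
#' sim <- generateCohort(syntheticConfig(nSubjects = 20, seed = 3))
#' head(sim$cohort)
#' @export
generateCohort <- function(config) {
    validateSyntheticConfig(config)
    withSeed(config$seed, {
        n <- config$nSubjects
        shape <- config$imageShape
        id <- sprintf("S%03d", seq_len(n))
        gender <- ifelse(stats::rbinom(n, 1L, config$femaleFraction) == 1L,
                         "female", "male")
        age <- sample(66:75, n, replace = TRUE)
        apoe4 <- stats::rbinom(n, 1L, config$apoePrevalence)
        fchdr <- integer(n)
        fem <- gender == "female"
        fchdr[fem] <- pmax(0L, as.integer(round(stats::rnorm(sum(fem),
                                                             11.5, 3.5))))
        fchdr[!fem] <- pmax(0L, as.integer(round(stats::rnorm(sum(!fem),
                                                              6.5, 3))))

        # standardized score within gender (slope units: per score SD)
        z <- numeric(n)
        for (g in c("female", "male")) {
            sel <- gender == g
            if (sum(sel) >= 2L && stats::sd(fchdr[sel]) > 0)
                z[sel] <- (fchdr[sel] - mean(fchdr[sel])) /
                    stats::sd(fchdr[sel])
        }

        hypoMeds <- stats::rbinom(n, 1L, stats::plogis(-2.6 + 0.25 * z))
        glucose <- round(pmax(60, 88 + 4 * z + stats::rnorm(n, 0, 12) +
                                  30 * hypoMeds), 1)
        bpBase <- 128 + 5 * z + stats::rnorm(n, 0, 10)
        bp1 <- round(bpBase + 4 + stats::rnorm(n, 0, 6))
        bp2 <- round(bpBase + stats::rnorm(n, 0, 4))
        bp3 <- round(bpBase + stats::rnorm(n, 0, 4))
        totalChol <- round(pmax(100, 205 + 8 * z + stats::rnorm(n, 0, 25)), 1)
        hdl <- round(pmax(20, 52 - 4 * z + stats::rnorm(n, 0, 10)), 1)
        ldl <- round(pmax(40, 128 + 7 * z + stats::rnorm(n, 0, 22)), 1)
        smoker <- stats::rbinom(n, 1L, stats::plogis(-1.2 + 0.35 * z))

        cohort <- data.frame(
            subject_id = id, gender = gender, age = age, fchdr = fchdr,
            glucose = glucose, hypoglycemic_meds = hypoMeds,
            bp1_sys = bp1, bp2_sys = bp2, bp3_sys = bp3,
            total_chol = totalChol, hdl = hdl, ldl = ldl,
            smoker = smoker, apoe4 = apoe4,
            stringsAsFactors = FALSE)

        pattern <- makeWeightPattern(shape, config$patternSparsity)
        template <- baselineTemplate(shape)
        slope <- ifelse(fem, config$effectSizeFemale, config$effectSizeMale) *
            (1 + config$apoeEffectMultiplier * apoe4)
        effect <- slope * z

        arr <- array(0, c(n, shape))
        for (i in seq_len(n)) {
            img <- template - effect[i] * pattern +
                smoothNoise(shape, config$noiseSd, config$smoothSd)
            arr[i, , , ] <- pmin(1, pmax(0, img))
        }
        images <- new("GMImageSet", intensities = arr, affine = diag(4),
                      subjectIds = id)
        list(cohort = cohort, images = images,
             truth = list(weightPattern = pattern, latentScore = z,
                          realizedEffect = effect))
    })
}

#' Generate a null cohort carrying no image-score association
#'
#' Identical to [generateCohort()] with both effect sizes forced to zero:
#' the clinical table keeps its full structure but the images are pure
#' template plus smooth noise, so any downstream decoding statistic is
#' distributed under its null.
#'
#' @inheritParams generateCohort
#' @return list with \code{cohort} and \code{images} (no truth pattern).
#' @export
generateNullCohort <- function(config) {
    validateSyntheticConfig(config)
    config$effectSizeFemale <- 0
    config$effectSizeMale <- 0
    out <- generateCohort(config)
    out["truth"] <- NULL
    out
}

#' Write the planted truth pattern as NIfTI
#'
#' Persists the voxel weight pattern of a synthetic cohort so recovery
#' analyses (for example weight-map enrichment) can be run against it
#' from disk.
#'
#' @param truth the \code{truth} element returned by [generateCohort()].
#' @param path output NIfTI path.
#' @param affine 4x4 voxel-to-world transform (default identity, matching
#'   generated image sets).
#' @return invisible \code{path}.
#' @export
writeTruthPattern <- function(truth, path, affine = diag(4)) {
    img <- RNifti::asNifti(truth$weightPattern)
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Read and write the delimited cohort table
#'
#' Tab-delimited text with one header row and the canonical column set
#' (\code{subject_id}, \code{gender}, \code{age}, \code{fchdr},
#' \code{glucose}, \code{hypoglycemic_meds}, \code{bp1_sys},
#' \code{bp2_sys}, \code{bp3_sys}, \code{total_chol}, \code{hdl},
#' \code{ldl}, \code{smoker}, \code{apoe4}).
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return \code{readCohortTable} returns the cohort data.frame;
#'   \code{writeCohortTable} returns \code{path} invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
    utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

cohortColumns <- c("subject_id", "gender", "age", "fchdr", "glucose",
                   "hypoglycemic_meds", "bp1_sys", "bp2_sys", "bp3_sys",
                   "total_chol", "hdl", "ldl", "smoker", "apoe4")

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
    cohort <- utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    missing <- setdiff(cohortColumns, names(cohort))
    if (length(missing))
        stop("cohort table at '", path, "' lacks required columns: ",
             paste(missing, collapse = ", "), call. = FALSE)
    cohort
}
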