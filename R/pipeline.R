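#' Run the full decoding analysis battery
#'
#' Configuration-driven orchestration of the complete analysis: synthetic
#' cohort generation (or loading a cohort table plus images), masking and
#' feature extraction, kernel construction with confound removal,
#' matched-pair risk-group classification, FCHDR and single-factor SVR
#' batteries with gender and APOE4 splits, dichotomous diabetes
#' classification, and weight-map export. Every run writes a config echo
#' sufficient to reproduce it exactly, plus a run log.
#'
#' @param config named list, or path to a YAML file with the same fields:
#'   \describe{
#'     \item{synthetic}{list of [syntheticConfig()] arguments, or}
#'     \item{cohortPath, imageDir}{paths to a cohort table and NIfTI
#'       images,}
#'     \item{analyses}{subset of \code{classify-pairs},
#'       \code{regress-fchdr}, \code{regress-factors},
#'       \code{regress-by-gender}, \code{regress-apoe-split},
#'       \code{diabetes-classify}, \code{weights},}
#'     \item{outDir}{output directory,}
#'     \item{threshold, maskRule, caliper, Cparam, epsilon, B, seed,
#'       confounds, pCorrection}{hyperparameters (defaults 0.15,
#'       \code{mean}, 2, 1, 0.1, 200, 1, \code{"apoe4"}, \code{none}).}
#'   }
#' @param overrides named list of values overriding the config file.
#' @return invisible list of in-memory results, one element per analysis.
#' @export
runPipeline <- function(config, overrides = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config[names(overrides)] <- overrides
    defaults <- list(analyses = c("classify-pairs", "regress-fchdr",
                                  "regress-factors", "regress-by-gender",
                                  "regress-apoe-split", "diabetes-classify",
                                  "weights"),
                     outDir = "cvdecode-results", threshold = 0.15,
                     maskRule = "mean", caliper = 2, Cparam = 1,
                     epsilon = 0.1, B = 200L, seed = 1L,
                     confounds = "apoe4", pCorrection = "none")
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    addOne <- identical(config$pCorrection, "add-one")
    outDir <- config$outDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logLines <- character(0)
    say <- function(...) {
        msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
        logLines <<- c(logLines, msg)
        message(msg)
    }
    onStage <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    # ---- inputs -----------------------------------------------------
    say("stage: inputs")
    if (!is.null(config$synthetic)) {
        sc <- do.call(syntheticConfig, config$synthetic)
        sim <- onStage("inputs", generateCohort(sc))
        cohort <- sim$cohort
        images <- sim$images
    } else {
        cohort <- onStage("inputs", readCohortTable(config$cohortPath))
        paths <- sort(list.files(config$imageDir, "\\.nii(\\.gz)?$",
                                 full.names = TRUE))
        images <- onStage("inputs", readImages(paths))
        stopIfNot(identical(subjectIds(images), cohort$subject_id),
                  "image subject order must match the cohort table")
    }

    # ---- features and kernel ---------------------------------------
    say("stage: features")
    mask <- onStage("features",
                    buildMask(images, config$threshold, config$maskRule))
    feats <- vectorizeImages(images, mask)
    K <- linearKernel(feats)
    C <- confoundMatrix(cohort, config$confounds)
    Kres <- normalizeKernel(removeConfounds(K, C))
    results <- list()
    writeJson <- function(x, name)
        jsonlite::write_json(x, file.path(outDir, name), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)

    # ---- classification of matched risk-group pairs ----------------
    if ("classify-pairs" %in% config$analyses) {
        say("stage: classify-pairs")
        comps <- list(c("medium", "low"), c("high", "medium"),
                      c("high", "low"))
        cls <- list()
        for (cmp in comps) {
            nm <- paste(cmp, collapse = "_vs_")
            mt <- matchGroups(cohort, cmp[1L], cmp[2L], config$caliper)
            if (nrow(mt$pairs) < 2L) {
                say("  ", nm, ": fewer than 2 pairs, skipped")
                next
            }
            ids <- c(mt$pairs$idA, mt$pairs$idB)
            rows <- match(ids, cohort$subject_id)
            sub <- cohort[rows, ]
            Ksub <- normalizeKernel(
                removeConfounds(K[rows, rows],
                                confoundMatrix(sub, config$confounds)))
            y <- c(rep(1, nrow(mt$pairs)), rep(-1, nrow(mt$pairs)))
            pairs <- cbind(seq_len(nrow(mt$pairs)),
                           nrow(mt$pairs) + seq_len(nrow(mt$pairs)))
            res <- onStage(nm, leavePairOutCv(Ksub, y, pairs,
                                              config$Cparam))
            # labels are exchanged within matched pairs so every permuted
            # labeling keeps the balanced paired design
            perm <- permutationTest(function(yp)
                leavePairOutCv(Ksub, yp, pairs, config$Cparam,
                               checkPairs = FALSE)@accuracy,
                y, B = config$B, tail = "greater", seed = config$seed,
                strata = c(seq_len(nrow(mt$pairs)),
                           seq_len(nrow(mt$pairs))),
                addOne = addOne)
            prAll <- projectionCorrelation(res, sub$fchdr, "all")
            prCor <- tryCatch(projectionCorrelation(res, sub$fchdr,
                                                    "correct"),
                              error = function(e) list(r = NA_real_))
            utils::write.table(res@perSubject,
                file.path(outDir, paste0("classify_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            cls[[nm]] <- list(comparison = nm, nPairs = nrow(mt$pairs),
                              accuracy = res@accuracy,
                              sensitivity = res@sensitivity,
                              specificity = res@specificity,
                              p_accuracy = perm@pValue,
                              projection_r_all = prAll$r,
                              projection_r_correct = prCor$r)
        }
        writeJson(cls, "classification.json")
        results$classification <- cls
    }

    # ---- regression analyses ---------------------------------------
    runBattery <- function(subgroup, factors) {
        runFactorBattery(cohort, K, factors = factors, subgroup = subgroup,
                         confounds = config$confounds, B = config$B,
                         seed = config$seed, Cparam = config$Cparam,
                         epsilon = config$epsilon)
    }
    if ("regress-fchdr" %in% config$analyses) {
        say("stage: regress-fchdr")
        tab <- onStage("regress-fchdr", runBattery("all", "fchdr"))
        utils::write.table(tab, file.path(outDir, "regress_fchdr.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$regressFchdr <- tab
    }
    if ("regress-factors" %in% config$analyses) {
        say("stage: regress-factors")
        tab <- onStage("regress-factors", runBattery("all", batteryFactors))
        utils::write.table(tab, file.path(outDir, "regress_factors.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$regressFactors <- tab
    }
    if ("regress-by-gender" %in% config$analyses) {
        say("stage: regress-by-gender")
        tab <- onStage("regress-by-gender",
                       rbind(runBattery("female", batteryFactors),
                             runBattery("male", batteryFactors)))
        utils::write.table(tab, file.path(outDir, "regress_by_gender.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$regressByGender <- tab
    }
    if ("regress-apoe-split" %in% config$analyses) {
        say("stage: regress-apoe-split")
        tab <- onStage("regress-apoe-split",
                       rbind(runBattery("apoe4_carriers", "fchdr"),
                             runBattery("matched_noncarriers", "fchdr")))
        utils::write.table(tab, file.path(outDir, "regress_apoe_split.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$regressApoeSplit <- tab
    }
    if ("diabetes-classify" %in% config$analyses) {
        say("stage: diabetes-classify")
        flags <- diabetesStatus(cohort$glucose, cohort$hypoglycemic_meds)
        if (length(unique(flags)) < 2L || min(table(flags)) < 2L) {
            say("  diabetes flag (nearly) single-class, skipped")
        } else {
            res <- onStage("diabetes-classify",
                           classifyDichotomousFactor(Kres, flags,
                                                     config$Cparam))
            out <- list(accuracy = res@accuracy,
                        nDiabetic = sum(flags), n = length(flags),
                        majorityRate = max(mean(flags), 1 - mean(flags)))
            writeJson(out, "diabetes_classification.json")
            results$diabetes <- out
        }
    }

    # ---- weight map -------------------------------------------------
    if ("weights" %in% config$analyses) {
        say("stage: weights")
        R <- residualMatrix(C, n = nrow(K))
        zn <- zNormalize(cohort$fchdr)
        fit <- onStage("weights", trainSvr(Kres, zn$values, config$Cparam,
                                           config$epsilon))
        wm <- computeWeights(fit, feats, R,
                             kernelScale = attr(Kres, "kernelScale"))
        writeWeightMap(wm, images@affine,
                       file.path(outDir, "svr_weights.nii.gz"),
                       metadata = list(target = "fchdr",
                                       Cparam = config$Cparam,
                                       epsilon = config$epsilon,
                                       confounds = config$confounds))
        results$weights <- wm
    }

    # ---- reproducibility artifacts ---------------------------------
    echo <- config
    echo$toolVersion <- as.character(utils::packageVersion("cvdecode"))
    writeJson(echo, "config_echo.json")
    writeLines(logLines, file.path(outDir, "run.log"))
    say("pipeline complete: ", outDir)
    invisible(results)
}
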