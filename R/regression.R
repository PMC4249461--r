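#' Z-normalize a regression target
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (n - 1 denominator). Normalizing every clinical target to unit variance
#' makes mean squared errors comparable across factors measured in
#' different units; the transform parameters are retained for inversion.
#'
#' @param targets numeric vector with at least two distinct values.
#' @return list with \code{values} (normalized), \code{mean} and \code{sd}.
#' @examples
#' zNormalize(c(1, 2, 3))$values  # -1 0 1
#' @export
zNormalize <- function(targets) {
    stopIfNot(length(unique(targets)) >= 2L,
              "degenerate target: needs at least two distinct values")
    m <- mean(targets)
    s <- stats::sd(targets)
    list(values = (targets - m) / s, mean = m, sd = s)
}

#' Regression metrics: Pearson correlation and mean squared error
#'
#' @param true,predicted numeric vectors of equal length (>= 3), on the
#'   normalized scale.
#' @return list with \code{r} (NA when \code{predicted} is constant) and
#'   \code{mse}.
#' @export
regressionMetrics <- function(true, predicted) {
    stopIfNot(length(true) == length(predicted) && length(true) >= 3L,
              "true and predicted must have equal length >= 3")
    r <- if (stats::sd(predicted) == 0 || stats::sd(true) == 0) NA_real_
         else stats::cor(true, predicted)
    list(r = r, mse = mean((true - predicted)^2))
}

#' Leave-one-out support vector regression of a clinical target
#'
#' The target is z-normalized (full-sample by default, fold-wise behind a
#' flag to quantify the leakage of the normalization constants), then for
#' each subject an eps-SVR is trained on the remaining n - 1 subjects on
#' the precomputed (typically confound-removed) kernel and the held-out
#' subject is predicted. With unit-variance targets the trivial
#' mean-predictor has MSE close to 1, so any materially smaller MSE
#' indicates predictive signal.
#'
#' @param K kernel matrix over the sample.
#' @param targets raw target values (z-normalized internally).
#' @param Cparam SVR cost (default 1).
#' @param epsilon SVR tube width (default 0.1).
#' @param foldwiseNorm re-estimate the normalization inside each training
#'   fold (default FALSE: full-sample, keeping cross-factor MSE
#'   comparability).
#' @param confounds optional n x p confound design: when given, \code{K}
#'   must be the raw kernel and confound removal plus trace
#'   normalization happen fold-wise on the training subjects only
#'   ([removeConfoundsFold()]), avoiding the test-information leakage of
#'   full-sample removal.
#' @param subjects optional subject ids.
#' @return a [RegressionResult-class] on the normalized scale.
#' @export
looSvr <- function(K, targets, Cparam = 1, epsilon = 0.1,
                   foldwiseNorm = FALSE, confounds = NULL,
                   subjects = NULL) {
    n <- nrow(K)
    stopIfNot(n >= 10L, "leave-one-out SVR needs at least 10 subjects")
    stopIfNot(length(targets) == n,
              "targets must align with the kernel rows")
    zn <- zNormalize(targets)
    if (is.null(subjects))
        subjects <- if (!is.null(rownames(K))) rownames(K)
                    else as.character(seq_len(n))
    predicted <- numeric(n)
    for (i in seq_len(n)) {
        train <- setdiff(seq_len(n), i)
        ytr <- if (foldwiseNorm) zNormalize(targets[train])$values
               else zn$values[train]
        kb <- foldKernel(K, confounds, train, i)
        fit <- trainSvr(kb$train, ytr, Cparam, epsilon)
        pred <- decisionValues(fit, kb$test)
        if (foldwiseNorm) {
            zi <- zNormalize(targets[train])
            pred <- (pred * zi$sd + zi$mean - zn$mean) / zn$sd
        }
        predicted[i] <- pred
    }
    met <- regressionMetrics(zn$values, predicted)
    new("RegressionResult",
        perSubject = data.frame(subject = subjects, true = zn$values,
                                predicted = predicted,
                                stringsAsFactors = FALSE),
        r = met$r, mse = met$mse,
        normalization = c(mean = zn$mean, sd = zn$sd))
}

# Extract a named clinical factor as a numeric regression target.
factorTarget <- function(cohort, factor) {
    switch(factor,
        fchdr = cohort$fchdr,
        blood_pressure = meanBloodPressure(
            cohort[, c("bp1_sys", "bp2_sys", "bp3_sys")]),
        age = cohort$age,
        total_cholesterol = cohort$total_chol,
        ldl_cholesterol = cohort$ldl,
        smoking_status = cohort$smoker,
        stop("unknown factor '", factor, "'", call. = FALSE))
}

batteryFactors <- c("fchdr", "blood_pressure", "age", "total_cholesterol",
                    "ldl_cholesterol", "smoking_status")

# Resolve a subgroup filter to cohort row indices.
subgroupRows <- function(cohort, subgroup) {
    switch(subgroup,
        all = seq_len(nrow(cohort)),
        female = which(cohort$gender == "female"),
        male = which(cohort$gender == "male"),
        apoe4_carriers = which(cohort$apoe4 == 1),
        matched_noncarriers = {
            m <- matchApoeNoncarriers(cohort)
            match(m$matched$noncarrier, cohort$subject_id)
        },
        stop("unknown subgroup '", subgroup, "'", call. = FALSE))
}

#' Single risk-factor regression battery
#'
#' Runs leave-one-out SVR for each requested clinical factor within a
#' subgroup, with kernel confound removal re-applied inside the subgroup,
#' and permutation p-values for the correlation (upper tail) and the MSE
#' (lower tail). Output rows mirror the layout factor / n / R / p(R) /
#' MSE / p(MSE) / subgroup.
#'
#' @param cohort cohort data.frame.
#' @param K kernel matrix over all cohort subjects (raw, before confound
#'   removal; the battery residualizes within the subgroup).
#' @param factors subset of \code{fchdr}, \code{blood_pressure},
#'   \code{age}, \code{total_cholesterol}, \code{ldl_cholesterol},
#'   \code{smoking_status}.
#' @param subgroup one of \code{all}, \code{female}, \code{male},
#'   \code{apoe4_carriers}, \code{matched_noncarriers}.
#' @param confounds confound column names for [confoundMatrix()]; use
#'   \code{character(0)} for intercept-only centering.
#' @param B permutations per factor (default 199).
#' @param seed RNG seed for permutation shuffles.
#' @param Cparam,epsilon SVR hyperparameters.
#' @return data.frame with one row per factor.
#' @export
runFactorBattery <- function(cohort, K, factors = batteryFactors,
                             subgroup = "all", confounds = "apoe4",
                             B = 199L, seed = 1L, Cparam = 1,
                             epsilon = 0.1) {
    stopIfNot(all(factors %in% batteryFactors),
              paste("factors must be drawn from:",
                    paste(batteryFactors, collapse = ", ")))
    rows <- subgroupRows(cohort, subgroup)
    stopIfNot(length(rows) > 0, "empty subgroup after filtering")
    sub <- cohort[rows, , drop = FALSE]
    Ksub <- K[rows, rows, drop = FALSE]
    # residualize within the subgroup; drop confounds that are constant
    # there (e.g. apoe4 within a carriers-only subgroup)
    keep <- confounds[vapply(confounds,
                             function(cl) length(unique(sub[[cl]])) > 1L,
                             logical(1L))]
    Kres <- normalizeKernel(removeConfounds(Ksub, confoundMatrix(sub, keep)))
    out <- list()
    for (fc in factors) {
        tgt <- factorTarget(sub, fc)
        if (anyNA(tgt) || length(unique(tgt)) < 2L) {
            warning("factor '", fc, "' skipped in subgroup '", subgroup,
                    "' (missing or degenerate values)", call. = FALSE)
            next
        }
        res <- looSvr(Kres, tgt, Cparam, epsilon)
        statR <- function(t) looSvr(Kres, t, Cparam, epsilon)@r
        statM <- function(t) looSvr(Kres, t, Cparam, epsilon)@mse
        pR <- permutationTest(statR, tgt, B = B, tail = "greater",
                              seed = seed)@pValue
        pM <- permutationTest(statM, tgt, B = B, tail = "less",
                              seed = seed)@pValue
        out[[fc]] <- data.frame(factor = fc, n = length(rows),
                                R = res@r, p_R = pR, MSE = res@mse,
                                p_MSE = pM, subgroup = subgroup,
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify a dichotomous clinical factor from brain images
#'
#' Leave-one-out SVM classification of a binary clinical flag (for example
#' diabetes status derived from glycemia and medication); classes may be
#' unbalanced, so accuracy should be compared against the majority-class
#' rate.
#'
#' @param K kernel matrix (typically confound-removed).
#' @param flags logical/0-1 vector; TRUE maps to the +1 class.
#' @param Cparam SVM cost.
#' @param subjects optional subject ids.
#' @return a [ClassificationResult-class].
#' @export
classifyDichotomousFactor <- function(K, flags, Cparam = 1,
                                      subjects = NULL) {
    y <- ifelse(as.logical(flags), 1, -1)
    looClassify(K, y, Cparam = Cparam, subjects = subjects)
}
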