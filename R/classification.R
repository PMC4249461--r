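#' Classification metrics from confusion counts
#'
#' Accuracy \eqn{(TP+TN)/n}, sensitivity \eqn{TP/(TP+FN)} (recall of the
#' higher-risk class) and specificity \eqn{TN/(TN+FP)} (recall of the
#' lower-risk class). Empty denominators yield \code{NA} rather than an
#' error.
#'
#' @param tp,fp,tn,fn confusion counts (higher-risk class = positive).
#' @return named list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity} as proportions.
#' @examples
#' m <- classificationMetrics(tp = 18, fp = 7, tn = 15, fn = 4)
#' round(100 * unlist(m), 2)  # 75.00, 81.82, 68.18
#' @export
classificationMetrics <- function(tp, fp, tn, fn) {
    n <- tp + fp + tn + fn
    stopIfNot(all(c(tp, fp, tn, fn) >= 0) && n > 0,
              "counts must be nonnegative with a positive total")
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    list(accuracy = (tp + tn) / n,
         sensitivity = safe(tp, tp + fn),
         specificity = safe(tn, tn + fp))
}

#' Balanced leave-pair-out cross-validated classification
#'
#' For each matched pair (one subject from each class) the SVM is trained
#' on all remaining subjects and the held-out two are predicted, so every
#' training set stays balanced. Decision values are retained per subject
#' for the projection analysis. A decision value of exactly 0 predicts the
#' +1 class (deterministic tie-break).
#'
#' @param K kernel matrix over the full matched sample (typically
#'   confound-removed).
#' @param labels -1/+1 labels aligned to the kernel rows.
#' @param pairs two-column matrix (or data.frame) of row indices into
#'   \code{K}, one row per fold; pairs must partition the sample.
#' @param Cparam SVM cost (default 1).
#' @param checkPairs verify that each pair holds one subject per class
#'   (disable inside permutation re-runs, where shuffled labels legitimately
#'   break pair composition while the folds stay fixed).
#' @param confounds optional n x p confound design: when given, \code{K}
#'   must be the raw kernel and confound removal plus trace
#'   normalization happen fold-wise on the training subjects only
#'   ([removeConfoundsFold()]), avoiding the test-information leakage of
#'   full-sample removal.
#' @param subjects optional subject ids (defaults to kernel dimnames or
#'   indices).
#' @return a [ClassificationResult-class].
#' @export
leavePairOutCv <- function(K, labels, pairs, Cparam = 1, checkPairs = TRUE,
                           confounds = NULL, subjects = NULL) {
    y <- labelsToPm1(labels)
    pairs <- as.matrix(pairs)
    n <- nrow(K)
    idx <- as.vector(pairs)
    stopIfNot(length(idx) == n && setequal(idx, seq_len(n)),
              "pairs must partition the sample (every subject exactly once)")
    if (checkPairs)
        stopIfNot(all(y[pairs[, 1L]] + y[pairs[, 2L]] == 0),
                  "each pair must contain one subject from each class")
    if (is.null(subjects))
        subjects <- if (!is.null(rownames(K))) rownames(K)
                    else as.character(seq_len(n))
    decision <- numeric(n)
    for (f in seq_len(nrow(pairs))) {
        test <- pairs[f, ]
        train <- setdiff(seq_len(n), test)
        kb <- foldKernel(K, confounds, train, test)
        fit <- trainSvm(kb$train, y[train], Cparam)
        decision[test] <- decisionValues(fit, kb$test)
    }
    predicted <- ifelse(decision >= 0, 1, -1)
    counts <- c(tp = sum(predicted == 1 & y == 1),
                fp = sum(predicted == 1 & y == -1),
                tn = sum(predicted == -1 & y == -1),
                fn = sum(predicted == -1 & y == 1))
    met <- classificationMetrics(counts[["tp"]], counts[["fp"]],
                                 counts[["tn"]], counts[["fn"]])
    new("ClassificationResult",
        perSubject = data.frame(subject = subjects, label = y,
                                decision = decision, predicted = predicted,
                                stringsAsFactors = FALSE),
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity = met$specificity, counts = counts)
}

#' Leave-one-out cross-validated classification
#'
#' Single-subject-out variant used for dichotomous clinical targets (for
#' example diabetic versus non-diabetic), where classes may be unbalanced;
#' accuracy should then be read against the majority-class rate, which is
#' reported alongside.
#'
#' @inheritParams leavePairOutCv
#' @return a [ClassificationResult-class]; the majority-class rate is
#'   available from the counts.
#' @export
looClassify <- function(K, labels, Cparam = 1, confounds = NULL,
                        subjects = NULL) {
    y <- labelsToPm1(labels)
    stopIfNot(length(unique(y)) == 2L, "both classes must be present")
    stopIfNot(min(table(y)) >= 2L,
              "each class needs at least 2 subjects for leave-one-out")
    n <- nrow(K)
    if (is.null(subjects))
        subjects <- if (!is.null(rownames(K))) rownames(K)
                    else as.character(seq_len(n))
    decision <- numeric(n)
    for (i in seq_len(n)) {
        train <- setdiff(seq_len(n), i)
        kb <- foldKernel(K, confounds, train, i)
        fit <- trainSvm(kb$train, y[train], Cparam)
        decision[i] <- decisionValues(fit, kb$test)
    }
    predicted <- ifelse(decision >= 0, 1, -1)
    counts <- c(tp = sum(predicted == 1 & y == 1),
                fp = sum(predicted == 1 & y == -1),
                tn = sum(predicted == -1 & y == -1),
                fn = sum(predicted == -1 & y == 1))
    met <- classificationMetrics(counts[["tp"]], counts[["fp"]],
                                 counts[["tn"]], counts[["fn"]])
    new("ClassificationResult",
        perSubject = data.frame(subject = subjects, label = y,
                                decision = decision, predicted = predicted,
                                stringsAsFactors = FALSE),
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity = met$specificity, counts = counts)
}

#' Correlation between SVM projections and the FCHDR score
#'
#' Pearson correlation between cross-validated decision values (the
#' projections onto the discriminating direction) and the FCHDR score,
#' over all subjects or only those correctly classified. The underlying
#' idea: the more extreme the cardiovascular risk, the further a subject
#' should project from the decision boundary.
#'
#' @param result a [ClassificationResult-class].
#' @param fchdr FCHDR scores aligned to \code{result@perSubject} rows.
#' @param subset \code{"all"} or \code{"correct"} (correctly classified
#'   subjects only).
#' @param B number of permutations for a p-value (0 = none).
#' @param tail permutation tail (default \code{"greater"}).
#' @param seed RNG seed for the permutation shuffles.
#' @return list with \code{r}, \code{n}, \code{subset} and (when
#'   \code{B > 0}) \code{p} and the [PermutationResult-class].
#' @export
projectionCorrelation <- function(result, fchdr,
                                  subset = c("all", "correct"),
                                  B = 0, tail = "greater", seed = 1L) {
    subset <- match.arg(subset)
    ps <- result@perSubject
    stopIfNot(nrow(ps) == length(fchdr),
              "fchdr must align with the per-subject results")
    keep <- if (subset == "correct") ps$predicted == ps$label
            else rep(TRUE, nrow(ps))
    d <- ps$decision[keep]; s <- fchdr[keep]
    stopIfNot(length(d) >= 3L, "need at least 3 subjects in the subset")
    if (stats::sd(d) == 0 || stats::sd(s) == 0)
        return(list(r = NA_real_, n = length(d), subset = subset))
    r <- stats::cor(d, s)
    out <- list(r = r, n = length(d), subset = subset)
    if (B > 0) {
        perm <- permutationTest(function(sp) stats::cor(d, sp), s,
                                B = B, tail = tail, seed = seed)
        out$p <- perm@pValue
        out$permutation <- perm
    }
    out
}

# Fold kernel blocks: passthrough when no fold-wise confound design is
# given; otherwise train-only residualization plus trace normalization
# estimated on the training kernel.
foldKernel <- function(K, confounds, train, test) {
    if (is.null(confounds))
        return(list(train = K[train, train, drop = FALSE],
                    test = K[test, train, drop = FALSE]))
    kb <- removeConfoundsFold(K, confounds, train, test)
    s <- mean(diag(kb$train))
    if (s > 0) {
        kb$train <- kb$train / s
        kb$test <- kb$test / s
    }
    kb
}
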