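#' Permutation test for a cross-validated pipeline statistic
#'
#' Re-runs the complete cross-validated analysis \code{B} times with
#' labels/targets randomly shuffled across subjects (the kernel, confound
#' design and fold structure stay fixed) and reports the proportion of
#' permuted statistics at or beyond the observed one. For accuracy and
#' correlation the upper tail is appropriate; for MSE the lower tail.
#' By default \eqn{p = \mathrm{count} / B} exactly; when the count is 0
#' the result prints as \eqn{p \le 1/B}. The \code{addOne} flag applies
#' the common \eqn{(\mathrm{count}+1)/(B+1)} correction instead.
#'
#' @param statisticFn function mapping a label/target vector to the
#'   pipeline statistic (must be deterministic given its input).
#' @param y the observed labels or targets.
#' @param B number of permutations (>= 1).
#' @param tail \code{"greater"} or \code{"less"}.
#' @param seed integer RNG seed for the shuffles.
#' @param strata optional factor; when given, shuffles happen within
#'   strata (for example within gender).
#' @param addOne apply the add-one correction (default FALSE).
#' @return a [PermutationResult-class].
#' @examples
#' obs <- c(1, 2, 3, 4, 5)
#' pt <- permutationTest(function(y) cor(y, obs), obs, B = 99, seed = 2)
#' pValue(pt)
#' @export
permutationTest <- function(statisticFn, y, B = 1000L,
                            tail = c("greater", "less"), seed = 1L,
                            strata = NULL, addOne = FALSE) {
    tail <- match.arg(tail)
    B <- as.integer(B)
    stopIfNot(B >= 1L, "B must be at least 1")
    observed <- statisticFn(y)
    permuted <- withSeed(seed, {
        vapply(seq_len(B), function(b) {
            yp <- if (is.null(strata)) sample(y)
                  else shuffleWithin(y, strata)
            statisticFn(yp)
        }, numeric(1L))
    })
    count <- if (tail == "greater") sum(permuted >= observed)
             else sum(permuted <= observed)
    p <- if (addOne) (count + 1) / (B + 1) else count / B
    new("PermutationResult", observed = observed, permuted = permuted,
        pValue = p, B = B, tail = tail, seed = as.integer(seed),
        addOne = addOne)
}

shuffleWithin <- function(y, strata) {
    out <- y
    for (s in unique(strata)) {
        i <- which(strata == s)
        out[i] <- y[i][sample.int(length(i))]
    }
    out
}

#' Summary of the permuted null distribution
#'
#' Mean and standard deviation of the permuted statistics, used to check
#' calibration: for balanced classification the null accuracy should sit
#' close to chance (about 50%), for regression the null correlation close
#' to 0.
#'
#' @param result a [PermutationResult-class] with \code{B >= 2}.
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
permutedStatisticSummary <- function(result) {
    stopIfNot(result@B >= 2L, "need at least 2 permutations to summarize")
    c(mean = mean(result@permuted), sd = stats::sd(result@permuted))
}

#' Balanced within-gender median split of the FCHDR score
#'
#' Utility for calibration studies: within each gender, subjects are
#' ordered by (FCHDR, subject id) and the lower half labeled -1, the upper
#' half +1; with an odd count the middle subject is dropped (NA). The
#' resulting labels are exactly balanced within gender, so same-gender
#' pairs for balanced leave-pair-out folds always exist.
#'
#' @param cohort cohort data.frame.
#' @return integer vector of -1/+1/NA aligned to cohort rows.
#' @export
medianRiskSplit <- function(cohort) {
    lab <- rep(NA_integer_, nrow(cohort))
    for (g in unique(cohort$gender)) {
        i <- which(cohort$gender == g)
        o <- i[order(cohort$fchdr[i], cohort$subject_id[i])]
        h <- length(o) %/% 2L
        if (h == 0L) next
        lab[o[seq_len(h)]] <- -1L
        lab[o[seq.int(length(o) - h + 1L, length(o))]] <- 1L
    }
    lab
}
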