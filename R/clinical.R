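#' Diabetes mellitus status from fasting glucose and medication
#'
#' A subject is considered diabetic when fasting glucose is at least
#' 126 mg/dl and/or the subject currently uses insulin or oral
#' hypoglycemic drugs.
#'
#' @param glucose fasting glucose in mg/dl (vectorized, must be positive).
#' @param hypoglycemicMeds logical/0-1 flag for current insulin or oral
#'   hypoglycemic treatment.
#' @return logical vector.
#' @examples
#' diabetesStatus(c(126, 125, 90), c(FALSE, FALSE, TRUE))
#' @export
diabetesStatus <- function(glucose, hypoglycemicMeds) {
    if (anyNA(glucose) && anyNA(hypoglycemicMeds))
        stop("missing glucose with absent medication flag", call. = FALSE)
    meds <- as.logical(hypoglycemicMeds)
    if (anyNA(glucose[!meds %in% TRUE]))
        stop("missing glucose for subjects without a medication flag",
             call. = FALSE)
    stopIfNot(all(glucose > 0, na.rm = TRUE),
              "glucose must be strictly positive")
    (!is.na(glucose) & glucose >= 126) | meds %in% TRUE
}

#' Averaged blood pressure from three sequential readings
#'
#' The first (acclimatization) reading is discarded; the arithmetic mean of
#' the second and third readings is returned.
#'
#' @param readings numeric vector of exactly three readings (mmHg), ordered
#'   by acquisition, or a matrix with three columns (one row per subject).
#' @return mmHg value (vector for matrix input).
#' @examples
#' meanBloodPressure(c(140, 130, 126))  # 128
#' @export
meanBloodPressure <- function(readings) {
    if (is.matrix(readings) || is.data.frame(readings)) {
        readings <- as.matrix(readings)
        stopIfNot(ncol(readings) == 3L,
                  "exactly three blood-pressure readings are required")
        return((readings[, 2L] + readings[, 3L]) / 2)
    }
    stopIfNot(length(readings) == 3L,
              "exactly three blood-pressure readings are required")
    (readings[2L] + readings[3L]) / 2
}

#' Risk-group categorization from the FCHDR score
#'
#' Gender-specific integer cutoffs: males are low risk up to a score of 5,
#' medium above 5 up to 8, high above 8; females low up to 9, medium above
#' 9 up to 14, high above 14. Boundary scores fall in the lower group of
#' each pair.
#'
#' @param fchdr integer score(s), >= 0.
#' @param gender \code{"male"}/\code{"female"} (recycled if length 1).
#' @return factor with levels \code{low}, \code{medium}, \code{high}.
#' @examples
#' riskGroup(c(5, 9), "male")     # low, high
#' riskGroup(14, "female")        # medium
#' @export
riskGroup <- function(fchdr, gender) {
    stopIfNot(all(fchdr >= 0), "fchdr must be nonnegative")
    if (length(gender) == 1L) gender <- rep(gender, length(fchdr))
    stopIfNot(all(gender %in% c("male", "female")),
              "gender must be 'male' or 'female'")
    cut1 <- ifelse(gender == "male", 5, 9)
    cut2 <- ifelse(gender == "male", 8, 14)
    out <- ifelse(fchdr <= cut1, "low",
                  ifelse(fchdr <= cut2, "medium", "high"))
    factor(out, levels = c("low", "medium", "high"))
}

# Resolve a group specification (risk label or explicit subject ids) to ids.
resolveGroup <- function(cohort, group) {
    if (length(group) == 1L && group %in% c("low", "medium", "high")) {
        rg <- riskGroup(cohort$fchdr, cohort$gender)
        return(cohort$subject_id[rg == group])
    }
    stopIfNot(all(group %in% cohort$subject_id),
              "group members must be cohort subject ids or a risk label")
    group
}

#' Gender- and age-matched pairing of two groups
#'
#' Greedy nearest-age matching within gender: candidate same-gender pairs
#' with an absolute age difference at most \code{ageCaliper} are ranked by
#' age difference (ties broken by subject id order) and accepted while both
#' members are unused. Subjects left unpaired are reported as discarded.
#'
#' @param cohort cohort data.frame.
#' @param groupA,groupB risk-group labels (\code{"low"}, \code{"medium"},
#'   \code{"high"}) or explicit subject-id vectors.
#' @param ageCaliper maximum allowed age difference in years (default 2;
#'   use \code{Inf} to disable).
#' @return list with \code{pairs} (data.frame \code{idA}, \code{idB},
#'   \code{gender}, \code{ageA}, \code{ageB}) and \code{discarded}
#'   (subject ids).
#' @export
matchGroups <- function(cohort, groupA, groupB, ageCaliper = 2) {
    idsA <- resolveGroup(cohort, groupA)
    idsB <- resolveGroup(cohort, groupB)
    stopIfNot(length(idsA) > 0 && length(idsB) > 0,
              "both groups must be non-empty")
    rows <- function(ids) cohort[match(ids, cohort$subject_id), ]
    a <- rows(idsA); b <- rows(idsB)
    cand <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
    cand <- cand[a$gender[cand$ia] == b$gender[cand$ib], , drop = FALSE]
    cand$dAge <- abs(a$age[cand$ia] - b$age[cand$ib])
    cand <- cand[cand$dAge <= ageCaliper, , drop = FALSE]
    cand <- cand[order(cand$dAge, cand$ia, cand$ib), , drop = FALSE]
    usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
    keep <- integer(0)
    for (r in seq_len(nrow(cand))) {
        ia <- cand$ia[r]; ib <- cand$ib[r]
        if (!usedA[ia] && !usedB[ib]) {
            usedA[ia] <- TRUE; usedB[ib] <- TRUE
            keep <- c(keep, r)
        }
    }
    sel <- cand[keep, , drop = FALSE]
    pairs <- data.frame(idA = a$subject_id[sel$ia],
                        idB = b$subject_id[sel$ib],
                        gender = a$gender[sel$ia],
                        ageA = a$age[sel$ia], ageB = b$age[sel$ib],
                        stringsAsFactors = FALSE)
    discarded <- c(a$subject_id[!usedA], b$subject_id[!usedB])
    list(pairs = pairs, discarded = discarded)
}

#' Covariate-matched non-carrier control group for APOE4 carriers
#'
#' Selects one non-carrier per carrier of the same gender, greedily
#' minimizing the age difference with the FCHDR score difference as
#' tiebreak (then subject-id order); each non-carrier is used at most once.
#'
#' @param cohort cohort data.frame with an \code{apoe4} column.
#' @param carriers optional subject-id vector; defaults to all
#'   \code{apoe4 == 1} subjects.
#' @return list with \code{matched} (data.frame \code{carrier},
#'   \code{noncarrier}) and \code{unmatched} (carrier ids without a
#'   control). A warning is raised when the non-carrier pool is
#'   insufficient.
#' @export
matchApoeNoncarriers <- function(cohort, carriers = NULL) {
    if (is.null(carriers))
        carriers <- cohort$subject_id[cohort$apoe4 == 1]
    if (length(carriers) == 0L)
        return(list(matched = data.frame(carrier = character(0),
                                         noncarrier = character(0)),
                    unmatched = character(0)))
    pool <- cohort[!(cohort$subject_id %in% carriers) & cohort$apoe4 == 0, ]
    carr <- cohort[match(carriers, cohort$subject_id), ]
    cand <- expand.grid(ic = seq_len(nrow(carr)), ip = seq_len(nrow(pool)))
    cand <- cand[carr$gender[cand$ic] == pool$gender[cand$ip], , drop = FALSE]
    cand$dAge <- abs(carr$age[cand$ic] - pool$age[cand$ip])
    cand$dF <- abs(carr$fchdr[cand$ic] - pool$fchdr[cand$ip])
    cand <- cand[order(cand$dAge, cand$dF, cand$ic, cand$ip), , drop = FALSE]
    usedC <- logical(nrow(carr)); usedP <- logical(nrow(pool))
    keep <- integer(0)
    for (r in seq_len(nrow(cand))) {
        ic <- cand$ic[r]; ip <- cand$ip[r]
        if (!usedC[ic] && !usedP[ip]) {
            usedC[ic] <- TRUE; usedP[ip] <- TRUE
            keep <- c(keep, r)
        }
    }
    sel <- cand[keep, , drop = FALSE]
    sel <- sel[order(sel$ic), , drop = FALSE]
    matched <- data.frame(carrier = carr$subject_id[sel$ic],
                          noncarrier = pool$subject_id[sel$ip],
                          stringsAsFactors = FALSE)
    unmatched <- carr$subject_id[!usedC]
    if (length(unmatched))
        warning("insufficient compatible non-carriers: ",
                length(unmatched), " carrier(s) left unmatched",
                call. = FALSE)
    list(matched = matched, unmatched = unmatched)
}

#' Hardy-Weinberg equilibrium test for APOE epsilon-4 genotype counts
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' (epsilon4/epsilon4, epsilon4/other, other/other) against the
#' proportions \eqn{p^2, 2pq, q^2} expected from the estimated allele
#' frequency \eqn{p = (2 n_{44} + n_{4x}) / (2N)}.
#'
#' @param n44 count of epsilon4 homozygotes.
#' @param n4x count of heterozygotes.
#' @param nxx count of subjects without an epsilon4 allele.
#' @return object of class \code{"htest"} with the chi-square statistic,
#'   df = 1 and p-value. Monomorphic samples return a statistic of 0.
#' @examples
#' hardyWeinbergTest(49, 42, 9)   # exact HW proportions: statistic 0
#' @export
hardyWeinbergTest <- function(n44, n4x, nxx) {
    counts <- c(n44, n4x, nxx)
    stopIfNot(all(counts >= 0) && sum(counts) > 0,
              "genotype counts must be nonnegative with a positive total")
    n <- sum(counts)
    p <- (2 * counts[1L] + counts[2L]) / (2 * n)
    q <- 1 - p
    expected <- n * c(p^2, 2 * p * q, q^2)
    nz <- expected > 0
    stat <- sum((counts[nz] - expected[nz])^2 / expected[nz])
    pval <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    structure(list(statistic = c("X-squared" = stat),
                   parameter = c(df = 1L),
                   p.value = pval,
                   estimate = c("allele frequency" = p),
                   expected = expected,
                   method = paste("Hardy-Weinberg equilibrium chi-square",
                                  "test (1 df)"),
                   data.name = paste(counts, collapse = ", ")),
              class = "htest")
}
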