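test_that("diabetes status applies the glucose threshold and meds rule", {
    expect_true(diabetesStatus(126, FALSE))   # boundary is diabetic
    expect_false(diabetesStatus(125, FALSE))
    expect_true(diabetesStatus(90, TRUE))     # medication alone suffices
    expect_identical(diabetesStatus(c(126, 125, 90), c(0, 0, 1)),
                     c(TRUE, FALSE, TRUE))
    expect_error(diabetesStatus(NA, NA), "missing")
    expect_error(diabetesStatus(-5, FALSE), "positive")
})

test_that("blood pressure discards the first reading", {
    expect_equal(meanBloodPressure(c(140, 130, 126)), 128)
    expect_equal(meanBloodPressure(c(999, 120, 120)), 120)
    expect_equal(meanBloodPressure(c(118, 121, 124)), 122.5)
    m <- rbind(c(140, 130, 126), c(999, 120, 120))
    expect_equal(unname(meanBloodPressure(m)), c(128, 120))
    expect_error(meanBloodPressure(c(120, 130)), "three")
})

test_that("risk groups follow the gender-specific cutoffs", {
    expect_equal(as.character(riskGroup(5, "male")), "low")
    expect_equal(as.character(riskGroup(9, "male")), "high")
    expect_equal(as.character(riskGroup(14, "female")), "medium")
    # totality and boundary placement over a score sweep
    for (g in c("male", "female")) {
        rg <- riskGroup(0:30, g)
        expect_false(anyNA(rg))
        cuts <- if (g == "male") c(5, 8) else c(9, 14)
        expect_equal(as.character(rg[cuts[1] + 1]), "low")
        expect_equal(as.character(rg[cuts[1] + 2]), "medium")
        expect_equal(as.character(rg[cuts[2] + 1]), "medium")
        expect_equal(as.character(rg[cuts[2] + 2]), "high")
    }
    expect_error(riskGroup(5, "other"), "gender")
})

test_that("matched pairing is gender-constrained, age-aware and symmetric", {
    # identical (gender, age) multisets pair off completely
    co <- toyCohort(gender = rep(c("male", "female"), each = 4),
                    age = rep(c(66, 70, 70, 74), 2))
    a <- co$subject_id[c(1, 2, 5, 6)]
    b <- co$subject_id[c(3, 4, 7, 8)]
    m <- matchGroups(co, a, b, ageCaliper = Inf)
    expect_equal(nrow(m$pairs), 4)
    expect_length(m$discarded, 0)
    expect_true(all(m$pairs$gender ==
        co$gender[match(m$pairs$idA, co$subject_id)]))
    # all-male vs all-female: nothing can be paired
    co2 <- toyCohort(gender = rep(c("male", "female"), each = 3),
                     age = 70)
    m2 <- matchGroups(co2, co2$subject_id[1:3], co2$subject_id[4:6])
    expect_equal(nrow(m2$pairs), 0)
    expect_length(m2$discarded, 6)
    # symmetric in group order up to orientation
    m3 <- matchGroups(co, b, a, ageCaliper = Inf)
    expect_equal(nrow(m3$pairs), nrow(m$pairs))
    expect_setequal(m3$discarded, m$discarded)
})

test_that("pair counts equal within-gender minima at infinite caliper", {
    # group sizes (9M, 33F) vs (44M, 17F) can yield at most 9 + 17 pairs
    gender <- c(rep("male", 9), rep("female", 33),
                rep("male", 44), rep("female", 17))
    set.seed(4)
    co <- toyCohort(gender = gender,
                    age = sample(66:75, length(gender), TRUE))
    a <- co$subject_id[1:42]
    b <- co$subject_id[43:103]
    m <- matchGroups(co, a, b, ageCaliper = Inf)
    expect_equal(nrow(m$pairs), 26)
    expect_true(all(abs(m$pairs$ageA - m$pairs$ageB) >= 0))
    # a finite caliper can only reduce the count
    m2 <- matchGroups(co, a, b, ageCaliper = 2)
    expect_lte(nrow(m2$pairs), 26)
})

test_that("APOE4 carrier matching balances gender, age and score", {
    co <- toyCohort(gender = rep(c("male", "female"), 6),
                    age = rep(c(67, 69, 71), 4),
                    fchdr = rep(c(4L, 8L, 12L), 4),
                    apoe4 = rep(c(1L, 0L), each = 6))
    m <- matchApoeNoncarriers(co)
    expect_equal(nrow(m$matched), 6)
    expect_length(m$unmatched, 0)
    carr <- co[match(m$matched$carrier, co$subject_id), ]
    ctrl <- co[match(m$matched$noncarrier, co$subject_id), ]
    expect_true(all(carr$gender == ctrl$gender))
    expect_false(any(duplicated(m$matched$noncarrier)))
    # empty carrier set
    e <- matchApoeNoncarriers(co, carriers = character(0))
    expect_equal(nrow(e$matched), 0)
    # insufficient pool warns and reports unmatched
    co3 <- toyCohort(gender = rep("male", 3), age = c(70, 70, 70),
                     apoe4 = c(1L, 1L, 0L))
    expect_warning(m3 <- matchApoeNoncarriers(co3), "unmatched")
    expect_equal(nrow(m3$matched), 1)
    expect_length(m3$unmatched, 1)
})

test_that("Hardy-Weinberg chi-square matches an independent oracle", {
    # (25, 10, 1) sits exactly at HW proportions for p = 5/6
    expect_equal(unname(hardyWeinbergTest(25, 10, 1)$statistic), 0)
    # perfect-fit and monomorphic cases
    expect_equal(unname(hardyWeinbergTest(49, 42, 9)$statistic), 0)
    expect_equal(unname(hardyWeinbergTest(0, 0, 100)$statistic), 0)
    # non-trivial counts against stats::chisq.test with HW probabilities
    counts <- c(30, 5, 1)
    p <- (2 * counts[1] + counts[2]) / (2 * sum(counts))
    oracle <- suppressWarnings(
        chisq.test(counts, p = c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    ours <- hardyWeinbergTest(30, 5, 1)
    expect_equal(unname(ours$statistic), unname(oracle$statistic))
    expect_equal(ours$p.value,
                 pchisq(unname(oracle$statistic), 1, lower.tail = FALSE))
    expect_error(hardyWeinbergTest(0, 0, 0), "positive total")
})
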