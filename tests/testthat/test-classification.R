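# Toy 1-D geometry: two points at x = -1 and x = +1, one per class.
# At large C the maximum-margin solution has w = 1, b = 0, so f(x) = x.
toyKernel <- function() {
    X <- matrix(c(-1, 1), 2, 1)
    list(X = X, K = linearKernel(X), y = c(-1, 1))
}

test_that("SVM dual solution reproduces the maximum-margin geometry", {
    toy <- toyKernel()
    fit <- trainSvm(toy$K, toy$y, Cparam = 100)
    # midpoint between singleton classes scores 0
    expect_equal(decisionValues(fit, matrix(c(0, 0), 1, 2)), 0,
                 tolerance = 1e-6)
    # support vectors sit on the margin: |f| = 1
    f <- decisionValues(fit, toy$K)
    expect_equal(f, c(-1, 1), tolerance = 1e-3)
    # dual constraints
    expect_lte(max(abs(fit@coefs)), 100 + 1e-6)
    expect_equal(sum(fit@coefs), 0, tolerance = 1e-6)
})

test_that("label flips negate decision values", {
    set.seed(6)
    X <- matrix(rnorm(80), 8)
    K <- linearKernel(X)
    y <- rep(c(-1, 1), 4)
    f1 <- decisionValues(trainSvm(K, y), K)
    f2 <- decisionValues(trainSvm(K, -y), K)
    expect_equal(f1, -f2, tolerance = 1e-4)
    # zero kernel block: decision reduces to the bias
    fit <- trainSvm(K, y)
    expect_equal(decisionValues(fit, matrix(0, 3, 8)),
                 rep(fit@b, 3))
    # duplicate test rows give identical decisions
    f3 <- decisionValues(fit, K[c(1, 1), ])
    expect_equal(f3[1], f3[2])
    expect_error(trainSvm(K, rep(1, 8)), "both classes")
})

test_that("separable toy set is classified without training error", {
    X <- rbind(c(-2, 0), c(-1.5, 0.5), c(1.5, -0.5), c(2, 0))
    y <- c(-1, -1, 1, 1)
    K <- linearKernel(X)
    fit <- trainSvm(K, y, Cparam = 100)
    expect_equal(sign(decisionValues(fit, K)), y)
})

test_that("classification metrics follow the standard formulas", {
    m <- classificationMetrics(tp = 4, fp = 0, tn = 4, fn = 0)
    expect_equal(unlist(m), c(accuracy = 1, sensitivity = 1,
                              specificity = 1))
    # empty denominators yield NA markers, not errors
    m2 <- classificationMetrics(tp = 0, fp = 2, tn = 3, fn = 0)
    expect_true(is.na(m2$sensitivity))
    expect_equal(m2$specificity, 0.6)
    expect_error(classificationMetrics(0, 0, 0, 0), "positive total")
})

test_that("leave-pair-out classification is balanced and leak-free", {
    X <- rbind(c(-2, 0), c(-1.8, 0.3), c(1.9, -0.2), c(2.1, 0.1))
    K <- linearKernel(X)
    y <- c(-1, -1, 1, 1)
    pairs <- cbind(c(1, 2), c(3, 4))
    res <- leavePairOutCv(K, y, pairs, Cparam = 10)
    expect_equal(res@accuracy, 1)
    # stored metrics equal metrics recomputed from per-subject rows
    ps <- res@perSubject
    expect_equal(res@accuracy, mean(ps$predicted == ps$label))
    expect_equal(unname(res@counts["tp"]),
                 sum(ps$predicted == 1 & ps$label == 1))
    # no leakage: a held-out subject's label does not affect its own
    # fold's decision values (other folds keep both classes)
    X6 <- rbind(X, c(-2.2, 0.1), c(2.2, -0.1))
    K6 <- linearKernel(X6)
    y6 <- c(-1, -1, 1, 1, -1, 1)
    p6 <- cbind(c(1, 2, 5), c(3, 4, 6))
    r6 <- leavePairOutCv(K6, y6, p6, Cparam = 10)
    y6b <- y6; y6b[1] <- 1
    r6b <- leavePairOutCv(K6, y6b, p6, Cparam = 10, checkPairs = FALSE)
    expect_equal(r6b@perSubject$decision[1], r6@perSubject$decision[1])
    expect_equal(r6b@perSubject$decision[3], r6@perSubject$decision[3])
    # malformed designs are rejected
    expect_error(leavePairOutCv(K, y, cbind(c(1, 2), c(3, 3))),
                 "partition")
    expect_error(leavePairOutCv(K, c(-1, 1, -1, 1), pairs), "one subject")
})

test_that("projection correlation tracks decision-score agreement", {
    sim <- defaultSim()
    wf <- kernelWorkflow(sim)
    ds <- riskSplitDesign(sim)
    res <- leavePairOutCv(wf$Kres[ds$rows, ds$rows], ds$labels, ds$pairs)
    fchdr <- sim$cohort$fchdr[ds$rows]
    prAll <- projectionCorrelation(res, fchdr, "all")
    expect_true(abs(prAll$r) <= 1)
    expect_equal(prAll$n, length(ds$rows))
    # decision values exactly affine in the score give r = 1
    fake <- res
    fake@perSubject$decision <- 2 * fchdr + 3
    expect_equal(projectionCorrelation(fake, fchdr, "all")$r, 1)
    # all-correct results make both subsets identical
    fake@perSubject$predicted <- fake@perSubject$label
    fake@perSubject$decision <- fchdr + rnorm(length(fchdr), 0, 0.1)
    expect_equal(projectionCorrelation(fake, fchdr, "correct")$r,
                 projectionCorrelation(fake, fchdr, "all")$r)
    # permutation p accompanies r on request
    pr <- projectionCorrelation(res, fchdr, "all", B = 39, seed = 3)
    expect_true(pr$p >= 0 && pr$p <= 1)
    expect_s4_class(pr$permutation, "PermutationResult")
})
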