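test_that("linear kernel is the Gram matrix of the features", {
    X <- rbind(c(1, 0), c(0, 1))
    expect_equal(linearKernel(X), diag(2))
    set.seed(1)
    M <- matrix(rnorm(30), 5)
    K <- linearKernel(M)
    expect_true(isSymmetric(K))
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
    # duplicated subjects give identical kernel rows
    K2 <- linearKernel(rbind(M, M[1, ]))
    expect_equal(unname(K2[1, ]), unname(K2[6, ]))
})

test_that("residual projector matches hand linear algebra", {
    # no confounds: identity
    expect_equal(residualMatrix(matrix(numeric(0), 4, 0), n = 4), diag(4))
    # intercept-only, n = 2: centering matrix
    R <- residualMatrix(cbind(rep(1, 2)))
    expect_equal(R, matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12)
    # full-rank design spanning the whole space annihilates everything
    expect_equal(residualMatrix(diag(3)), matrix(0, 3, 3),
                 tolerance = 1e-10)
    # properties on a random (rank-deficient) design
    set.seed(2)
    C <- cbind(1, rbinom(8, 1, 0.5))
    C <- cbind(C, C[, 2])                 # duplicated column
    R <- residualMatrix(C)
    expect_equal(R, t(R))
    expect_equal(R %*% R, R, tolerance = 1e-8)
    expect_equal(max(abs(R %*% C)), 0, tolerance = 1e-8)
})

test_that("kernel confound removal equals the Gram matrix of RX", {
    set.seed(3)
    for (rep in 1:5) {
        n <- sample(6:12, 1)
        X <- matrix(rnorm(n * 20), n)
        C <- cbind(1, rbinom(n, 1, 0.4))
        R <- residualMatrix(C)
        K <- linearKernel(X)
        Krm <- removeConfounds(K, C)
        expect_equal(Krm, linearKernel(R %*% X), tolerance = 1e-6,
                     ignore_attr = TRUE)
        expect_gte(min(eigen(Krm, symmetric = TRUE,
                             only.values = TRUE)$values), -1e-8)
    }
})

test_that("degenerate confound designs behave as limits", {
    set.seed(4)
    K <- linearKernel(matrix(rnorm(40), 5))
    # empty design: kernel unchanged
    expect_identical(removeConfounds(K, matrix(numeric(0), 5, 0)), K)
    # kernel = identity, ones confound, n = 2: R I R = R
    K2 <- removeConfounds(diag(2), cbind(rep(1, 2)))
    expect_equal(K2, matrix(c(0.5, -0.5, -0.5, 0.5), 2),
                 tolerance = 1e-12)
    # features exactly linear in the confounds are annihilated
    C <- cbind(1, c(0, 0, 1, 1, 0))
    Xc <- C %*% matrix(rnorm(2 * 15), 2)
    expect_equal(max(abs(removeConfounds(linearKernel(Xc), C))), 0,
                 tolerance = 1e-8)
    expect_error(removeConfounds(K, cbind(rep(1, 3))), "match")
})

test_that("fold-wise removal matches explicit train-estimated residuals", {
    set.seed(6)
    n <- 12
    X <- matrix(rnorm(n * 25), n)
    C <- cbind(1, rbinom(n, 1, 0.5))
    K <- linearKernel(X)
    train <- 1:9
    test <- 10:12
    kb <- removeConfoundsFold(K, C, train, test)
    # oracle: residualize features explicitly with train-fit coefficients
    beta <- MASS::ginv(crossprod(C[train, ])) %*% t(C[train, ]) %*% X[train, ]
    Xtr <- X[train, ] - C[train, ] %*% beta
    Xte <- X[test, ] - C[test, ] %*% beta
    expect_equal(kb$train, tcrossprod(Xtr), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(kb$test, Xte %*% t(Xtr), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # empty design passes blocks through unchanged
    kb0 <- removeConfoundsFold(K, matrix(numeric(0), n, 0), train, test)
    expect_equal(kb0$train, K[train, train], ignore_attr = TRUE)
})

test_that("trace normalization rescales to unit mean diagonal", {
    set.seed(5)
    K <- linearKernel(matrix(rnorm(60), 6))
    Kn <- normalizeKernel(K)
    expect_equal(mean(diag(Kn)), 1)
    expect_equal(attr(Kn, "kernelScale") * Kn, K, ignore_attr = TRUE)
})

test_that("kernel matrices round-trip through delimited text", {
    sim <- defaultSim()
    wf <- kernelWorkflow(sim)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeKernel(wf$K, path)
    back <- readKernel(path)
    expect_equal(back, wf$K, tolerance = 1e-12)
    expect_equal(colnames(back), sim$cohort$subject_id)
})

test_that("confound designs are built from cohort columns with intercept", {
    sim <- defaultSim()
    C <- confoundMatrix(sim$cohort)
    expect_equal(colnames(C), c("intercept", "apoe4"))
    expect_true(all(C[, "intercept"] == 1))
    expect_equal(C[, "apoe4"], as.numeric(sim$cohort$apoe4),
                 ignore_attr = TRUE)
    expect_equal(ncol(confoundMatrix(sim$cohort, character(0),
                                     intercept = FALSE)), 0)
    expect_error(confoundMatrix(sim$cohort, "nope"), "nope")
})
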