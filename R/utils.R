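# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

# Separable Gaussian blur of a 3-D array; sd in voxels, kernel truncated at
# 3 sd and renormalized at the edges (matrix operator per axis).
gaussianBlur3d <- function(arr, sd) {
    if (sd <= 0) return(arr)
    blurOp <- function(n) {
        idx <- seq_len(n)
        M <- exp(-outer(idx, idx, "-")^2 / (2 * sd^2))
        M[abs(outer(idx, idx, "-")) > ceiling(3 * sd)] <- 0
        M / rowSums(M)
    }
    d <- dim(arr)
    # axis 1
    x <- blurOp(d[1L]) %*% matrix(arr, d[1L])
    arr <- array(x, d)
    # axis 2
    arr <- aperm(arr, c(2L, 1L, 3L))
    x <- blurOp(d[2L]) %*% matrix(arr, d[2L])
    arr <- aperm(array(x, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
    # axis 3
    arr <- aperm(arr, c(3L, 1L, 2L))
    x <- blurOp(d[3L]) %*% matrix(arr, d[3L])
    aperm(array(x, d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

# Symmetrize a nearly-symmetric matrix (numerical hygiene after projections).
symmetrize <- function(M) (M + t(M)) / 2

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
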