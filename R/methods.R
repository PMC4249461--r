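#' @rdname GMImageSet-class
#' @export
setMethod("subjectIds", "GMImageSet", function(x) x@subjectIds)

#' @rdname GMImageSet-class
#' @export
setMethod("dim", "GMImageSet", function(x) dim(x@intensities))

#' @describeIn GMImageSet-class subset by subject (first index).
#' @param i subject index or id
#' @param j,...,drop ignored
#' @export
setMethod("[", "GMImageSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@subjectIds)
    new("GMImageSet",
        intensities = x@intensities[i, , , , drop = FALSE],
        affine = x@affine,
        subjectIds = x@subjectIds[i])
})

setMethod("show", "GMImageSet", function(object) {
    d <- dim(object@intensities)
    cat("GMImageSet:", d[1L], "subjects on a",
        paste(d[-1L], collapse = " x "), "voxel grid\n")
    cat("  intensity range:",
        paste(signif(range(object@intensities), 4), collapse = " - "), "\n")
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("maskArray", "FeatureMatrix", function(x) x@mask)

#' @rdname FeatureMatrix-class
#' @export
setMethod("subjectIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix:", nrow(object@values), "subjects x",
        ncol(object@values), "masked voxels (grid",
        paste(dim(object@mask), collapse = " x "), ")\n")
})

setMethod("show", "SvmFit", function(object) {
    cat("SvmFit [", object@type, "]: ", length(object@svIndex),
        " support vectors of ", length(object@coefs),
        " subjects, C = ", object@Cparam, sep = "")
    if (!is.na(object@epsilon)) cat(", epsilon =", object@epsilon)
    cat("\n")
})

fmtPct <- function(x) {
    ifelse(is.na(x), "undefined", sprintf("%.2f%%", 100 * x))
}

setMethod("show", "ClassificationResult", function(object) {
    cat("ClassificationResult over", nrow(object@perSubject), "subjects\n")
    cat("  accuracy:   ", fmtPct(object@accuracy), "\n")
    cat("  sensitivity:", fmtPct(object@sensitivity), "\n")
    cat("  specificity:", fmtPct(object@specificity), "\n")
})

setMethod("show", "RegressionResult", function(object) {
    cat("RegressionResult over", nrow(object@perSubject), "subjects\n")
    cat("  Pearson r:", signif(object@r, 4),
        " MSE (normalized scale):", signif(object@mse, 4), "\n")
})

#' @rdname PermutationResult-class
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

setMethod("show", "PermutationResult", function(object) {
    lab <- if (!object@addOne && object@pValue == 0)
        paste0("<= ", format(1 / object@B)) else format(object@pValue)
    cat("PermutationResult: observed =", signif(object@observed, 4),
        ", B =", object@B, ", tail =", object@tail, "\n")
    cat("  p =", lab, "\n")
})

setMethod("show", "WeightMap", function(object) {
    cat("WeightMap (", object@normalization, "): ",
        length(object@weights), " masked voxels, |w| range ",
        paste(signif(range(abs(object@weights)), 3), collapse = " - "),
        "\n", sep = "")
})
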