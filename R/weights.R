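#' Back-project a kernel model to a voxel weight map
#'
#' Recovers the primal weight vector of a linear-kernel SVM/SVR from its
#' dual coefficients, \eqn{w = (RX)' c}, in the residualized feature space
#' when the model was trained on a confound-removed kernel (mapping back
#' without R would misstate the pattern). Positive weights associate
#' higher gray matter with a higher predicted score. The weights form one
#' global multivariate pattern; it is not appropriate to draw regional
#' conclusions from single voxels.
#'
#' @param fit a [SvmFit-class] trained on the (confound-removed) kernel of
#'   \code{X}.
#' @param X the [FeatureMatrix-class] the kernel was computed from.
#' @param R optional residual projector used on the kernel (identity when
#'   omitted).
#' @param kernelScale trace-normalization factor applied to the kernel the
#'   model was trained on (the \code{"kernelScale"} attribute set by
#'   [normalizeKernel()]); features are divided by its square root so the
#'   primal weights reproduce the kernel decision values exactly.
#' @param normalize \code{"raw"} or \code{"unit"} (Euclidean norm 1).
#' @return a [WeightMap-class].
#' @export
computeWeights <- function(fit, X, R = NULL, kernelScale = 1,
                           normalize = c("raw", "unit")) {
    normalize <- match.arg(normalize)
    V <- if (is(X, "FeatureMatrix")) X@values else as.matrix(X)
    stopIfNot(nrow(V) == length(fit@coefs),
              "feature rows must match the training sample of the model")
    if (!is.null(R)) {
        stopIfNot(all(dim(R) == nrow(V)),
                  "projector dimensions must match the feature rows")
        V <- R %*% V
    }
    if (kernelScale != 1) V <- V / sqrt(kernelScale)
    w <- as.vector(crossprod(V, fit@coefs))
    if (normalize == "unit") {
        nrm <- sqrt(sum(w^2))
        stopIfNot(nrm > 0, "cannot unit-normalize an all-zero weight map")
        w <- w / nrm
    }
    mask <- if (is(X, "FeatureMatrix")) X@mask
            else array(TRUE, c(ncol(V), 1L, 1L))
    new("WeightMap", weights = w, mask = mask, normalization = normalize)
}

#' Render a weight map as a 3-D array
#'
#' @param map a [WeightMap-class].
#' @return numeric array, zero outside the mask.
#' @export
weightArray <- function(map) unmask(map@weights, map@mask)

#' Write a weight map to NIfTI with a JSON sidecar
#'
#' Voxels outside the mask are written as 0; a sidecar
#' \code{<path>.json} records the normalization and any extra metadata
#' (model configuration, subgroup). Weights are stored at double
#' precision, so a round-trip read reproduces them exactly.
#'
#' @param map a [WeightMap-class].
#' @param affine 4x4 voxel-to-world transform.
#' @param path output NIfTI path (e.g. \code{weights.nii.gz}).
#' @param metadata optional named list merged into the sidecar.
#' @return invisible \code{path}.
#' @export
writeWeightMap <- function(map, affine, path, metadata = list()) {
    arr <- weightArray(map)
    img <- RNifti::asNifti(arr)
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::writeNifti(img, path, datatype = "double")
    side <- c(list(normalization = map@normalization,
                   maskedVoxels = length(map@weights),
                   gridShape = dim(map@mask),
                   note = paste("Weights form one global multivariate",
                                "pattern; single-voxel or regional",
                                "inference is not appropriate.")),
              metadata)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
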