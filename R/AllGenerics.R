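#' @rdname GMImageSet-class
#' @param object,x a \code{GMImageSet}, \code{FeatureMatrix} or result object
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Decision values of a fitted kernel model
#'
#' Evaluates \eqn{f(x) = \sum_i c_i K(x, x_i) + b} for test subjects given
#' the test-by-training kernel block.
#'
#' @param fit a [SvmFit-class] object.
#' @param K numeric matrix, test subjects x training subjects, of inner
#'   products against the training sample (same subject order as used in
#'   training).
#' @return numeric vector of decision values, one per test row.
#' @export
setGeneric("decisionValues", function(fit, K) standardGeneric("decisionValues"))

#' @rdname PermutationResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
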