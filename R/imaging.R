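#' Read gray-matter probability maps into a GMImageSet
#'
#' Accepts either one NIfTI path per subject (3-D volumes) or a single 4-D
#' NIfTI file holding the whole stack. All volumes must share grid shape
#' and affine; a mismatch is reported with the offending file.
#'
#' @param paths character vector of NIfTI file paths.
#' @param subjectIds optional ids; defaults to file base names (or
#'   \code{V001...} for a 4-D file).
#' @return a [GMImageSet-class].
#' @export
readImages <- function(paths, subjectIds = NULL) {
    stopIfNot(all(file.exists(paths)),
              paste("missing image file(s):",
                    paste(paths[!file.exists(paths)], collapse = ", ")))
    vols <- lapply(paths, RNifti::readNifti)
    if (length(paths) == 1L && length(dim(vols[[1L]])) == 4L) {
        v <- vols[[1L]]
        d <- dim(v)
        arr <- aperm(array(as.numeric(v), d), c(4L, 1L, 2L, 3L))
        ids <- if (is.null(subjectIds)) sprintf("V%03d", seq_len(d[4L]))
               else subjectIds
        return(new("GMImageSet", intensities = arr,
                   affine = matrix(as.numeric(RNifti::xform(v)), 4L, 4L),
                   subjectIds = ids))
    }
    d0 <- dim(vols[[1L]])
    a0 <- matrix(as.numeric(RNifti::xform(vols[[1L]])), 4L, 4L)
    for (i in seq_along(vols)) {
        if (!identical(dim(vols[[i]]), d0))
            stop("image shape mismatch in file '", paths[i], "'",
                 call. = FALSE)
        ai <- matrix(as.numeric(RNifti::xform(vols[[i]])), 4L, 4L)
        if (max(abs(ai - a0)) > 1e-4)
            stop("affine mismatch in file '", paths[i], "'", call. = FALSE)
    }
    arr <- array(0, c(length(vols), d0))
    for (i in seq_along(vols)) arr[i, , , ] <- as.numeric(vols[[i]])
    ids <- if (is.null(subjectIds))
        vapply(paths, function(p) sub("\\.nii(\\.gz)?$", "", basename(p)),
               character(1L), USE.NAMES = FALSE)
    else subjectIds
    new("GMImageSet", intensities = arr, affine = a0, subjectIds = ids)
}

#' Write a GMImageSet to NIfTI
#'
#' Writes one 3-D NIfTI file per subject (\code{<id>.nii.gz} under
#' \code{dir}); a round-trip through [readImages()] reproduces the
#' intensities exactly.
#'
#' @param images a [GMImageSet-class].
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
writeImageSet <- function(images, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(images@subjectIds, ".nii.gz"))
    for (i in seq_along(paths)) {
        vol <- images@intensities[i, , , ]
        img <- RNifti::asNifti(vol)
        RNifti::qform(img) <- structure(images@affine, code = 2L)
        RNifti::writeNifti(img, paths[i], datatype = "double")
    }
    invisible(paths)
}

#' Build the gray-matter analysis mask
#'
#' Voxels with a gray-matter probability below the threshold are discarded;
#' voxels exactly at the threshold are kept. The common mask across
#' subjects uses either the across-subject mean intensity
#' (\code{rule = "mean"}, default) or requires every subject to reach the
#' threshold (\code{rule = "all"}).
#'
#' @param images a [GMImageSet-class].
#' @param threshold gray-matter probability cutoff in \eqn{[0, 1]}
#'   (default 0.15).
#' @param rule \code{"mean"} or \code{"all"}.
#' @return logical 3-D array.
#' @export
buildMask <- function(images, threshold = 0.15, rule = c("mean", "all")) {
    rule <- match.arg(rule)
    stopIfNot(threshold >= 0 && threshold <= 1,
              "threshold must lie in [0, 1]")
    arr <- images@intensities
    mask <- if (rule == "mean") {
        apply(arr, c(2L, 3L, 4L), mean) >= threshold
    } else {
        apply(arr, c(2L, 3L, 4L), min) >= threshold
    }
    if (!any(mask))
        stop("empty mask: no voxel reaches the threshold in the ",
             "required subjects", call. = FALSE)
    mask
}

#' Flatten masked voxels into a subject-by-voxel feature matrix
#'
#' Columns follow the native column-major order of the voxel grid, which is
#' fixed and reproducible; values are copied unmodified.
#'
#' @param images a [GMImageSet-class].
#' @param mask logical array from [buildMask()].
#' @return a [FeatureMatrix-class].
#' @export
vectorizeImages <- function(images, mask) {
    stopIfNot(identical(dim(mask), dim(images@intensities)[-1L]),
              "mask shape must match the image grid")
    n <- dim(images@intensities)[1L]
    flat <- matrix(images@intensities, nrow = n)  # subjects x all voxels
    values <- flat[, as.vector(mask), drop = FALSE]
    rownames(values) <- images@subjectIds
    new("FeatureMatrix", values = values, mask = mask,
        voxelIndex = which(mask, arr.ind = TRUE), affine = images@affine)
}

#' Map a masked-voxel vector back onto the 3-D grid
#'
#' Inverse of the flattening done by [vectorizeImages()] for a single
#' subject or weight vector; voxels outside the mask are filled with
#' \code{fill}.
#'
#' @param values numeric vector with one entry per TRUE mask voxel.
#' @param mask logical 3-D array.
#' @param fill value for voxels outside the mask (default 0).
#' @return numeric 3-D array.
#' @export
unmask <- function(values, mask, fill = 0) {
    stopIfNot(length(values) == sum(mask),
              "values length must equal the number of TRUE mask voxels")
    out <- array(fill, dim(mask))
    out[mask] <- values
    out
}
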