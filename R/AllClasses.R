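#' @import methods
NULL

.UNIT_TOL <- 1e-6

#' NormalMap: a dense field of unit surface normals
#'
#' The central data container: an H x W grid of outward unit 3-vectors,
#' stored as an H x W x 3 array (x, y, z components). The grid is row-major
#' with origin at the top-left pixel. Skin patches follow the outward
#' convention z > 0 everywhere.
#'
#' @slot normals numeric array, H x W x 3, every pixel unit length.
#'
#' @examples
#' nm <- flatNormalMap(8, 8)
#' dim(nm)
#' @export
setClass("NormalMap", representation(normals = "array"))

setValidity("NormalMap", function(object) {
    a <- object@normals
    if (length(dim(a)) != 3L || dim(a)[3] != 3L)
        return("normals must be an H x W x 3 array")
    if (any(!is.finite(a)))
        return("normals contain non-finite values")
    nrm <- sqrt(a[, , 1]^2 + a[, , 2]^2 + a[, , 3]^2)
    if (any(abs(nrm - 1) > .UNIT_TOL))
        return(sprintf("normals deviate from unit length by up to %g",
                       max(abs(nrm - 1))))
    if (any(a[, , 3] <= 0))
        return("normal z components must be strictly positive")
    TRUE
})

#' RotationField: per-pixel rotations from a normal map to its smoothed version
#'
#' Each pixel carries the axis-angle rotation taking the original normal onto
#' the smoothed (low-frequency) normal at the same pixel, i.e. the
#' high-frequency residual of the surface.
#'
#' @slot axis numeric array, H x W x 3, unit rotation axes.
#' @slot angle numeric matrix, H x W, rotation angles in [0, pi] (radians).
#' @slot radius numeric, smoothing radius in pixels used to produce the field.
#'
#' @export
setClass("RotationField",
         representation(axis = "array", angle = "matrix", radius = "numeric"))

setValidity("RotationField", function(object) {
    d <- dim(object@axis)
    if (length(d) != 3L || d[3] != 3L)
        return("axis must be an H x W x 3 array")
    if (!all(d[1:2] == dim(object@angle)))
        return("axis and angle dimensions disagree")
    if (any(object@angle < 0 | object@angle > pi + 1e-12))
        return("angles must lie in [0, pi]")
    nrm <- sqrt(object@axis[, , 1]^2 + object@axis[, , 2]^2 +
                object@axis[, , 3]^2)
    if (any(abs(nrm - 1) > 1e-6))
        return("rotation axes must be unit length")
    TRUE
})

#' RotationPyramid: multi-resolution rotation-field decomposition
#'
#' Ordered levels of (high-frequency RotationField, low-frequency NormalMap)
#' pairs; spatial dimensions halve (integer floor) from one level to the next
#' and level 1 matches the input dimensions.
#'
#' @slot fields list of \linkS4class{RotationField}, one per level.
#' @slot lows list of \linkS4class{NormalMap} (the smoothed map at each level).
#' @slot radius numeric, smoothing radius shared by all levels.
#'
#' @export
setClass("RotationPyramid",
         representation(fields = "list", lows = "list", radius = "numeric"))

setValidity("RotationPyramid", function(object) {
    if (length(object@fields) != length(object@lows))
        return("fields and lows must have the same number of levels")
    if (length(object@fields) < 1L) return("at least one level required")
    TRUE
})

#' APDIPyramid: azimuthal projection distance images at halving resolutions
#'
#' @slot images list of numeric matrices, level 1 at native resolution.
#' @slot variant character, "original_L2" or "modified_arc".
#' @slot meanMode character, "fixed" or "local".
#' @slot window numeric, local-mean window in pixels (odd).
#'
#' @export
setClass("APDIPyramid",
         representation(images = "list", variant = "character",
                        meanMode = "character", window = "numeric"))

#' LabeledPatch: a synthetic or imported skin patch with ground truth
#'
#' @slot normal \linkS4class{NormalMap} of the patch.
#' @slot albedo numeric matrix (greyscale albedo), same dimensions.
#' @slot height numeric matrix, the generating height field (pixels), or a
#'   0 x 0 matrix when unknown.
#' @slot condition character, one of "wrinkles", "pores", "acne", "smooth".
#' @slot severity integer severity grade 1-5 (1 = clear skin).
#' @slot ratings numeric vector of simulated/collected rater scores (may be
#'   empty).
#'
#' @export
setClass("LabeledPatch",
         representation(normal = "NormalMap", albedo = "matrix",
                        height = "matrix", condition = "character",
                        severity = "integer", ratings = "numeric"))

setValidity("LabeledPatch", function(object) {
    if (!object@condition %in% c("wrinkles", "pores", "acne", "smooth"))
        return("unknown condition")
    if (object@severity < 1L || object@severity > 5L)
        return("severity must be in 1..5")
    if (!all(dim(object@albedo) == dim(object@normal)))
        return("albedo dimensions must match the normal map")
    TRUE
})

#' EvalReport: cross-validated classification results
#'
#' @slot perClass data.frame with per-class precision, recall and F-measure.
#' @slot weightedF numeric, support-weighted mean F-measure.
#' @slot macroF numeric, unweighted mean F-measure.
#' @slot confusion table of predicted vs true labels pooled over folds.
#' @slot folds integer vector of fold assignments.
#' @slot seed integer seed used for folding and training.
#' @slot config list snapshot of classifier/selection settings.
#'
#' @export
setClass("EvalReport",
         representation(perClass = "data.frame", weightedF = "numeric",
                        macroF = "numeric", confusion = "table",
                        folds = "integer", seed = "integer", config = "list"))

#' @describeIn NormalMap dimensions (H, W) of the pixel grid.
#' @param x a NormalMap.
#' @export
setMethod("dim", "NormalMap", function(x) dim(x@normals)[1:2])

#' @describeIn RotationField dimensions (H, W) of the field.
#' @param x a RotationField.
#' @export
setMethod("dim", "RotationField", function(x) dim(x@angle))

setMethod("show", "NormalMap", function(object) {
    d <- dim(object)
    z <- object@normals[, , 3]
    cat(sprintf("NormalMap: %d x %d pixels, mean slant %.2f deg\n",
                d[1], d[2], mean(acos(pmin(z, 1))) * 180 / pi))
})

setMethod("show", "RotationField", function(object) {
    d <- dim(object)
    cat(sprintf(
        "RotationField: %d x %d pixels (r = %g px), mean angle %.4f rad\n",
        d[1], d[2], object@radius, mean(object@angle)))
})

setMethod("show", "RotationPyramid", function(object) {
    dims <- vapply(object@fields, function(f) paste(dim(f), collapse = "x"),
                   character(1))
    cat(sprintf("RotationPyramid: %d levels (%s), r = %g px\n",
                length(object@fields), paste(dims, collapse = ", "),
                object@radius))
})

setMethod("show", "APDIPyramid", function(object) {
    dims <- vapply(object@images, function(m) paste(dim(m), collapse = "x"),
                   character(1))
    cat(sprintf("APDIPyramid: %s, depth %d (%s), %s mean\n",
                object@variant, length(object@images),
                paste(dims, collapse = ", "), object@meanMode))
})

setMethod("show", "LabeledPatch", function(object) {
    cat(sprintf("LabeledPatch: %s, severity %d, %d x %d px, %d rating(s)\n",
                object@condition, object@severity,
                dim(object@normal)[1], dim(object@normal)[2],
                length(object@ratings)))
})

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport: weighted F = %.3f, macro F = %.3f (%d folds)\n",
                object@weightedF, object@macroF,
                length(unique(object@folds))))
    print(object@perClass, row.names = FALSE)
})

#' Accessors
#'
#' Small accessor functions for the package's S4 containers, preferred over
#' direct slot access.
#'
#' @param x an object of the matching class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
normals <- function(x) {
    stopifnot(is(x, "NormalMap"))
    x@normals
}

#' @rdname accessors
#' @export
rotationAngles <- function(x) {
    stopifnot(is(x, "RotationField"))
    x@angle
}

#' @rdname accessors
#' @export
rotationAxes <- function(x) {
    stopifnot(is(x, "RotationField"))
    x@axis
}

#' @rdname accessors
#' @export
pyramidLevels <- function(x) {
    if (is(x, "RotationPyramid")) return(length(x@fields))
    if (is(x, "APDIPyramid")) return(length(x@images))
    stop("not a pyramid object")
}

#' @rdname accessors
#' @export
apdiImages <- function(x) {
    stopifnot(is(x, "APDIPyramid"))
    x@images
}

#' @rdname accessors
#' @export
patchNormalMap <- function(x) {
    stopifnot(is(x, "LabeledPatch"))
    x@normal
}

#' @rdname accessors
#' @export
patchAlbedo <- function(x) {
    stopifnot(is(x, "LabeledPatch"))
    x@albedo
}

#' @rdname accessors
#' @export
patchCondition <- function(x) {
    stopifnot(is(x, "LabeledPatch"))
    x@condition
}

#' @rdname accessors
#' @export
patchSeverity <- function(x) {
    stopifnot(is(x, "LabeledPatch"))
    x@severity
}

#' @rdname accessors
#' @export
patchRatings <- function(x) {
    stopifnot(is(x, "LabeledPatch"))
    x@ratings
}

#' @rdname accessors
#' @export
weightedF <- function(x) {
    stopifnot(is(x, "EvalReport"))
    x@weightedF
}

#' @rdname accessors
#' @export
perClassF <- function(x) {
    stopifnot(is(x, "EvalReport"))
    x@perClass
}
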