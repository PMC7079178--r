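# Proposed method III: original and modified Azimuthal Projection Distance
# Images (APDI) and their multi-resolution pyramid features. Normals are
# projected onto the tangent plane of a reference mean normal; the scalar
# image is either the L2 norm of the projected point (original) or the
# azimuth-sensitive arc value (modified). The modified descriptor uses
# per-pixel local mean normals, removing the low-frequency bias that a
# fixed projection reference retains.

#' Azimuthal projection of a normal map
#'
#' Per-pixel tangent-plane coordinates (x, y) of each normal about a
#' reference mean normal: either the fixed vertical (0, 0, 1)
#' (\code{meanMode = "fixed"}, the original formulation) or the local mean
#' over a window (\code{meanMode = "local"}). The scale factor is
#' k' = c / sin(c) with the limit k' = 1 at c = 0.
#'
#' Two conventions for c are provided. \code{"literal"} (default)
#' transcribes the source formulation exactly: for local means,
#' c = sin(tb) sin(t) + cos(t) cos(p - pb); for the fixed mean, c = sin(t)
#' with the simplified coordinate equations (t, p: elevation and azimuth;
#' tb, pb: their means). \code{"standard"} uses the great-circle relation
#' cos c = sin(tb) sin(t) + cos(tb) cos(t) cos(p - pb), which makes the
#' projection the exact azimuthal-equidistant chart: the norm of (x, y)
#' then equals the geodesic angle between normal and mean. The two differ
#' only in radial scaling.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param meanMode "local" or "fixed".
#' @param window odd local-mean window in pixels.
#' @param cMode "literal" or "standard" (see Details).
#' @param meanMethod smoothing mean for the local reference,
#'   "euclidean" (default, fast) or "geodesic".
#' @return list with coordinate matrices \code{x} and \code{y}.
#' @export
azimuthalProjection <- function(N, meanMode = c("local", "fixed"),
                                window = 15L,
                                cMode = c("literal", "standard"),
                                meanMethod = c("euclidean", "geodesic")) {
    meanMode <- match.arg(meanMode)
    cMode <- match.arg(cMode)
    meanMethod <- match.arg(meanMethod)
    a <- .comps(normals(N))
    th <- .sphTheta(a$z)
    ph <- .sphPhi(a$x, a$y)
    if (meanMode == "fixed") {
        if (cMode == "literal") {
            # simplified fixed-mean equations as printed: c = sin(theta)
            cc <- sin(th)
            k <- ifelse(abs(cc) < 1e-12, 1, cc / sin(cc))
            return(list(x = k * cos(th) * sin(ph),
                        y = k * cos(th) * cos(ph)))
        }
        tb <- matrix(pi / 2, nrow(th), ncol(th))
        pb <- matrix(0, nrow(th), ncol(th))
    } else {
        if (window %% 2L == 0L) stop("window must be odd")
        mu <- smoothNormalMap(N, r = (window - 1L) %/% 2L,
                              method = meanMethod)
        m <- .comps(normals(mu))
        tb <- .sphTheta(m$z)
        pb <- .sphPhi(m$x, m$y)
    }
    dp <- ph - pb
    if (cMode == "standard") {
        cc <- acos(.clamp(sin(tb) * sin(th) + cos(tb) * cos(th) * cos(dp)))
    } else {
        cc <- sin(tb) * sin(th) + cos(th) * cos(dp)
    }
    sc <- sin(cc)
    k <- ifelse(abs(cc) < 1e-12, 1, cc / ifelse(abs(sc) < 1e-300, 1e-300, sc))
    list(x = k * cos(th) * sin(dp),
         y = k * (cos(tb) * sin(th) - sin(tb) * cos(th) * cos(dp)))
}

#' APDI pixel value from projected coordinates
#'
#' \code{"original_L2"}: sqrt(x^2 + y^2), the distance from the projection
#' centre - constant for all normals sharing a polar offset, blind to
#' azimuth. \code{"modified_arc"}: atan2(x, y) * sqrt(x^2 + y^2), the arc
#' from the x-axis to the projected point, which varies with azimuth as
#' well (atan2(0, 0) is taken as 0 so flat regions score 0 in both
#' variants).
#'
#' @param x,y projected coordinates (vectors or matrices).
#' @param variant "modified_arc" or "original_L2".
#' @return numeric values, same shape as the inputs.
#' @export
apdiValue <- function(x, y, variant = c("modified_arc", "original_L2")) {
    variant <- match.arg(variant)
    r <- sqrt(x^2 + y^2)
    if (variant == "original_L2") return(r)
    atan2(x, y) * r
}

#' Azimuthal Projection Distance Image
#'
#' Composition of [azimuthalProjection()] and [apdiValue()] at every pixel.
#' With local means a constant map projects to identically 0.
#'
#' @inheritParams azimuthalProjection
#' @inheritParams apdiValue
#' @return numeric H x W matrix with projection settings in attributes.
#' @export
apdiImage <- function(N, variant = c("modified_arc", "original_L2"),
                      meanMode = c("local", "fixed"), window = 15L,
                      cMode = c("literal", "standard"),
                      meanMethod = c("euclidean", "geodesic")) {
    variant <- match.arg(variant)
    meanMode <- match.arg(meanMode)
    cMode <- match.arg(cMode)
    meanMethod <- match.arg(meanMethod)
    p <- azimuthalProjection(N, meanMode = meanMode, window = window,
                             cMode = cMode, meanMethod = meanMethod)
    img <- apdiValue(p$x, p$y, variant = variant)
    attr(img, "variant") <- variant
    attr(img, "meanMode") <- meanMode
    attr(img, "window") <- window
    img
}

#' Multi-resolution APDI pyramid
#'
#' Level i is the APDI of the normal map down-sampled by 2^(i-1) with the
#' geodesic resampling algorithm (window 2^(i-1) x 2^(i-1)); level 1 is the
#' native-resolution APDI. Deeper levels trade pore-scale detail for the
#' larger structures (acne-scale spots) that the native level misses.
#'
#' @inheritParams apdiImage
#' @param depth number of levels; dims must be >= 2^(depth-1).
#' @return an \linkS4class{APDIPyramid}.
#' @export
apdiPyramid <- function(N, depth = 4L,
                        variant = c("modified_arc", "original_L2"),
                        meanMode = c("local", "fixed"), window = 15L,
                        cMode = c("literal", "standard"),
                        meanMethod = c("euclidean", "geodesic")) {
    variant <- match.arg(variant)
    meanMode <- match.arg(meanMode)
    cMode <- match.arg(cMode)
    meanMethod <- match.arg(meanMethod)
    depth <- as.integer(depth)
    if (depth < 1L) stop("depth must be >= 1")
    if (any(dim(N) < 2^(depth - 1L))) stop("map too small for depth ", depth)
    imgs <- vector("list", depth)
    for (i in seq_len(depth)) {
        S <- 2L^(i - 1L)
        Ni <- if (S == 1L) N else
            downsampleNormalMap(N, S, window = c(S, S))
        imgs[[i]] <- apdiImage(Ni, variant = variant, meanMode = meanMode,
                               window = window, cMode = cMode,
                               meanMethod = meanMethod)
    }
    new("APDIPyramid", images = imgs, variant = variant,
        meanMode = meanMode, window = as.numeric(window))
}

#' APDI pyramid feature vector
#'
#' A grey-level histogram per pyramid level, concatenated: length
#' bins * depth (e.g. 512 for 128 bins and 4 levels). By default each
#' level is binned over its own min-max range; \code{range} fixes a common
#' binning range for cross-patch comparability (values outside are
#' clamped), which the classification pipeline uses. A constant level puts
#' all mass in its first bin.
#'
#' @param P an \linkS4class{APDIPyramid}.
#' @param bins histogram bins per level (>= 2).
#' @param range optional fixed c(lo, hi) binning range.
#' @return numeric feature vector with descriptor metadata attributes.
#' @export
apdiFeatures <- function(P, bins = 128L, range = NULL) {
    bins <- as.integer(bins)
    if (bins < 2L) stop("bins must be >= 2")
    out <- lapply(P@images, function(img) {
        v <- as.vector(img)
        rg <- if (is.null(range)) base::range(v) else range
        if (diff(rg) == 0)
            return(c(length(v), numeric(bins - 1L)))
        v <- .clamp(v, rg[1], rg[2])
        .histCounts(v, seq(rg[1], rg[2], length.out = bins + 1L))
    })
    v <- unlist(out)
    attr(v, "descriptor") <- paste0("apdi_", P@variant)
    attr(v, "params") <- list(depth = length(P@images), bins = bins,
                              meanMode = P@meanMode, window = P@window)
    v
}
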