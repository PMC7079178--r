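# Normal-map container operations: I/O, derived channel maps, geodesic
# smoothing and resampling. All pixel grids are row-major with the origin
# at the top-left pixel.

#' Construct a NormalMap
#'
#' @param a numeric H x W x 3 array of normal components.
#' @param renormalise logical; rescale each pixel to exact unit length first.
#' @return a \linkS4class{NormalMap}.
#' @export
NormalMap <- function(a, renormalise = FALSE) {
    if (renormalise) a <- .renorm3(a)
    new("NormalMap", normals = a)
}

#' @rdname NormalMap
#' @param nx,ny,nz component matrices of equal dimensions.
#' @export
normalMapFromComponents <- function(nx, ny, nz, renormalise = TRUE) {
    NormalMap(.bind3(nx, ny, nz), renormalise = renormalise)
}

#' @rdname NormalMap
#' @param H,W grid dimensions for a constant upward-facing map.
#' @export
flatNormalMap <- function(H, W = H) {
    NormalMap(.bind3(matrix(0, H, W), matrix(0, H, W), matrix(1, H, W)))
}

#' Normal map of a height field
#'
#' Normals of the surface z = h(x, y): the normalised
#' (-dh/dx, -dh/dy, 1). Gradients use central differences in the interior
#' and one-sided differences at the borders, with x along columns and y
#' along rows (units: height in pixels).
#'
#' @param h numeric matrix, the height field.
#' @return a \linkS4class{NormalMap}.
#' @export
normalMapFromHeight <- function(h) {
    g <- .heightGradient(h)
    normalMapFromComponents(-g$hx, -g$hy, matrix(1, nrow(h), ncol(h)))
}

.heightGradient <- function(h) {
    H <- nrow(h); W <- ncol(h)
    hx <- matrix(0, H, W); hy <- matrix(0, H, W)
    if (W >= 3) hx[, 2:(W - 1)] <- (h[, 3:W] - h[, 1:(W - 2)]) / 2
    if (W >= 2) {
        hx[, 1] <- h[, 2] - h[, 1]
        hx[, W] <- h[, W] - h[, W - 1]
    }
    if (H >= 3) hy[2:(H - 1), ] <- (h[3:H, ] - h[1:(H - 2), ]) / 2
    if (H >= 2) {
        hy[1, ] <- h[2, ] - h[1, ]
        hy[H, ] <- h[H, ] - h[H - 1, ]
    }
    list(hx = hx, hy = hy)
}

#' Read and write normal maps
#'
#' \code{encoding = "rgb8"} is the common 8-bit RGB PNG convention with
#' component = 2 * value - 1 (flat surface encodes as RGB (128, 128, 255));
#' decoded normals are renormalised to unit length. \code{encoding =
#' "float"} is a lossless plain-text container (header "H W", then one
#' "nx ny nz" triple per line in row-major order) for exact round-trips.
#'
#' @param path file path.
#' @param encoding "rgb8" or "float".
#' @param flipZ logical; flip pixels with non-positive z instead of
#'   rejecting the file.
#' @return \code{readNormalMap} returns a \linkS4class{NormalMap};
#'   \code{writeNormalMap} returns \code{path} invisibly.
#' @export
readNormalMap <- function(path, encoding = c("rgb8", "float"),
                          flipZ = FALSE) {
    encoding <- match.arg(encoding)
    if (!file.exists(path)) stop("no such file: ", path)
    if (encoding == "rgb8") {
        v <- png::readPNG(path)
        if (length(dim(v)) != 3L || dim(v)[3] < 3L)
            stop("rgb8 normal maps need a 3-channel PNG")
        a <- 2 * v[, , 1:3] - 1
    } else {
        ln <- readLines(path)
        hd <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
        vals <- scan(text = ln[-1], quiet = TRUE)
        a <- aperm(array(vals, c(3L, hd[2], hd[1])), c(3, 2, 1))
    }
    if (any(!is.finite(a))) stop("non-finite values in normal map")
    if (any(a[, , 3] <= 0)) {
        if (flipZ) a[, , 3] <- abs(a[, , 3])
        else stop("normal map contains pixels with z <= 0 ",
                  "(use flipZ = TRUE to flip them)")
    }
    NormalMap(a, renormalise = TRUE)
}

#' @rdname readNormalMap
#' @param N a \linkS4class{NormalMap} to write.
#' @export
writeNormalMap <- function(N, path, encoding = c("rgb8", "float")) {
    encoding <- match.arg(encoding)
    a <- normals(N)
    if (encoding == "rgb8") {
        png::writePNG((a + 1) / 2, path)
    } else {
        d <- dim(a)
        flat <- aperm(a, c(3, 2, 1))
        writeLines(c(paste(d[1], d[2]),
                     paste(format(flat[seq(1, length(flat), 3)], digits = 17),
                           format(flat[seq(2, length(flat), 3)], digits = 17),
                           format(flat[seq(3, length(flat), 3)], digits = 17))),
                   path)
    }
    invisible(path)
}

#' Slant-tilt map of a normal map
#'
#' Per pixel, the tangents of the normal's slant (angle from the z axis)
#' and tilt (azimuth): \code{tan(sigma) = sqrt(nx^2 + ny^2) / nz},
#' \code{tan(tau) = ny / nx}. Degenerate tilt at nx = 0 takes
#' \code{sign(ny) * clipLarge} (0 when ny is also 0), and both channels are
#' clipped to \code{[-clipLarge, clipLarge]}. With \code{rescale = TRUE}
#' each channel is then affinely rescaled per patch to [-1, 1] (tangent
#' values are unbounded, so rescaling is what bounds the map); constant
#' channels rescale to 0.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param rescale logical; rescale each channel to [-1, 1].
#' @param clipLarge magnitude cap for the raw tangent values.
#' @return list with matrices \code{slant} and \code{tilt}.
#' @export
slantTilt <- function(N, rescale = TRUE, clipLarge = 1e6) {
    a <- .comps(normals(N))
    ts <- sqrt(a$x^2 + a$y^2) / a$z
    tt <- ifelse(a$x == 0, sign(a$y) * clipLarge, a$y / a$x)
    ts <- .clamp(ts, -clipLarge, clipLarge)
    tt <- .clamp(tt, -clipLarge, clipLarge)
    if (rescale) {
        ts <- .rescale11(ts)
        tt <- .rescale11(tt)
    }
    list(slant = ts, tilt = tt)
}

.rescale11 <- function(m) {
    rg <- range(m)
    if (diff(rg) == 0) return(m * 0)
    2 * (m - rg[1]) / diff(rg) - 1
}

#' Tangent map: chart coordinates about local geodesic means
#'
#' Per pixel, the neighbourhood geodesic mean (Gaussian weights, window
#' \code{window} pixels) is computed and the central normal is unfolded
#' about it with the logarithmic map, giving a two-channel map of tangent
#' coordinates. Pixels equal to their local mean map to (0, 0).
#'
#' @param N a \linkS4class{NormalMap}.
#' @param window odd window size in pixels (>= 3).
#' @param method "geodesic" or "euclidean" neighbourhood mean.
#' @return list with coordinate matrices \code{x} and \code{y}.
#' @export
tangentMap <- function(N, window = 5L, method = c("geodesic", "euclidean")) {
    method <- match.arg(method)
    if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
    mu <- smoothNormalMap(N, r = window %/% 2L, method = method)
    a <- .comps(normals(N)); m <- .comps(normals(mu))
    r <- .logChartC(a$x, a$y, a$z, m$x, m$y, m$z)
    list(x = r$x, y = r$y)
}

# One shift of a matrix by (dy, dx) with zero fill; mask marks valid source.
.shiftM <- function(m, dy, dx) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dy):min(H, H + dy)
    cs <- max(1, 1 + dx):min(W, W + dx)
    if (length(rs) > 0 && length(cs) > 0)
        out[rs, cs] <- m[rs - dy, cs - dx]
    out
}

#' Smooth a normal map by per-pixel weighted means
#'
#' Replaces every normal by the Gaussian-weighted mean of its neighbourhood
#' (radius \code{r} pixels, sigma = r/2, kernel truncated at r). The
#' geodesic method runs the Karcher fixed-point iteration at every pixel
#' simultaneously; the Euclidean method takes the arithmetic mean of the
#' components followed by the required post-normalisation. Windows at the
#' image border are truncated and their weights renormalised.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param r neighbourhood radius in pixels (>= 1).
#' @param method "geodesic" (default) or "euclidean".
#' @param tol,maxIter Karcher iteration controls (geodesic method).
#' @return smoothed \linkS4class{NormalMap}.
#' @export
smoothNormalMap <- function(N, r, method = c("geodesic", "euclidean"),
                            tol = 1e-9, maxIter = 100L) {
    method <- match.arg(method)
    if (r < 1) stop("r must be >= 1")
    a <- .comps(normals(N))
    k <- .gauss1d(r)
    ones <- matrix(1, nrow(a$x), ncol(a$x))
    wsum <- .sepConv2(ones, k)
    mx <- .sepConv2(a$x, k) / wsum
    my <- .sepConv2(a$y, k) / wsum
    mz <- .sepConv2(a$z, k) / wsum
    nrm <- sqrt(mx^2 + my^2 + mz^2)
    mx <- mx / nrm; my <- my / nrm; mz <- mz / nrm
    if (method == "euclidean")
        return(normalMapFromComponents(mx, my, mz, renormalise = FALSE))
    # Karcher iteration, all pixels at once, initialised at the Euclidean
    # mean field computed above.
    offs <- expand.grid(dy = -r:r, dx = -r:r)
    wk <- outer(k, k)
    for (it in seq_len(maxIter)) {
        Tx <- Ty <- Tz <- Wa <- matrix(0, nrow(mx), ncol(mx))
        for (o in seq_len(nrow(offs))) {
            dy <- offs$dy[o]; dx <- offs$dx[o]
            w <- wk[dy + r + 1L, dx + r + 1L]
            sx <- .shiftM(a$x, dy, dx)
            sy <- .shiftM(a$y, dy, dx)
            sz <- .shiftM(a$z, dy, dx)
            mk <- .shiftM(ones, dy, dx)
            dt <- .clamp(sx * mx + sy * my + sz * mz)
            cc <- acos(dt)
            ux <- sx - dt * mx; uy <- sy - dt * my; uz <- sz - dt * mz
            un <- sqrt(ux^2 + uy^2 + uz^2)
            f <- ifelse(un < 1e-14, 0, cc / pmax(un, 1e-300)) * w * mk
            Tx <- Tx + f * ux; Ty <- Ty + f * uy; Tz <- Tz + f * uz
            Wa <- Wa + w * mk
        }
        Tx <- Tx / Wa; Ty <- Ty / Wa; Tz <- Tz / Wa
        stp <- sqrt(Tx^2 + Ty^2 + Tz^2)
        sfac <- ifelse(stp < 1e-300, 0, sin(stp) / pmax(stp, 1e-300))
        nx <- mx * cos(stp) + Tx * sfac
        ny <- my * cos(stp) + Ty * sfac
        nz <- mz * cos(stp) + Tz * sfac
        nrm <- sqrt(nx^2 + ny^2 + nz^2)
        mx <- nx / nrm; my <- ny / nrm; mz <- nz / nrm
        if (max(stp) < tol)
            return(normalMapFromComponents(mx, my, mz, renormalise = FALSE))
    }
    stop("geodesic smoothing did not converge in ", maxIter, " iterations")
}

# Chart of a whole map about a fixed reference normal mu, and back.
.mapToChart <- function(N, mu) {
    a <- .comps(normals(N))
    .logChartC(a$x, a$y, a$z, mu[1], mu[2], mu[3])
}

.chartToMap <- function(tx, ty, mu) {
    r <- .expChartC(tx, ty, mu[1], mu[2], mu[3])
    normalMapFromComponents(r$x, r$y, r$z, renormalise = TRUE)
}

#' Global geodesic mean of a normal map
#'
#' The Karcher mean of all pixels; used as the fixed chart point for
#' down- and up-sampling.
#'
#' @param N a \linkS4class{NormalMap}.
#' @return unit 3-vector.
#' @export
globalMean <- function(N) {
    a <- normals(N)
    geodesicMean(cbind(as.vector(a[, , 1]), as.vector(a[, , 2]),
                       as.vector(a[, , 3])))
}

#' Geodesic normal-map down-sampling
#'
#' Down-samples by an integer factor \code{S} with output size
#' (floor(H/S), floor(W/S)). All normals are unfolded into one fixed
#' tangent chart (at the global geodesic mean of the map), each output
#' pixel is the arithmetic mean of the chart coordinates over a
#' \code{u x v} window anchored at the corresponding input position
#' (rows \code{i*S - floor(u/2)} onward, truncated at the borders), and the
#' result is folded back with the exponential map.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param S integer scale factor >= 1.
#' @param window integer window size c(u, v); defaults to c(S, S).
#' @param mu fixed chart point; defaults to [globalMean()].
#' @return down-sampled \linkS4class{NormalMap}.
#' @export
downsampleNormalMap <- function(N, S, window = c(S, S), mu = NULL) {
    S <- as.integer(S)
    if (S < 1L) stop("S must be >= 1")
    u <- as.integer(window[1]); v <- as.integer(window[2])
    if (u < 1L || v < 1L) stop("window sizes must be >= 1")
    d <- dim(N)
    H2 <- d[1] %/% S; W2 <- d[2] %/% S
    if (H2 < 1L || W2 < 1L) stop("output dimension would be 0")
    if (S == 1L && u == 1L && v == 1L) return(N)
    if (is.null(mu)) mu <- globalMean(N)
    ch <- .mapToChart(N, mu)
    accx <- matrix(0, H2, W2); accy <- matrix(0, H2, W2)
    cnt <- matrix(0, H2, W2)
    r0 <- seq_len(H2) * S - u %/% 2L
    c0 <- seq_len(W2) * S - v %/% 2L
    for (k in seq_len(u)) {
        ri <- r0 + (k - 1L)
        okr <- ri >= 1L & ri <= d[1]
        for (l in seq_len(v)) {
            ci <- c0 + (l - 1L)
            okc <- ci >= 1L & ci <= d[2]
            if (!any(okr) || !any(okc)) next
            accx[okr, okc] <- accx[okr, okc] + ch$x[ri[okr], ci[okc]]
            accy[okr, okc] <- accy[okr, okc] + ch$y[ri[okr], ci[okc]]
            cnt[okr, okc] <- cnt[okr, okc] + 1
        }
    }
    .chartToMap(accx / cnt, accy / cnt, mu)
}

#' Geodesic normal-map up-sampling
#'
#' Bilinear interpolation performed in the fixed tangent chart at the global
#' geodesic mean (log, interpolate, exp), with align-centre grid mapping.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param S integer scale factor >= 1.
#' @param mu fixed chart point; defaults to [globalMean()].
#' @return up-sampled \linkS4class{NormalMap} of size (H*S, W*S).
#' @export
upsampleNormalMap <- function(N, S, mu = NULL) {
    S <- as.integer(S)
    if (S < 1L) stop("S must be >= 1")
    if (S == 1L) return(N)
    if (is.null(mu)) mu <- globalMean(N)
    ch <- .mapToChart(N, mu)
    d <- dim(N)
    ri <- (seq_len(d[1] * S) - 0.5) / S + 0.5
    ci <- (seq_len(d[2] * S) - 0.5) / S + 0.5
    grid <- expand.grid(r = ri, c = ci)
    tx <- matrix(.bilinear(ch$x, grid$r, grid$c), d[1] * S, d[2] * S)
    ty <- matrix(.bilinear(ch$y, grid$r, grid$c), d[1] * S, d[2] * S)
    .chartToMap(tx, ty, mu)
}

#' Classical per-channel resampling (comparison baseline)
#'
#' The naive route that treats the three normal components as independent
#' image channels: point decimation for down-sampling, bilinear
#' interpolation for up-sampling, renormalising to unit length afterwards.
#' Provided as the comparator for the geodesic resampling route.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param S integer scale factor >= 1.
#' @return resampled \linkS4class{NormalMap}.
#' @export
naiveDownsample <- function(N, S) {
    S <- as.integer(S)
    if (S == 1L) return(N)
    a <- normals(N)
    d <- dim(N)
    ri <- seq(1L, by = S, length.out = d[1] %/% S)
    ci <- seq(1L, by = S, length.out = d[2] %/% S)
    NormalMap(a[ri, ci, , drop = FALSE], renormalise = TRUE)
}

#' @rdname naiveDownsample
#' @export
naiveUpsample <- function(N, S) {
    S <- as.integer(S)
    if (S == 1L) return(N)
    a <- .comps(normals(N))
    d <- dim(N)
    ri <- (seq_len(d[1] * S) - 0.5) / S + 0.5
    ci <- (seq_len(d[2] * S) - 0.5) / S + 0.5
    grid <- expand.grid(r = ri, c = ci)
    f <- function(m) matrix(.bilinear(m, grid$r, grid$c), d[1] * S, d[2] * S)
    normalMapFromComponents(f(a$x), f(a$y), f(a$z), renormalise = TRUE)
}

#' Mean angular error between two normal maps
#'
#' Mean over pixels of acos of the clamped dot product, in radians.
#'
#' @param A,B \linkS4class{NormalMap}s of identical dimensions.
#' @return mean angular error in radians.
#' @export
meanAngularError <- function(A, B) {
    if (!all(dim(A) == dim(B))) stop("dimension mismatch")
    a <- normals(A); b <- normals(B)
    d <- .clamp(a[, , 1] * b[, , 1] + a[, , 2] * b[, , 2] +
                a[, , 3] * b[, , 3])
    mean(acos(d))
}
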