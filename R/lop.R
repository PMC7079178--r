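# Proposed method II: Local Orientation Patterns - a generalised
# texture-spectrum descriptor over normal orientations. Each pixel gets a
# texture-unit value encoding the comparison patterns between the central
# normal and N normals sampled on a circle of radius r, in base-n
# positional code; the descriptor is the image-wide histogram of the codes.

#' Configuration for Local Orientation Patterns
#'
#' @param nPoints number of circle sampling points N (>= 1).
#' @param radius circle radius in pixels (>= 1); off-grid points are
#'   sampled by bilinear interpolation in the fixed tangent chart.
#' @param patternFn 1 (thresholded dot product, 2 patterns) or
#'   2 (azimuth/polar comparison, 4 patterns).
#' @param threshold dot-product threshold in [-1, 1] for pattern function 1;
#'   NULL derives it from the map via \code{thresholdMode}.
#' @param thresholdMode "global" (mean dot product over all centre-neighbour
#'   pairs evaluated by the texture units) or "local_map" (per-pixel mean
#'   over the pixel's own texture unit).
#' @return a list of class \code{lopConfig}.
#' @export
lopConfig <- function(nPoints = 8L, radius = 1, patternFn = 1L,
                      threshold = NULL,
                      thresholdMode = c("global", "local_map")) {
    thresholdMode <- match.arg(thresholdMode)
    if (nPoints < 1L) stop("nPoints must be >= 1")
    if (!patternFn %in% c(1L, 2L)) stop("patternFn must be 1 or 2")
    if (!is.null(threshold) && (threshold < -1 || threshold > 1))
        stop("threshold must be in [-1, 1]")
    structure(list(nPoints = as.integer(nPoints), radius = radius,
                   patternFn = as.integer(patternFn), threshold = threshold,
                   thresholdMode = thresholdMode),
              class = "lopConfig")
}

#' LOP pattern functions
#'
#' \code{patternFn1} compares the dot product of two unit normals to a
#' threshold (1 iff \code{sum(n0 * ni) >= tau}). \code{patternFn2} compares
#' azimuth (atan2(ny, nx)) and polar angle (acos(nz)) directly, giving four
#' patterns; equal angles fall in the >= branches, so identical normals map
#' to pattern 3.
#'
#' @param n0,ni unit 3-vectors (centre and circle normal).
#' @param tau threshold in [-1, 1].
#' @return \code{patternFn1}: 0 or 1; \code{patternFn2}: 0, 1, 2 or 3.
#' @export
patternFn1 <- function(n0, ni, tau) {
    if (tau < -1 || tau > 1) stop("tau must be in [-1, 1]")
    as.integer(sum(n0 * ni) >= tau)
}

#' @rdname patternFn1
#' @export
patternFn2 <- function(n0, ni) {
    az0 <- atan2(n0[2], n0[1]); azi <- atan2(ni[2], ni[1])
    po0 <- acos(.clamp(n0[3])); poi <- acos(.clamp(ni[3]))
    2L * as.integer(az0 >= azi) + as.integer(po0 >= poi)
}

# Sample the normal components on the N circle points around every interior
# pixel. Integer offsets index directly; fractional offsets interpolate in
# the fixed tangent chart at the global mean. Returns the interior index
# ranges and per-point component matrices.
.lopSamples <- function(N, cfg) {
    d <- dim(N)
    R <- as.integer(ceiling(cfg$radius))
    if (d[1] < 2L * R + 1L || d[2] < 2L * R + 1L)
        stop("patch smaller than 2r + 1")
    rr <- (1L + R):(d[1] - R)
    cc <- (1L + R):(d[2] - R)
    a <- .comps(normals(N))
    nI <- length(rr); nJ <- length(cc)
    angles <- 2 * pi * (seq_len(cfg$nPoints) - 1L) / cfg$nPoints
    chart <- NULL; mu <- NULL
    pts <- vector("list", cfg$nPoints)
    for (i in seq_len(cfg$nPoints)) {
        dx <- cfg$radius * cos(angles[i])
        dy <- cfg$radius * sin(angles[i])
        if (abs(dx - round(dx)) < 1e-9 && abs(dy - round(dy)) < 1e-9) {
            ri <- rr + as.integer(round(dy))
            ci <- cc + as.integer(round(dx))
            pts[[i]] <- list(x = a$x[ri, ci, drop = FALSE],
                             y = a$y[ri, ci, drop = FALSE],
                             z = a$z[ri, ci, drop = FALSE])
        } else {
            if (is.null(chart)) {
                mu <- globalMean(N)
                chart <- .mapToChart(N, mu)
            }
            pr <- rep(rr + dy, times = nJ)
            pc <- rep(cc + dx, each = nI)
            tx <- matrix(.bilinear(chart$x, pr, pc), nI, nJ)
            ty <- matrix(.bilinear(chart$y, pr, pc), nI, nJ)
            e <- .expChartC(tx, ty, mu[1], mu[2], mu[3])
            nrm <- sqrt(e$x^2 + e$y^2 + e$z^2)
            pts[[i]] <- list(x = e$x / nrm, y = e$y / nrm, z = e$z / nrm)
        }
    }
    list(rr = rr, cc = cc,
         centre = list(x = a$x[rr, cc, drop = FALSE],
                       y = a$y[rr, cc, drop = FALSE],
                       z = a$z[rr, cc, drop = FALSE]),
         points = pts)
}

.lopDots <- function(s) {
    lapply(s$points, function(p)
        .clamp(s$centre$x * p$x + s$centre$y * p$y + s$centre$z * p$z))
}

#' Dot-product threshold for LOP pattern function 1
#'
#' In global mode, the mean of the dot products over all centre-neighbour
#' pairs that the map's texture units evaluate (one value per map). In
#' local mode, a per-pixel threshold map obtained by averaging the dot
#' products within each pixel's own texture unit.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param cfg an [lopConfig()].
#' @return scalar threshold (global) or matrix over interior pixels (local).
#' @export
globalThreshold <- function(N, cfg = lopConfig()) {
    s <- .lopSamples(N, cfg)
    dots <- .lopDots(s)
    if (cfg$thresholdMode == "global")
        return(mean(vapply(dots, mean, numeric(1))))
    Reduce(`+`, dots) / length(dots)
}

#' Local Orientation Pattern image
#'
#' Per-pixel texture-unit values f(p0) = sum_i f_i * n^(i-1) over the N
#' circle patterns, n = 2 for pattern function 1 and n = 4 for pattern
#' function 2. Border pixels with incomplete neighbourhoods are NA and
#' excluded from histograms. Values are bounded by n^N - 1.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param cfg an [lopConfig()].
#' @return numeric H x W matrix (NA borders) with the config in
#'   \code{attr(, "config")}.
#' @export
lopImage <- function(N, cfg = lopConfig()) {
    s <- .lopSamples(N, cfg)
    nBase <- if (cfg$patternFn == 1L) 2 else 4
    if (cfg$patternFn == 1L) {
        dots <- .lopDots(s)
        tau <- cfg$threshold
        if (is.null(tau)) {
            tau <- if (cfg$thresholdMode == "global")
                mean(vapply(dots, mean, numeric(1)))
            else Reduce(`+`, dots) / length(dots)
        }
        pats <- lapply(dots, function(dm) (dm >= tau) * 1)
    } else {
        az0 <- atan2(s$centre$y, s$centre$x)
        po0 <- acos(.clamp(s$centre$z))
        pats <- lapply(s$points, function(p) {
            azi <- atan2(p$y, p$x)
            poi <- acos(.clamp(p$z))
            2 * (az0 >= azi) + (po0 >= poi)
        })
    }
    val <- 0
    for (i in seq_along(pats)) val <- val + pats[[i]] * nBase^(i - 1)
    out <- matrix(NA_real_, dim(N)[1], dim(N)[2])
    out[s$rr, s$cc] <- val
    attr(out, "config") <- cfg
    out
}

#' Histogram of LOP texture-unit values
#'
#' Counts the frequency of every possible texture-unit value: length 2^N
#' for pattern function 1 (256 for the standard 8-point circle) and 4^N for
#' pattern function 2 (65536 for 8 points). Sums to the number of interior
#' pixels.
#'
#' @param L a matrix from [lopImage()].
#' @param cfg the [lopConfig()] used (defaults to the one attached to L).
#' @return named numeric vector of counts, bins 0 .. n^N - 1.
#' @export
lopHistogram <- function(L, cfg = attr(L, "config")) {
    if (is.null(cfg)) stop("cfg required (none attached to the image)")
    nBase <- if (cfg$patternFn == 1L) 2 else 4
    nBins <- nBase^cfg$nPoints
    v <- L[!is.na(L)]
    counts <- tabulate(as.integer(v) + 1L, nbins = nBins)
    names(counts) <- as.character(seq_len(nBins) - 1L)
    counts
}

#' LOP feature vector of a normal map
#'
#' Convenience composition of [lopImage()] and [lopHistogram()].
#'
#' @inheritParams lopImage
#' @return numeric feature vector with descriptor metadata attributes.
#' @export
lopDescriptor <- function(N, cfg = lopConfig()) {
    h <- lopHistogram(lopImage(N, cfg), cfg)
    attr(h, "descriptor") <- "lop"
    attr(h, "params") <- unclass(cfg)
    h
}
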