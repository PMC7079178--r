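# 2D texture baselines (Gabor bank, rotation-invariant LBP) on albedo
# images and their 3D extensions on slant-tilt and tangent maps, with the
# shared multi-scale response-normalisation scheme.

#' Min-max response normalisation
#'
#' Affine rescale of a filter-response image to [0, 1]; a constant image
#' maps to all zeros (numerically constant images, whose range is pure
#' floating-point noise relative to their magnitude, are treated the same
#' way). Idempotent.
#'
#' @param R numeric matrix.
#' @return matrix in [0, 1].
#' @export
normaliseResponse <- function(R) {
    rg <- range(R)
    if (diff(rg) <= 1e-12 * max(1, abs(rg[1]), abs(rg[2])))
        return(R * 0)
    (R - rg[1]) / diff(rg)
}

#' Gabor filter bank
#'
#' Complex Gabor kernels at \code{orientations} evenly spaced angles and
#' the given spatial frequencies (cycles/pixel). Bandwidth follows the
#' usual one-octave convention sigma = 0.56 / frequency, aspect ratio 0.5,
#' kernel truncated at 3 sigma. Responses are taken as the complex modulus.
#'
#' @param orientations number of filter orientations.
#' @param frequencies numeric vector of spatial frequencies (cycles/pixel).
#' @return list of kernels, each a list with \code{re} and \code{im}
#'   matrices.
#' @export
gaborBank <- function(orientations = 6L, frequencies = c(0.1, 0.25)) {
    out <- list()
    gamma <- 0.5
    for (f in frequencies) {
        sigma <- 0.56 / f
        hw <- max(3L, as.integer(ceiling(3 * sigma)))
        g <- expand.grid(x = -hw:hw, y = -hw:hw)
        for (o in seq_len(orientations)) {
            th <- pi * (o - 1) / orientations
            xp <- g$x * cos(th) + g$y * sin(th)
            yp <- -g$x * sin(th) + g$y * cos(th)
            env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
            re <- matrix(env * cos(2 * pi * f * xp), 2L * hw + 1L)
            im <- matrix(env * sin(2 * pi * f * xp), 2L * hw + 1L)
            re <- re - mean(re)  # zero-DC even part
            out[[length(out) + 1L]] <-
                list(re = re, im = im, frequency = f, theta = th)
        }
    }
    out
}

.gaborResponse <- function(img, kern) {
    sqrt(.filter2(img, kern$re, boundary = "replicate")^2 +
         .filter2(img, kern$im, boundary = "replicate")^2)
}

# Channel stacks per pyramid level for the three input spaces. Albedo
# levels are Gaussian-blurred and decimated; normal-derived levels use the
# geodesic (tangent-chart) down-sampling and recompute their channels.
.baselineChannels <- function(x, space, levels, window = 5L,
                              meanMethod = "euclidean") {
    out <- vector("list", levels)
    if (space == "albedo") {
        img <- x
        for (l in seq_len(levels)) {
            out[[l]] <- list(albedo = img)
            if (l < levels) {
                k <- .gauss1d(2L, sigma = 1)
                sm <- .sepConv2(img, k) /
                    .sepConv2(matrix(1, nrow(img), ncol(img)), k)
                img <- sm[seq(1L, nrow(sm), 2L), seq(1L, ncol(sm), 2L),
                          drop = FALSE]
            }
        }
        return(out)
    }
    N <- x
    for (l in seq_len(levels)) {
        out[[l]] <- if (space == "slantTilt") {
            st <- slantTilt(N)
            list(slant = st$slant, tilt = st$tilt)
        } else {
            tm <- tangentMap(N, window = window, method = meanMethod)
            list(tx = tm$x, ty = tm$y)
        }
        if (l < levels) N <- downsampleNormalMap(N, 2L, window = c(2L, 2L))
    }
    out
}

#' Multi-scale Gabor texture descriptor (2D and 3D variants)
#'
#' At each pyramid level every channel is filtered with the Gabor bank, the
#' responses are min-max normalised to [0, 1] and histogrammed, and the
#' histograms are concatenated; the next level works on a down-sampled
#' input (plain Gaussian pyramid for albedo, tangent-chart geodesic
#' down-sampling for the normal-derived spaces). Feature length is
#' levels * channels * filters * bins.
#'
#' @param x a matrix (albedo space) or \linkS4class{NormalMap} (slant-tilt
#'   and tangent spaces).
#' @param space "albedo", "slantTilt" or "tangent".
#' @param levels pyramid levels.
#' @param orientations,frequencies Gabor bank geometry.
#' @param bins histogram bins per response.
#' @param window local-mean window for the tangent space.
#' @return numeric feature vector with descriptor metadata attributes.
#' @export
gaborDescriptor <- function(x, space = c("albedo", "slantTilt", "tangent"),
                            levels = 3L, orientations = 6L,
                            frequencies = c(0.1, 0.25), bins = 32L,
                            window = 5L) {
    space <- match.arg(space)
    bank <- gaborBank(orientations, frequencies)
    chans <- .baselineChannels(x, space, levels, window = window)
    breaks <- seq(0, 1, length.out = bins + 1L)
    feats <- list()
    for (l in seq_len(levels)) for (ch in chans[[l]]) for (kern in bank) {
        rn <- normaliseResponse(.gaborResponse(ch, kern))
        feats[[length(feats) + 1L]] <- .histCounts(as.vector(rn), breaks)
    }
    v <- unlist(feats)
    attr(v, "descriptor") <- paste0("gabor_", space)
    attr(v, "params") <- list(levels = levels, orientations = orientations,
                              frequencies = frequencies, bins = bins)
    v
}

# Rotation-invariant LBP code table: each 8-bit code maps to the minimum
# value over its cyclic bit rotations; labels are re-indexed 1..nCodes.
.riTable <- function(nPoints = 8L) {
    codes <- 0:(2^nPoints - 1L)
    bits <- sapply(codes, function(cd)
        as.integer(intToBits(cd))[seq_len(nPoints)])
    minrot <- apply(bits, 2, function(b) {
        min(vapply(seq_len(nPoints), function(s) {
            rb <- c(b[s:nPoints], b[seq_len(s - 1L)])[seq_len(nPoints)]
            sum(rb * 2^(seq_len(nPoints) - 1L))
        }, numeric(1)))
    })
    lv <- sort(unique(minrot))
    list(label = match(minrot, lv), nCodes = length(lv))
}

#' Rotation-invariant LBP label image
#'
#' Classical circular local binary patterns on a scalar image (N points,
#' radius r, bilinear sampling off grid, >= comparison with the centre),
#' reduced to rotation-invariant codes by taking the minimum over cyclic
#' rotations. Border pixels are NA.
#'
#' @param img numeric matrix.
#' @param radius circle radius in pixels.
#' @param nPoints number of circle points.
#' @return list with \code{labels} (matrix of 1-based ri labels, NA at
#'   borders) and \code{nCodes}.
#' @export
rlbpImage <- function(img, radius = 1, nPoints = 8L) {
    H <- nrow(img); W <- ncol(img)
    R <- as.integer(ceiling(radius))
    if (H < 2L * R + 1L || W < 2L * R + 1L) stop("image smaller than 2r + 1")
    rr <- (1L + R):(H - R); cc <- (1L + R):(W - R)
    nI <- length(rr); nJ <- length(cc)
    ctr <- img[rr, cc, drop = FALSE]
    code <- matrix(0, nI, nJ)
    for (i in seq_len(nPoints)) {
        ang <- 2 * pi * (i - 1L) / nPoints
        dx <- radius * cos(ang); dy <- radius * sin(ang)
        if (abs(dx - round(dx)) < 1e-9 && abs(dy - round(dy)) < 1e-9) {
            nb <- img[rr + as.integer(round(dy)), cc + as.integer(round(dx)),
                      drop = FALSE]
        } else {
            pr <- rep(rr + dy, times = nJ)
            pc <- rep(cc + dx, each = nI)
            nb <- matrix(.bilinear(img, pr, pc), nI, nJ)
        }
        code <- code + (nb >= ctr) * 2^(i - 1L)
    }
    tab <- .riTable(nPoints)
    lab <- matrix(NA_real_, H, W)
    lab[rr, cc] <- tab$label[code + 1L]
    list(labels = lab, nCodes = tab$nCodes)
}

#' Multi-scale rotation-invariant LBP descriptor (2D and 3D variants)
#'
#' Same multi-scale scheme as [gaborDescriptor()] with histograms of
#' rotation-invariant LBP labels per channel per level. Feature length is
#' levels * channels * nCodes (36 codes for 8 points).
#'
#' @inheritParams gaborDescriptor
#' @param radius LBP circle radius in pixels.
#' @param nPoints LBP circle points.
#' @return numeric feature vector with descriptor metadata attributes.
#' @export
rlbpDescriptor <- function(x, space = c("albedo", "slantTilt", "tangent"),
                           levels = 3L, radius = 1, nPoints = 8L,
                           window = 5L) {
    space <- match.arg(space)
    chans <- .baselineChannels(x, space, levels, window = window)
    feats <- list()
    for (l in seq_len(levels)) for (ch in chans[[l]]) {
        lb <- rlbpImage(ch, radius = radius, nPoints = nPoints)
        v <- lb$labels[!is.na(lb$labels)]
        feats[[length(feats) + 1L]] <- tabulate(v, nbins = lb$nCodes)
    }
    v <- unlist(feats)
    attr(v, "descriptor") <- paste0("rlbp_", space)
    attr(v, "params") <- list(levels = levels, radius = radius,
                              nPoints = nPoints)
    v
}
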