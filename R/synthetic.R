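# Synthetic skin-patch generator: height-field based skin micro-geometry
# with graded wrinkle / pore / acne severity, exported as unit normal
# fields (z > 0 by construction), plus Lambertian relighting for the BTF
# baseline. Stands in for light-stage captures: the height-field model
# gives exactly integrable normal fields with condition structures whose
# amplitude and density scale monotonically with severity (severity 1 is
# clear skin).

.smoothNoise <- function(H, W, sigma) {
    b <- matrix(stats::rnorm(H * W), H, W)
    k <- .gauss1d(max(1L, as.integer(ceiling(2 * sigma))), sigma = sigma)
    sm <- .sepConv2(b, k) / .sepConv2(matrix(1, H, W), k)
    if (stats::sd(sm) < 1e-12) return(sm * 0)
    (sm - mean(sm)) / stats::sd(sm)
}

.addBlob <- function(h, cy, cx, sigma, amp) {
    H <- nrow(h); W <- ncol(h)
    R <- ceiling(3 * sigma)
    rr <- max(1, floor(cy - R)):min(H, ceiling(cy + R))
    cc <- max(1, floor(cx - R)):min(W, ceiling(cx + R))
    d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
    h[rr, cc] <- h[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
    h
}

#' Generate a synthetic skin patch
#'
#' Height field = smooth low-frequency base surface + condition structures
#' + pixel noise; normals are the normalised (-dh/dx, -dh/dy, 1) of the
#' height field (heights in pixel units). Condition structures:
#' \describe{
#'   \item{wrinkles}{oriented quasi-parallel valleys (wavelength
#'     \code{wrinkleWavelength}, Gaussian cross-profile, smooth orientation
#'     jitter).}
#'   \item{pores}{dense small Gaussian pits (radius ~1.2 px).}
#'   \item{acne}{sparse large Gaussian bumps (radius ~4 px) with slight
#'     albedo darkening.}
#'   \item{smooth}{base surface only.}
#' }
#' Severity s in 1..5 scales structure amplitude and density linearly via
#' (s - 1)/4, so severity 1 is clear skin for every condition. A fixed
#' (spec, seed) pair is bit-reproducible.
#'
#' @param condition "wrinkles", "pores", "acne" or "smooth".
#' @param severity integer 1..5.
#' @param size patch side in pixels (typical sampling grids: 20, 50, 80).
#' @param seed integer seed.
#' @param baseAmp base-surface amplitude (height sd, px).
#' @param noiseAmp per-pixel height noise sd (px).
#' @param wrinkleWavelength,wrinkleWidth,wrinkleDepth wrinkle geometry (px).
#' @param poreDensity,poreSigma,poreDepth pore geometry (count/px^2, px, px).
#' @param acneDensity,acneSigma,acneHeight acne geometry (count/px^2, px, px).
#' @return a \linkS4class{LabeledPatch}.
#' @export
makePatch <- function(condition = c("wrinkles", "pores", "acne", "smooth"),
                      severity = 3L, size = 50L, seed = 1L,
                      baseAmp = 2, noiseAmp = 0.02,
                      wrinkleWavelength = 12, wrinkleWidth = 2.5,
                      wrinkleDepth = 2, poreDensity = 0.05,
                      poreSigma = 1.2, poreDepth = 0.9,
                      acneDensity = 0.004, acneSigma = 4, acneHeight = 2.5) {
    condition <- match.arg(condition)
    severity <- as.integer(severity)
    if (severity < 1L || severity > 5L) stop("severity must be in 1..5")
    size <- as.integer(size)
    if (size < 8L) stop("size must be >= 8")
    set.seed(.subSeed(seed, 101L))
    s <- (severity - 1) / 4
    h <- baseAmp * .smoothNoise(size, size, sigma = size / 8)
    albedo <- 0.65 + 0.08 * .smoothNoise(size, size, sigma = size / 6)
    if (condition == "wrinkles" && s > 0) {
        alpha <- stats::runif(1, 0, pi)
        jit <- 0.35 * .smoothNoise(size, size, sigma = size / 6)
        xy <- expand.grid(y = seq_len(size), x = seq_len(size))
        t <- matrix((xy$x * cos(alpha) + xy$y * sin(alpha)) /
                        wrinkleWavelength, size, size) + jit
        frac <- t - round(t)
        valley <- exp(-(frac * wrinkleWavelength / wrinkleWidth)^2 / 2)
        h <- h - s * wrinkleDepth * valley
    } else if (condition == "pores" && s > 0) {
        nP <- round(s * poreDensity * size^2)
        for (i in seq_len(nP)) {
            cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
            dep <- s * poreDepth * stats::runif(1, 0.7, 1.3)
            h <- .addBlob(h, cy, cx, poreSigma, -dep)
            albedo <- .addBlob(albedo, cy, cx, poreSigma, -0.04)
        }
    } else if (condition == "acne" && s > 0) {
        nA <- max(1L, round(s * acneDensity * size^2))
        for (i in seq_len(nA)) {
            cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
            amp <- s * acneHeight * stats::runif(1, 0.7, 1.3)
            sg <- acneSigma * stats::runif(1, 0.8, 1.2)
            h <- .addBlob(h, cy, cx, sg, amp)
            albedo <- .addBlob(albedo, cy, cx, 1.5 * sg, -0.12 * s)
        }
    }
    if (noiseAmp > 0)
        h <- h + noiseAmp * matrix(stats::rnorm(size^2), size, size)
    albedo <- .clamp(albedo, 0.05, 1)
    new("LabeledPatch", normal = normalMapFromHeight(h), albedo = albedo,
        height = h, condition = condition, severity = severity,
        ratings = numeric(0))
}

.affineWarp <- function(img, rotation = 0, scale = 1, dx = 0, dy = 0) {
    H <- nrow(img); W <- ncol(img)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    g <- expand.grid(r = seq_len(H), c = seq_len(W))
    th <- rotation * pi / 180
    # inverse map: output -> input
    yr <- (g$r - cy - dy) / scale
    xr <- (g$c - cx - dx) / scale
    ri <- cy + (cos(th) * yr - sin(th) * xr)
    ci <- cx + (sin(th) * yr + cos(th) * xr)
    matrix(.bilinear(img, ri, ci), H, W)
}

#' Lambertian rendering of a patch
#'
#' Shading at each pixel is albedo * max(0, n . light); an optional small
#' in-plane re-projection (rotation/scale/shift) stands in for a viewpoint
#' change.
#'
#' @param patch a \linkS4class{LabeledPatch}.
#' @param light unit 3-vector with positive z.
#' @param view NULL or list with any of \code{rotation} (degrees),
#'   \code{scale}, \code{dx}, \code{dy}.
#' @return numeric matrix (greyscale image).
#' @export
renderPatch <- function(patch, light = c(0, 0, 1), view = NULL) {
    light <- light / sqrt(sum(light^2))
    if (light[3] <= 0) stop("light must have positive z")
    a <- normals(patchNormalMap(patch))
    sh <- pmax(0, a[, , 1] * light[1] + a[, , 2] * light[2] +
                  a[, , 3] * light[3])
    img <- patchAlbedo(patch) * sh
    if (!is.null(view)) {
        v <- utils::modifyList(list(rotation = 0, scale = 1, dx = 0, dy = 0),
                               view)
        img <- .affineWarp(img, v$rotation, v$scale, v$dx, v$dy)
    }
    img
}

#' Render a BTF stack for a patch
#'
#' Views are small in-plane re-projections (identity plus small rotations);
#' lights are one overhead direction plus \code{lights - 1} azimuths at 45
#' degree elevation.
#'
#' @param patch a \linkS4class{LabeledPatch}.
#' @param views number of viewpoints (>= 1).
#' @param lights number of light directions (>= 1).
#' @param azimuth0 azimuthal offset of the light ring (radians), for
#'   re-lighting the same geometry under rotated illumination.
#' @return a [btfStack()] with \code{views * lights} images.
#' @export
makeBTFStack <- function(patch, views = 2L, lights = 7L, azimuth0 = 0) {
    rots <- c(0, 4, -4, 8, -8, 12, -12)
    if (views > length(rots)) stop("at most ", length(rots), " views")
    viewDefs <- lapply(rots[seq_len(views)], function(r) list(rotation = r))
    ld <- list(c(0, 0, 1))
    if (lights > 1L) {
        az <- azimuth0 + 2 * pi * (seq_len(lights - 1L) - 1L) / (lights - 1L)
        e <- pi / 4
        ld <- c(ld, lapply(az, function(a)
            c(cos(e) * cos(a), cos(e) * sin(a), sin(e))))
    }
    imgs <- list()
    for (v in seq_len(views)) for (l in seq_len(lights)) {
        imgs[[length(imgs) + 1L]] <-
            renderPatch(patch, light = ld[[l]], view = viewDefs[[v]])
    }
    btfStack(imgs, views = views, lights = lights)
}

#' Generate a labelled synthetic corpus with simulated raters
#'
#' A balanced corpus of \code{nPerClass} patches per (condition, severity)
#' cell plus a simulated multi-rater score table: faithful raters score
#' clamp(round(severity + bias + N(0, raterSigma)), 1, 5) with a per-rater
#' bias drawn from N(0, raterBiasSd); adversarial raters score uniformly at
#' random (material for the rater-exclusion procedure).
#'
#' @param nPerClass patches per condition x severity cell.
#' @param conditions character vector of conditions.
#' @param severities integer severities to include.
#' @param size patch side in pixels.
#' @param seed integer seed.
#' @param nRaters number of faithful raters.
#' @param nAdversarial number of adversarial (uniform random) raters.
#' @param raterSigma faithful rater score noise sd; the default 1.0
#'   yields faithful pairwise Spearman correlations around 0.6, the
#'   agreement level typical of subjective skin-severity ratings.
#' @param raterBiasSd sd of per-rater additive bias.
#' @param ... further geometry parameters passed to [makePatch()].
#' @return list with \code{patches} (list of \linkS4class{LabeledPatch}),
#'   \code{labels} (data.frame: condition, severity) and \code{ratings}
#'   (patches x raters matrix; adversarial raters are the last columns,
#'   flagged in \code{attr(, "adversarial")}).
#' @export
makeDataset <- function(nPerClass = 2L,
                        conditions = c("wrinkles", "pores", "acne"),
                        severities = 1:5, size = 50L, seed = 1L,
                        nRaters = 5L, nAdversarial = 1L,
                        raterSigma = 1.0, raterBiasSd = 0.3, ...) {
    if (nPerClass < 1L) stop("nPerClass must be >= 1")
    grid <- expand.grid(rep = seq_len(nPerClass), severity = severities,
                        condition = conditions,
                        stringsAsFactors = FALSE)
    patches <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        patches[[i]] <- makePatch(condition = grid$condition[i],
                                  severity = grid$severity[i], size = size,
                                  seed = .subSeed(seed, 1000L + i), ...)
    }
    set.seed(.subSeed(seed, 77L))
    nP <- nrow(grid)
    bias <- stats::rnorm(nRaters, 0, raterBiasSd)
    ratings <- matrix(0L, nP, nRaters + nAdversarial)
    for (r in seq_len(nRaters)) {
        ratings[, r] <- pmin(pmax(round(grid$severity + bias[r] +
                                        stats::rnorm(nP, 0, raterSigma)),
                                  1), 5)
    }
    for (r in seq_len(nAdversarial)) {
        ratings[, nRaters + r] <- sample(1:5, nP, replace = TRUE)
    }
    colnames(ratings) <- c(paste0("rater", seq_len(nRaters)),
                           if (nAdversarial > 0)
                               paste0("adv", seq_len(nAdversarial)))
    attr(ratings, "adversarial") <-
        if (nAdversarial > 0) nRaters + seq_len(nAdversarial) else integer(0)
    list(patches = patches,
         labels = data.frame(condition = grid$condition,
                             severity = grid$severity),
         ratings = ratings)
}

#' Write a labelled patch to disk
#'
#' Normal map and albedo as paired PNGs plus a small JSON-free text sidecar
#' with condition, severity and ratings.
#'
#' @param patch a \linkS4class{LabeledPatch}.
#' @param prefix file path prefix.
#' @return invisible vector of written paths.
#' @export
writePatch <- function(patch, prefix) {
    pn <- paste0(prefix, "_normal.png")
    pa <- paste0(prefix, "_albedo.png")
    pm <- paste0(prefix, "_meta.txt")
    writeNormalMap(patchNormalMap(patch), pn)
    png::writePNG(.clamp(patchAlbedo(patch), 0, 1), pa)
    writeLines(c(paste("condition", patchCondition(patch)),
                 paste("severity", patchSeverity(patch)),
                 paste("ratings", paste(patchRatings(patch),
                                        collapse = " "))), pm)
    invisible(c(pn, pa, pm))
}
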