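# Proposed method I: multi-resolution rotation-field pyramid with SO(3)
# neighbourhood distance vectors quantised into k-means texton histograms.

#' Rotation field of a normal map
#'
#' Smooths the map with radius \code{r} and stores, at every pixel, the
#' axis-angle rotation carrying the original normal onto the smoothed one.
#' The field is the high-frequency residual of the surface: small radii
#' respond to pore-scale relief, large radii to wrinkles and acne.
#' Coincident normals get the canonical axis (0, 0, 1) with angle 0.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param r smoothing radius in pixels (>= 1).
#' @param method "geodesic" or "euclidean" smoothing mean.
#' @return a \linkS4class{RotationField}.
#' @export
rotationField <- function(N, r, method = c("geodesic", "euclidean")) {
    method <- match.arg(method)
    Ns <- smoothNormalMap(N, r, method = method)
    a <- .comps(normals(N)); b <- .comps(normals(Ns))
    cx <- a$y * b$z - a$z * b$y
    cy <- a$z * b$x - a$x * b$z
    cz <- a$x * b$y - a$y * b$x
    cn <- sqrt(cx^2 + cy^2 + cz^2)
    dt <- .clamp(a$x * b$x + a$y * b$y + a$z * b$z)
    ang <- acos(dt)
    deg <- cn < 1e-12
    ax <- ifelse(deg, 0, cx / pmax(cn, 1e-300))
    ay <- ifelse(deg, 0, cy / pmax(cn, 1e-300))
    az <- ifelse(deg, 1, cz / pmax(cn, 1e-300))
    ang[deg] <- 0
    new("RotationField", axis = .bind3(ax, ay, az), angle = ang,
        radius = as.numeric(r))
}

#' Rotation-fields pyramid
#'
#' At each level the low-frequency map (Gaussian geodesic/Euclidean
#' smoothing, radius \code{r}) is separated from the high-frequency
#' rotation field that carries it back to the level's input; the
#' low-frequency map is then down-sampled by a factor of 2 (geodesic
#' Algorithm-1 resampling, 2 x 2 window) and passed to the next level.
#' The three components of the rotation vector act as the level's
#' sub-bands.
#'
#' @param N a \linkS4class{NormalMap}; dims must be >= 2^(levels - 1).
#' @param levels number of pyramid levels (>= 1).
#' @param r smoothing radius in pixels, shared by all levels.
#' @param method smoothing mean, "geodesic" or "euclidean".
#' @return a \linkS4class{RotationPyramid}.
#' @export
rotationPyramid <- function(N, levels = 3L, r = 3L,
                            method = c("geodesic", "euclidean")) {
    method <- match.arg(method)
    levels <- as.integer(levels)
    if (levels < 1L) stop("levels must be >= 1")
    if (any(dim(N) < 2^(levels - 1L))) stop("map too small for ", levels,
                                            " levels")
    fields <- vector("list", levels)
    lows <- vector("list", levels)
    cur <- N
    for (l in seq_len(levels)) {
        fields[[l]] <- rotationField(cur, r, method = method)
        lows[[l]] <- smoothNormalMap(cur, r, method = method)
        if (l < levels)
            cur <- downsampleNormalMap(lows[[l]], 2L, window = c(2L, 2L))
    }
    new("RotationPyramid", fields = fields, lows = lows,
        radius = as.numeric(r))
}

#' Per-pixel SO(3) neighbourhood distance vectors
#'
#' For every interior pixel of a rotation field, the parallel-axis SO(3)
#' distances from the central rotation to each of the other rotations in an
#' N x M window (N*M - 1 values), concatenated with the central rotation
#' vector (axis times angle, 3 components), giving vectors of length
#' N*M + 2. Border pixels whose window leaves the field are excluded.
#'
#' @param F a \linkS4class{RotationField}.
#' @param window odd window dimensions c(N, M).
#' @return matrix with one row per interior pixel and N*M + 2 columns.
#' @export
neighbourhoodVectors <- function(F, window = c(3L, 3L)) {
    wN <- as.integer(window[1]); wM <- as.integer(window[2])
    if (wN %% 2L == 0L || wM %% 2L == 0L) stop("window must be odd")
    d <- dim(F)
    if (wN > d[1] || wM > d[2]) stop("window larger than field")
    ry <- wN %/% 2L; rx <- wM %/% 2L
    rr <- (1L + ry):(d[1] - ry)
    cc <- (1L + rx):(d[2] - rx)
    th <- rotationAngles(F)
    ax <- rotationAxes(F)
    ctr <- th[rr, cc, drop = FALSE]
    cols <- vector("list", wN * wM - 1L)
    i <- 0L
    for (dy in -ry:ry) for (dx in -rx:rx) {
        if (dy == 0L && dx == 0L) next
        i <- i + 1L
        nb <- th[rr + dy, cc + dx, drop = FALSE]
        cols[[i]] <- as.vector(.so3DistPar(ctr, nb))
    }
    rv <- cbind(as.vector(ax[rr, cc, 1] * ctr),
                as.vector(ax[rr, cc, 2] * ctr),
                as.vector(ax[rr, cc, 3] * ctr))
    out <- cbind(do.call(cbind, cols), rv)
    colnames(out) <- c(paste0("d", seq_len(wN * wM - 1L)),
                       "rx", "ry", "rz")
    out
}

#' Fit a k-means dictionary over descriptor vectors
#'
#' Plain \code{stats::kmeans} with multiple random restarts under a fixed
#' seed. When more centres than distinct vectors (or than \code{maxFit}
#' subsampled rows) are requested, the effective k is reduced; histograms
#' built from the dictionary are zero-padded back to the requested length.
#'
#' @param vectors numeric matrix, rows are observations.
#' @param k requested number of clusters.
#' @param seed integer seed for restarts and subsampling.
#' @param nstart number of random restarts.
#' @param maxFit subsample cap for the fitting set.
#' @return matrix of cluster centres (kEff x ncol).
#' @export
fitDictionary <- function(vectors, k, seed = 1L, nstart = 10L,
                          maxFit = 20000L) {
    if (nrow(vectors) < 1L) stop("no vectors to fit")
    set.seed(.subSeed(seed, 11L))
    fit <- vectors
    if (nrow(fit) > maxFit)
        fit <- fit[sample.int(nrow(fit), maxFit), , drop = FALSE]
    nDistinct <- nrow(unique(fit))
    kEff <- min(as.integer(k), nDistinct)
    if (kEff < 1L) stop("fewer vectors than clusters")
    if (kEff == nDistinct) {
        ctr <- unique(fit)
    } else {
        ctr <- stats::kmeans(fit, centers = kEff, nstart = nstart,
                             iter.max = 50L)$centers
    }
    attr(ctr, "k_requested") <- as.integer(k)
    ctr
}

#' @rdname fitDictionary
#' @param centers a dictionary from \code{fitDictionary}.
#' @return \code{assignDictionary}: integer labels (nearest centre).
#' @export
assignDictionary <- function(vectors, centers) {
    cn <- rowSums(centers^2)
    d2 <- outer(rowSums(vectors^2), cn, "+") -
        2 * vectors %*% t(centers)
    max.col(-d2, ties.method = "first")
}

#' Quantise descriptor vectors into a label histogram
#'
#' Maps each vector to its nearest dictionary centre and counts label
#' frequencies. The histogram has the requested dictionary length (zero
#' padded if the dictionary was rank-reduced) and sums to the number of
#' vectors.
#'
#' @param vectors numeric matrix, rows are observations.
#' @param k number of clusters (ignored when \code{centers} is given).
#' @param centers optional pre-fitted dictionary (training-fold fit).
#' @param seed integer seed for the self-fit case.
#' @return list with \code{counts} (length-k histogram), \code{centers}
#'   and \code{labels}.
#' @export
quantiseHistogram <- function(vectors, k = 100L, centers = NULL, seed = 1L) {
    if (is.null(centers)) centers <- fitDictionary(vectors, k, seed = seed)
    kReq <- attr(centers, "k_requested")
    if (is.null(kReq)) kReq <- nrow(centers)
    labels <- assignDictionary(vectors, centers)
    counts <- tabulate(labels, nbins = kReq)
    list(counts = counts, centers = centers, labels = labels)
}

#' Rotation-fields descriptor
#'
#' The concatenation over pyramid levels of k-means label histograms of the
#' SO(3) neighbourhood distance vectors: length levels * k (e.g. 300 for a
#' 3-level pyramid with k = 100, 600 with k = 200). Each level's histogram
#' sums to the number of interior pixels at that level.
#'
#' @param N a \linkS4class{NormalMap}.
#' @param levels pyramid levels.
#' @param k clusters per level.
#' @param r smoothing radius in pixels.
#' @param window neighbourhood window c(N, M), odd.
#' @param seed integer seed for dictionary fitting.
#' @param dictionaries optional list of per-level centre matrices fitted on
#'   a training corpus; when NULL each level self-fits its dictionary.
#' @param method smoothing mean passed to the pyramid.
#' @return numeric feature vector of length levels * k, with parameter
#'   metadata in attributes.
#' @export
rfDescriptor <- function(N, levels = 3L, k = 100L, r = 3L,
                         window = c(3L, 3L), seed = 1L,
                         dictionaries = NULL,
                         method = c("geodesic", "euclidean")) {
    method <- match.arg(method)
    pyr <- rotationPyramid(N, levels = levels, r = r, method = method)
    vecs <- lapply(pyr@fields, neighbourhoodVectors, window = window)
    out <- vector("list", levels)
    for (l in seq_len(as.integer(levels))) {
        ctr <- if (is.null(dictionaries)) NULL else dictionaries[[l]]
        q <- quantiseHistogram(vecs[[l]], k = k, centers = ctr,
                               seed = .subSeed(seed, l))
        out[[l]] <- q$counts
    }
    v <- unlist(out)
    attr(v, "descriptor") <- "rotation_fields"
    attr(v, "params") <- list(levels = levels, k = k, r = r,
                              window = window, seed = seed)
    v
}

#' Encode a rotation field as an RGB array
#'
#' The three components of the rotation vector (axis times angle) are
#' affinely mapped into [0, 1] for visual inspection of the sub-bands.
#'
#' @param F a \linkS4class{RotationField}.
#' @param maxAngle angle mapped to full scale (radians).
#' @return H x W x 3 array in [0, 1], writable with \code{png::writePNG}.
#' @export
rotationFieldToRGB <- function(F, maxAngle = max(rotationAngles(F), 1e-6)) {
    rv <- rotationAxes(F) * as.vector(rotationAngles(F))
    .clamp(rv / maxAngle, -1, 1) / 2 + 0.5
}
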