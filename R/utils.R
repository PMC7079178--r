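# Internal numeric helpers shared across modules.

.clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# Split an H x W x 3 array into component matrices (dims preserved even for
# single-row/column maps) and back.
.comps <- function(a) {
    d <- dim(a)
    list(x = matrix(a[, , 1], d[1], d[2]),
         y = matrix(a[, , 2], d[1], d[2]),
         z = matrix(a[, , 3], d[1], d[2]))
}

.bind3 <- function(x, y, z) {
    a <- array(0, c(dim(x), 3L))
    a[, , 1] <- x; a[, , 2] <- y; a[, , 3] <- z
    a
}

.renorm3 <- function(a) {
    d <- dim(a)
    m <- matrix(a, ncol = 3)
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("cannot renormalise a zero vector")
    array(m / nrm, d)
}

# Truncated Gaussian kernel on [-r, r] with sigma = r/2 (the smoothing
# convention used throughout), renormalised to sum 1.
.gauss1d <- function(r, sigma = r / 2) {
    if (sigma <= 0) return(1)
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k / sum(k)
}

# Separable 2D weighted sum with zero padding outside the image; callers
# divide by .sepConv2(ones) to get truncate-and-renormalise border handling.
# Implemented with banded matrix products (images here are small).
.convMat <- function(n, k) {
    r <- (length(k) - 1L) %/% 2L
    A <- matrix(0, n, n)
    for (o in -r:r) {
        i <- seq_len(n)
        j <- i + o
        ok <- j >= 1L & j <= n
        A[cbind(i[ok], j[ok])] <- k[o + r + 1L]
    }
    A
}

.sepConv2 <- function(m, k) {
    if (length(k) == 1L) return(m * k)
    A <- .convMat(nrow(m), k)
    B <- .convMat(ncol(m), k)
    A %*% m %*% t(B)
}

# Full (non-separable) 2D correlation via EBImage; zero boundary so border
# windows can be renormalised by the mask image. Images smaller than the
# kernel are edge-padded first (EBImage requires dim(x) >= dim(w)).
.filter2 <- function(m, kern, boundary = 0) {
    pr <- max(0L, nrow(kern) - nrow(m))
    pc <- max(0L, ncol(kern) - ncol(m))
    if (pr == 0L && pc == 0L)
        return(EBImage::filter2(m, kern, boundary = boundary))
    ri <- .clamp(seq_len(nrow(m) + 2L * pr) - pr, 1L, nrow(m))
    ci <- .clamp(seq_len(ncol(m) + 2L * pc) - pc, 1L, ncol(m))
    big <- EBImage::filter2(m[ri, ci, drop = FALSE], kern,
                            boundary = boundary)
    big[pr + seq_len(nrow(m)), pc + seq_len(ncol(m)), drop = FALSE]
}

# Bilinear sampling of a matrix at fractional (row, col) positions.
# Positions are clamped to the valid grid.
.bilinear <- function(m, ri, ci) {
    H <- nrow(m); W <- ncol(m)
    ri <- .clamp(ri, 1, H)
    ci <- .clamp(ci, 1, W)
    r0 <- pmin(floor(ri), H - 1L); r0 <- pmax(r0, 1L)
    c0 <- pmin(floor(ci), W - 1L); c0 <- pmax(c0, 1L)
    fr <- ri - r0
    fc <- ci - c0
    i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1L)
    i10 <- cbind(r0 + 1L, c0); i11 <- cbind(r0 + 1L, c0 + 1L)
    m[i00] * (1 - fr) * (1 - fc) + m[i01] * (1 - fr) * fc +
        m[i10] * fr * (1 - fc) + m[i11] * fr * fc
}

# Spherical coordinates used throughout: elevation theta = pi/2 - slant
# (latitude, pi/2 at the +z pole) and azimuth phi = atan2(ny, nx).
.sphTheta <- function(nz) asin(.clamp(nz))
.sphPhi <- function(nx, ny) atan2(ny, nx)

# Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, k) (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L

.histCounts <- function(x, breaks) {
    # hist() with right-closed last bin; values exactly at the top edge are
    # included. x must already lie within [breaks[1], breaks[length(breaks)]].
    bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(bin, nbins = length(breaks) - 1L)
}
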