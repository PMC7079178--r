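# Riemannian primitives on the unit sphere S^2 (surface normals) and on the
# rotation group SO(3), used by every descriptor in the package.
#
# The spherical chart is the azimuthal-equidistant projection about a
# reference normal mu: radial distances from the origin of the chart equal
# geodesic (great-circle) angles on the sphere. Coordinates follow the
# elevation/azimuth convention theta = pi/2 - slant, phi = atan2(ny, nx).

.checkUnit <- function(n, what = "normal", tol = 1e-6) {
    if (length(n) != 3L || any(!is.finite(n)))
        stop(what, " must be a finite 3-vector")
    if (abs(sqrt(sum(n^2)) - 1) > tol)
        stop(what, " must be unit length")
    invisible(n)
}

# Vectorised chart: component matrices/vectors in, chart coordinates out.
# k = c / sin c with the c -> 0 limit k = 1.
.logChartC <- function(nx, ny, nz, mx, my, mz) {
    t1 <- .sphTheta(nz); p1 <- .sphPhi(nx, ny)
    t0 <- .sphTheta(mz); p0 <- .sphPhi(mx, my)
    dp <- p1 - p0
    cosc <- .clamp(sin(t0) * sin(t1) + cos(t0) * cos(t1) * cos(dp))
    cc <- acos(cosc)
    sc <- sin(cc)
    k <- ifelse(sc < 1e-12, 1, cc / pmax(sc, 1e-300))
    list(x = k * cos(t1) * sin(dp),
         y = k * (cos(t0) * sin(t1) - sin(t0) * cos(t1) * cos(dp)),
         c = cc)
}

.expChartC <- function(tx, ty, mx, my, mz) {
    t0 <- .sphTheta(mz); p0 <- .sphPhi(mx, my)
    cc <- sqrt(tx^2 + ty^2)
    sc <- sin(cc)
    cosc <- cos(cc)
    safe <- pmax(cc, 1e-300)
    theta <- asin(.clamp(cosc * sin(t0) + ty * sc * cos(t0) / safe))
    phi <- p0 + atan2(tx * sc, cc * cos(t0) * cosc - ty * sin(t0) * sc)
    zero <- cc < 1e-14
    nx <- ifelse(zero, mx, cos(theta) * cos(phi))
    ny <- ifelse(zero, my, cos(theta) * sin(phi))
    nz <- ifelse(zero, mz, sin(theta))
    list(x = nx, y = ny, z = nz)
}

# Basis-free 3D tangent log/exp (used by iterative means; equivalent to the
# chart up to the choice of tangent basis).
.log3 <- function(N, mu) {
    # N: n x 3 matrix, mu: length-3; returns n x 3 tangent vectors at mu
    d <- .clamp(as.vector(N %*% mu))
    cc <- acos(d)
    U <- N - outer(d, mu)
    un <- sqrt(rowSums(U^2))
    f <- ifelse(un < 1e-14, 0, cc / pmax(un, 1e-300))
    U * f
}

.exp3 <- function(mu, v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-16) return(mu)
    mu * cos(nv) + (v / nv) * sin(nv)
}

#' Logarithmic map on the unit sphere
#'
#' Unfolds a unit normal into the azimuthal-equidistant tangent chart at a
#' reference normal \code{mu}. The chart preserves radial geodesic
#' distances: \code{sqrt(sum(logMap(n, mu)^2))} equals the great-circle
#' angle between \code{n} and \code{mu}. The scale factor is
#' \code{k = c / sin(c)} with \code{c} the geodesic angle (limit 1 at the
#' origin).
#'
#' @param n unit 3-vector to project.
#' @param mu unit 3-vector, chart reference point; must not be antipodal to
#'   \code{n}.
#' @return numeric length-2 chart coordinates (x', y').
#' @seealso [expMap()] for the inverse, [geodesicMean()].
#' @examples
#' logMap(c(0, 0, 1), c(0, 0, 1))         # origin of its own chart
#' sqrt(sum(logMap(c(sin(.1), 0, cos(.1)), c(0, 0, 1))^2))  # = 0.1
#' @export
logMap <- function(n, mu) {
    .checkUnit(n); .checkUnit(mu, "mu")
    if (sum(n * mu) < -1 + 1e-9)
        stop("degenerate chart: n is antipodal to mu")
    r <- .logChartC(n[1], n[2], n[3], mu[1], mu[2], mu[3])
    c(r$x, r$y)
}

#' Exponential map on the unit sphere
#'
#' Inverse of [logMap()]: maps tangent-chart coordinates at \code{mu} back
#' to a unit normal. Coordinates must lie inside the injectivity radius
#' (\code{sqrt(sum(t^2)) < pi}).
#'
#' @param t numeric length-2 chart coordinates.
#' @param mu unit 3-vector, chart reference point.
#' @return unit 3-vector.
#' @examples
#' expMap(c(0, 0), c(0, 0, 1))
#' expMap(logMap(c(0.1, 0.2, sqrt(0.95)), c(0, 0, 1)), c(0, 0, 1))
#' @export
expMap <- function(t, mu) {
    .checkUnit(mu, "mu")
    if (length(t) != 2L || any(!is.finite(t)))
        stop("t must be a finite 2-vector")
    if (sqrt(sum(t^2)) >= pi)
        stop("out of chart: ||t|| must be < pi")
    r <- .expChartC(t[1], t[2], mu[1], mu[2], mu[3])
    v <- c(r$x, r$y, r$z)
    v / sqrt(sum(v^2))
}

#' Weighted geodesic (Karcher) mean of unit normals
#'
#' The normal minimising the weighted sum of squared geodesic distances,
#' computed by the classical fixed-point iteration
#' mu <- Exp_mu( sum(w * Log_mu(n)) / sum(w) ), initialised at the
#' normalised Euclidean mean. Iteration stops when the update angle falls
#' below \code{tol} (default 1e-9 rad); more than \code{maxIter} iterations
#' raises an error.
#'
#' @param normals n x 3 matrix of unit normals (rows), or a length-3 vector.
#' @param weights non-negative weights, recycled to the number of normals.
#' @param tol convergence tolerance on the update angle, radians.
#' @param maxIter maximum number of fixed-point iterations.
#' @return unit 3-vector.
#' @examples
#' geodesicMean(rbind(c(0.1, 0, sqrt(0.99)), c(-0.1, 0, sqrt(0.99))))
#' @export
geodesicMean <- function(normals, weights = NULL, tol = 1e-9, maxIter = 100L) {
    if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3)
    n <- nrow(normals)
    if (n < 1L) stop("at least one normal required")
    if (is.null(weights)) weights <- rep(1, n)
    weights <- rep_len(weights, n)
    if (any(weights < 0) || sum(weights) <= 0)
        stop("weights must be non-negative with positive sum")
    mu <- euclideanMean(normals, weights)
    for (it in seq_len(maxIter)) {
        L <- .log3(normals, mu)
        step <- colSums(L * weights) / sum(weights)
        ang <- sqrt(sum(step^2))
        mu <- .exp3(mu, step)
        mu <- mu / sqrt(sum(mu^2))
        if (ang < tol) return(mu)
    }
    stop("geodesic mean did not converge in ", maxIter, " iterations")
}

#' Normalised weighted Euclidean mean of unit normals
#'
#' The weighted arithmetic mean of the vectors followed by the
#' post-normalisation that the extrinsic mean of unit vectors requires.
#' Agrees with [geodesicMean()] to O(spread^3) for tight clusters.
#'
#' @inheritParams geodesicMean
#' @return unit 3-vector.
#' @export
euclideanMean <- function(normals, weights = NULL) {
    if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3)
    n <- nrow(normals)
    if (is.null(weights)) weights <- rep(1, n)
    weights <- rep_len(weights, n)
    m <- colSums(normals * weights) / sum(weights)
    nm <- sqrt(sum(m^2))
    if (nm < 1e-12) stop("degenerate: weighted resultant is zero")
    m / nm
}

#' Rotation carrying one unit normal onto another
#'
#' Axis-angle rotation with axis along the cross product
#' \code{n x nTarget} and angle \code{acos(n . nTarget)} (dot product
#' clamped to [-1, 1]). Coincident normals return angle 0 with the
#' canonical axis (0, 0, 1); antipodal normals have no defined axis and
#' raise an error.
#'
#' @param n unit 3-vector, the normal to rotate.
#' @param nTarget unit 3-vector, the normal to reach.
#' @return list with components \code{axis} (unit 3-vector) and
#'   \code{angle} (radians in [0, pi]).
#' @seealso [applyRotation()], [so3Distance()].
#' @export
rotationBetween <- function(n, nTarget) {
    .checkUnit(n); .checkUnit(nTarget, "nTarget")
    d <- .clamp(sum(n * nTarget))
    if (d < -1 + 1e-9) stop("undefined axis: normals are antipodal")
    cr <- c(n[2] * nTarget[3] - n[3] * nTarget[2],
            n[3] * nTarget[1] - n[1] * nTarget[3],
            n[1] * nTarget[2] - n[2] * nTarget[1])
    cn <- sqrt(sum(cr^2))
    if (cn < 1e-12)
        return(list(axis = c(0, 0, 1), angle = 0))
    list(axis = cr / cn, angle = acos(d))
}

#' Apply an axis-angle rotation to a 3-vector (Rodrigues' formula)
#'
#' @param R list with \code{axis} (unit 3-vector) and \code{angle} (radians).
#' @param v 3-vector to rotate.
#' @return rotated 3-vector.
#' @export
applyRotation <- function(R, v) {
    e <- R$axis; th <- R$angle
    v * cos(th) + c(e[2] * v[3] - e[3] * v[2],
                    e[3] * v[1] - e[1] * v[3],
                    e[1] * v[2] - e[2] * v[1]) * sin(th) +
        e * sum(e * v) * (1 - cos(th))
}

#' Axis-angle to unit quaternion
#'
#' @param R list with \code{axis} (unit 3-vector) and \code{angle} (radians).
#' @return list with scalar part \code{s} and vector part \code{v}.
#' @export
quaternionFromRotation <- function(R) {
    list(s = cos(R$angle / 2), v = R$axis * sin(R$angle / 2))
}

#' Quaternion (Hamilton) product
#'
#' @param q1,q2 quaternions as lists with \code{s} and \code{v}.
#' @return quaternion list.
#' @export
quaternionMultiply <- function(q1, q2) {
    list(s = q1$s * q2$s - sum(q1$v * q2$v),
         v = q1$s * q2$v + q2$s * q1$v +
             c(q1$v[2] * q2$v[3] - q1$v[3] * q2$v[2],
               q1$v[3] * q2$v[1] - q1$v[1] * q2$v[3],
               q1$v[1] * q2$v[2] - q1$v[2] * q2$v[1]))
}

#' Distance between two rotations on SO(3)
#'
#' Two evaluation modes, both transcribed from the rotation-composition
#' metric used by the rotation-fields descriptor:
#' \describe{
#'   \item{\code{"parallel_axis"} (default)}{assumes the two rotation axes
#'     are parallel, which keeps the deviation component of the rotations
#'     and drops their orientation component:
#'     \code{d = atan2(sin(th1/2 + th2/2), cos(th1/2 + th2/2))}. This is the
#'     form the descriptor uses.}
#'   \item{\code{"full"}}{converts both rotations to unit quaternions,
#'     multiplies them and evaluates
#'     \code{atan2(||vector part||, scalar part)}. Agrees with the
#'     parallel-axis mode whenever the axes coincide and
#'     \code{th1 + th2 < 2*pi}.}
#' }
#' Note the metric composes the rotations rather than their relative
#' rotation, so \code{so3Distance(R, R)} equals the common angle, not 0;
#' this is deliberate (the descriptor quantifies accumulated deviation).
#'
#' @param R1,R2 rotations as lists with \code{axis} and \code{angle}.
#' @param mode \code{"parallel_axis"} or \code{"full"}.
#' @return distance in radians.
#' @export
so3Distance <- function(R1, R2, mode = c("parallel_axis", "full")) {
    mode <- match.arg(mode)
    if (mode == "parallel_axis") {
        h <- (R1$angle + R2$angle) / 2
        return(atan2(sin(h), cos(h)))
    }
    q <- quaternionMultiply(quaternionFromRotation(R1),
                            quaternionFromRotation(R2))
    atan2(sqrt(sum(q$v^2)), q$s)
}

# Vectorised parallel-axis SO(3) distance on angle matrices.
.so3DistPar <- function(th1, th2) {
    h <- (th1 + th2) / 2
    atan2(sin(h), cos(h))
}
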