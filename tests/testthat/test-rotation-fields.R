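# Rotation-field pyramid descriptor.

test_that("rotation field is zero on constant maps and local in support", {
    F0 <- rotationField(flatNormalMap(10), r = 2, method = "euclidean")
    expect_equal(max(rotationAngles(F0)), 0)
    # one perturbed pixel: non-zero angles only inside the radius-r footprint
    a <- normals(flatNormalMap(15))
    a[8, 8, ] <- c(sin(0.4), 0, cos(0.4))
    F1 <- rotationField(NormalMap(a), r = 3, method = "euclidean")
    ang <- rotationAngles(F1)
    outside <- ang
    outside[5:11, 5:11] <- 0
    expect_equal(max(outside), 0)
    expect_gt(ang[8, 8], 0)
})

test_that("per-pixel rotations carry original normals onto smoothed ones", {
    N <- randNormalMap(12, 12, amp = 2, seed = 31)
    Ns <- smoothNormalMap(N, r = 2, method = "geodesic")
    F1 <- rotationField(N, r = 2, method = "geodesic")
    a <- normals(N); b <- normals(Ns)
    ax <- rotationAxes(F1); ang <- rotationAngles(F1)
    for (i in c(1, 5, 9, 12)) for (j in c(2, 6, 12)) {
        got <- applyRotation(list(axis = ax[i, j, ], angle = ang[i, j]),
                             a[i, j, ])
        expect_lt(sqrt(sum((got - b[i, j, ])^2)), 1e-9)
    }
})

test_that("pyramid halves dimensions and level 1 matches the direct field", {
    N <- randNormalMap(64, 64, seed = 32)
    pyr <- rotationPyramid(N, levels = 3L, r = 2, method = "euclidean")
    expect_equal(pyramidLevels(pyr), 3L)
    dims <- t(vapply(pyr@fields, dim, integer(2)))
    expect_equal(dims[, 1], c(64L, 32L, 16L))
    F1 <- rotationField(N, r = 2, method = "euclidean")
    expect_equal(rotationAngles(pyr@fields[[1]]), rotationAngles(F1))
    expect_equal(rotationAxes(pyr@fields[[1]]), rotationAxes(F1))
    # constant input: all levels silent
    pyc <- rotationPyramid(flatNormalMap(16), levels = 3L, r = 2,
                           method = "euclidean")
    expect_true(all(vapply(pyc@fields,
                           function(f) max(rotationAngles(f)) == 0,
                           logical(1))))
    expect_error(rotationPyramid(flatNormalMap(2), levels = 3L, r = 1),
                 "too small")
})

test_that("neighbourhood vectors have length N*M + 2 with Eq-consistent entries", {
    H <- 8L
    th <- 0.3
    ax <- array(0, c(H, H, 3)); ax[, , 3] <- 1
    Fc <- new("RotationField", axis = ax, angle = matrix(th, H, H),
              radius = 1)
    V <- neighbourhoodVectors(Fc, window = c(3L, 3L))
    expect_equal(ncol(V), 11L)            # 3*3 - 1 distances + 3 components
    expect_equal(nrow(V), (H - 2L)^2)
    # constant field: every distance entry is atan2(sin th, cos th)
    expect_equal(max(abs(V[, 1:8] - atan2(sin(th), cos(th)))), 0)
    expect_equal(unname(V[1, 9:11]), c(0, 0, th))
    # identity-rotation field: distances 0 and zero central vector
    Fi <- new("RotationField", axis = ax, angle = matrix(0, H, H),
              radius = 1)
    Vi <- neighbourhoodVectors(Fi, window = c(3L, 3L))
    expect_equal(max(abs(Vi)), 0)
    expect_error(neighbourhoodVectors(Fc, window = c(2L, 3L)), "odd")
    expect_error(neighbourhoodVectors(Fc, window = c(9L, 9L)), "larger")
})

test_that("k-means quantisation conserves mass and separates clear clouds", {
    V <- matrix(1, 40, 5)
    q <- quantiseHistogram(V, k = 1L, seed = 2)
    expect_equal(q$counts, 40)
    # two well-separated clouds: masses equal the cloud sizes
    set.seed(41)
    V2 <- rbind(matrix(rnorm(60 * 4, 0, 0.1), ncol = 4),
                matrix(rnorm(25 * 4, 10, 0.1), ncol = 4))
    q2 <- quantiseHistogram(V2, k = 2L, seed = 3)
    expect_equal(sort(q2$counts), c(25, 60))
    # assignment agrees with direct nearest-centroid labels
    lab <- apply(V2, 1, function(v)
        which.min(colSums((t(q2$centers) - v)^2)))
    expect_equal(q2$labels, unname(lab))
    # conservation on random input
    V3 <- matrix(rnorm(200), ncol = 4)
    expect_equal(sum(quantiseHistogram(V3, k = 7L, seed = 1)$counts), 50)
    expect_error(fitDictionary(V3[0, , drop = FALSE], 2), "no vectors")
})

test_that("descriptor length is levels * k and mass is conserved per level", {
    N <- randNormalMap(32, 32, seed = 33)
    v <- rfDescriptor(N, levels = 3L, k = 100L, r = 2, seed = 5,
                      method = "euclidean")
    expect_length(v, 300L)
    v2 <- rfDescriptor(N, levels = 3L, k = 200L, r = 2, seed = 5,
                       method = "euclidean")
    expect_length(v2, 600L)
    v1 <- rfDescriptor(N, levels = 1L, k = 1L, r = 2, seed = 5,
                       method = "euclidean")
    expect_length(v1, 1L)
    # per-level mass equals that level's interior pixel count (window 3x3)
    expect_equal(sum(v[1:100]), (32 - 2)^2)
    expect_equal(sum(v[101:200]), (16 - 2)^2)
    expect_equal(sum(v[201:300]), (8 - 2)^2)
})

test_that("constant maps quantise to a single cluster for any seed", {
    N <- flatNormalMap(16)
    for (sd in c(1, 99)) {
        v <- rfDescriptor(N, levels = 2L, k = 5L, r = 2, seed = sd,
                          method = "euclidean")
        expect_equal(sum(v > 0), 2L)  # one occupied bin per level
        expect_equal(sum(v), (16 - 2)^2 + (8 - 2)^2)
    }
})

test_that("descriptor is stable under in-plane content translation", {
    # histograms of local quantities: shifting the content moves which
    # pixels are interior but leaves the bulk of the histogram intact
    set.seed(44)
    h <- matrix(0, 40, 40)
    for (i in 1:25) {
        cy <- runif(1, 12, 28); cx <- runif(1, 12, 28)
        d2 <- outer((1:40 - cy)^2, (1:40 - cx)^2, "+")
        h <- h - 0.8 * exp(-d2 / (2 * 1.5^2))
    }
    hShift <- rbind(h[3:40, ], h[1:2, ])  # translate rows by 2
    N1 <- normalMapFromHeight(h)
    N2 <- normalMapFromHeight(hShift)
    F1 <- rotationField(N1, r = 2, method = "euclidean")
    F2 <- rotationField(N2, r = 2, method = "euclidean")
    ctr <- fitDictionary(neighbourhoodVectors(F1), k = 8L, seed = 1)
    h1 <- quantiseHistogram(neighbourhoodVectors(F1), centers = ctr)$counts
    h2 <- quantiseHistogram(neighbourhoodVectors(F2), centers = ctr)$counts
    # L1 difference small relative to total mass (border effects only)
    expect_lt(sum(abs(h1 - h2)) / sum(h1), 0.15)
})

test_that("small radii respond to pores, large radii to acne (scale match)", {
    angFor <- function(cond, r) {
        m <- 0
        for (s in 1:3) {
            p <- makePatch(cond, 5L, size = 32L, seed = s)
            m <- m + mean(rotationAngles(
                rotationField(patchNormalMap(p), r, method = "euclidean")))
        }
        m / 3
    }
    porSmall <- angFor("pores", 2); porLarge <- angFor("pores", 7)
    acnSmall <- angFor("acne", 2); acnLarge <- angFor("acne", 7)
    # pores: fine relief already captured at small radius; the ratio
    # large/small is higher for the coarse acne structures
    expect_gt(acnLarge / acnSmall, porLarge / porSmall)
})

test_that("rotation fields export to a valid RGB array", {
    N <- randNormalMap(10, 10, seed = 35)
    rgb <- rotationFieldToRGB(rotationField(N, r = 2, method = "euclidean"))
    expect_equal(dim(rgb), c(10, 10, 3))
    expect_true(all(rgb >= 0 & rgb <= 1))
})
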