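# NormalMap container, I/O, derived maps, smoothing and resampling.

test_that("NormalMap validity enforces unit length and positive z", {
    expect_error(NormalMap(array(1, c(2, 2, 3))), "unit length")
    a <- array(0, c(2, 2, 3)); a[, , 3] <- -1
    expect_error(NormalMap(a), "positive")
    expect_s4_class(flatNormalMap(3, 4), "NormalMap")
    expect_equal(dim(flatNormalMap(3, 4)), c(3L, 4L))
})

test_that("rgb8 PNG round-trip matches the quantisation simulation", {
    N <- randNormalMap(12, 12, seed = 2)
    f <- tempfile(fileext = ".png")
    writeNormalMap(N, f, encoding = "rgb8")
    back <- readNormalMap(f, encoding = "rgb8")
    # oracle: simulate the 8-bit quantisation directly
    a <- normals(N)
    q <- round((a + 1) / 2 * 255) / 255
    sim <- NormalMap(2 * q - 1, renormalise = TRUE)
    expect_lt(maxAngularError(back, sim), 1e-6)
    # quantisation bound: componentwise error <= 1/255 pre-normalisation
    expect_lt(maxAngularError(back, N), 2 * sqrt(3) / 255)
    unlink(f)
})

test_that("flat-colour PNG decodes to vertical normals", {
    f <- tempfile(fileext = ".png")
    png::writePNG(array(c(128, 128, 255)[rep(1:3, each = 16)] / 255,
                        c(4, 4, 3)), f)
    N <- readNormalMap(f)
    expect_lt(maxAngularError(N, flatNormalMap(4)), 0.01)
    unlink(f)
})

test_that("float container round-trips exactly and z<=0 is policed", {
    N <- randNormalMap(5, 7, seed = 3)
    f <- tempfile(fileext = ".txt")
    writeNormalMap(N, f, encoding = "float")
    expect_equal(normals(readNormalMap(f, encoding = "float")), normals(N),
                 tolerance = 1e-12)
    # 1x1 identity case
    writeNormalMap(flatNormalMap(1, 1), f, encoding = "float")
    expect_equal(normals(readNormalMap(f, "float")),
                 normals(flatNormalMap(1, 1)))
    # a z<0 pixel must be rejected unless flipZ
    writeLines(c("1 1", "0 0 -1"), f)
    expect_error(readNormalMap(f, "float"), "z <= 0")
    expect_equal(normals(readNormalMap(f, "float", flipZ = TRUE))[1, 1, ],
                 c(0, 0, 1))
    unlink(f)
})

test_that("slant-tilt map implements the tangent formulas", {
    N <- normalMapFromComponents(
        matrix(c(0, 1 / sqrt(2), 0.5), 1), matrix(c(0, 0, 0.5), 1),
        matrix(c(1, 1 / sqrt(2), sqrt(2) / 2), 1), renormalise = FALSE)
    st <- slantTilt(N, rescale = FALSE)
    expect_equal(as.numeric(st$slant), c(0, 1, 1), tolerance = 1e-12)
    expect_equal(as.numeric(st$tilt), c(0, 0, 1), tolerance = 1e-12)
    # rescaled channels live in [-1, 1]; constant channels go to 0
    M <- randNormalMap(10, 10, seed = 6)
    sr <- slantTilt(M)
    expect_true(all(abs(sr$slant) <= 1) && all(abs(sr$tilt) <= 1))
    expect_equal(range(sr$slant), c(-1, 1))
    flat <- slantTilt(flatNormalMap(4))
    expect_true(all(flat$slant == 0) && all(flat$tilt == 0))
})

test_that("tangent map is zero on constant maps and local in support", {
    tm <- tangentMap(flatNormalMap(8), window = 3L)
    expect_equal(max(abs(tm$x)), 0)
    expect_equal(max(abs(tm$y)), 0)
    # single perturbed pixel: effects confined to windows covering it
    a <- normals(flatNormalMap(9))
    a[5, 5, ] <- c(sin(0.3), 0, cos(0.3))
    N <- NormalMap(a)
    tm <- tangentMap(N, window = 3L)
    mag <- sqrt(tm$x^2 + tm$y^2)
    far <- mag
    far[4:6, 4:6] <- 0
    expect_equal(max(far), 0)
    expect_gt(mag[5, 5], 0)
})

test_that("tangent map agrees with a per-pixel brute-force evaluation", {
    N <- randNormalMap(11, 11, amp = 2, seed = 8)
    w <- 3L
    tm <- tangentMap(N, window = w)
    a <- normals(N)
    r <- w %/% 2L
    k <- exp(-(-r:r)^2 / (2 * (r / 2)^2))
    for (i in c(1, 4, 6, 11)) for (j in c(1, 5, 9)) {
        rows <- max(1, i - r):min(11, i + r)
        cols <- max(1, j - r):min(11, j + r)
        nb <- NULL; wt <- NULL
        for (ri in rows) for (ci in cols) {
            nb <- rbind(nb, a[ri, ci, ])
            wt <- c(wt, k[ri - i + r + 1] * k[ci - j + r + 1])
        }
        mu <- geodesicMean(nb, wt)
        t0 <- logMap(a[i, j, ], mu)
        expect_equal(c(tm$x[i, j], tm$y[i, j]), t0, tolerance = 1e-6)
    }
})

test_that("smoothing preserves constants and finds two-normal midpoints", {
    for (m in c("geodesic", "euclidean")) {
        S <- smoothNormalMap(flatNormalMap(8), r = 2, method = m)
        expect_lt(maxAngularError(S, flatNormalMap(8)), 1e-12)
    }
    # checkerboard of two normals symmetric in x: midpoint is vertical
    n1 <- c(sin(0.1), 0, cos(0.1)); n2 <- c(-sin(0.1), 0, cos(0.1))
    H <- 24L
    pick <- outer(1:H, 1:H, function(i, j) (i + j) %% 2L)
    a <- array(0, c(H, H, 3))
    a[, , 1] <- n1[1] * (pick == 0) + n2[1] * (pick == 1)
    a[, , 3] <- n1[3]
    N <- NormalMap(a)
    S <- smoothNormalMap(N, r = 6, method = "geodesic")
    interior <- normals(S)[8:16, 8:16, ]
    expect_lt(max(acos(pmin(interior[, , 3], 1))), 0.02)
    # unit length preserved
    nrm <- sqrt(rowSums(matrix(normals(S), ncol = 3)^2))
    expect_lt(max(abs(nrm - 1)), 1e-9)
})

test_that("geodesic and euclidean smoothing agree on low-spread maps", {
    N <- randNormalMap(16, 16, amp = 0.3, seed = 12)  # < 5 degree spread
    G <- smoothNormalMap(N, r = 2, method = "geodesic")
    E <- smoothNormalMap(N, r = 2, method = "euclidean")
    expect_lt(maxAngularError(G, E), 1e-3)
})

test_that("geodesic down-sampling equals a straight-loop transcription", {
    N <- randNormalMap(8, 8, amp = 1, seed = 13)
    mu <- globalMean(N)
    D <- downsampleNormalMap(N, 2L, window = c(2L, 2L), mu = mu)
    expect_equal(dim(D), c(4L, 4L))
    # independent straight-loop implementation about the same chart point
    a <- normals(N)
    for (i in 1:4) for (j in 1:4) {
        acc <- c(0, 0)
        cnt <- 0
        w0 <- i * 2L - 1L; y0 <- j * 2L - 1L
        for (k in 0:1) for (l in 0:1) {
            ri <- w0 + k; ci <- y0 + l
            if (ri >= 1 && ri <= 8 && ci >= 1 && ci <= 8) {
                acc <- acc + logMap(a[ri, ci, ], mu)
                cnt <- cnt + 1
            }
        }
        expect_equal(normals(D)[i, j, ], expMap(acc / cnt, mu),
                     tolerance = 1e-9)
    }
})

test_that("down-sampling keeps constants and S = 1 is the identity", {
    F8 <- flatNormalMap(8)
    for (S in c(1L, 2L, 4L)) {
        D <- downsampleNormalMap(F8, S, window = c(S, S))
        expect_lt(maxAngularError(D, flatNormalMap(8 %/% S)), 1e-9)
    }
    N <- randNormalMap(6, 6, seed = 14)
    expect_identical(downsampleNormalMap(N, 1L, window = c(1L, 1L)), N)
    expect_identical(upsampleNormalMap(N, 1L), N)
    expect_error(downsampleNormalMap(N, 7L), "dimension")
})

test_that("geodesic down-then-up beats naive per-channel resampling", {
    # smooth low-frequency map: the ordering mirrors the geodesic route's
    # advantage over classical channel-wise resampling
    N <- randNormalMap(32, 32, amp = 2.5, sigma = 3, seed = 15)
    errG <- meanAngularError(N, upsampleNormalMap(
        downsampleNormalMap(N, 2L, window = c(2L, 2L)), 2L))
    errN <- meanAngularError(N, naiveUpsample(naiveDownsample(N, 2L), 2L))
    expect_lt(errG, errN)
    U <- upsampleNormalMap(flatNormalMap(4), 3L)
    expect_lt(maxAngularError(U, flatNormalMap(12)), 1e-9)
})

test_that("mean angular error matches its definition", {
    N <- randNormalMap(7, 7, amp = 0.5, seed = 16)
    expect_equal(meanAngularError(N, N), 0)
    # every pixel moved 0.1 rad along a geodesic
    a <- normals(N)
    b <- a
    for (i in 1:7) for (j in 1:7) {
        n <- a[i, j, ]
        d <- c(-n[2], n[1], 0)
        if (sqrt(sum(d^2)) < 1e-8) d <- c(1, 0, 0)
        d <- d / sqrt(sum(d^2))
        b[i, j, ] <- n * cos(0.1) + d * sin(0.1)
    }
    expect_equal(meanAngularError(N, NormalMap(b, renormalise = TRUE)), 0.1,
                 tolerance = 1e-9)
    # straight-loop equality on a random pair
    M <- randNormalMap(7, 7, seed = 17)
    acc <- 0
    am <- normals(M)
    for (i in 1:7) for (j in 1:7) acc <- acc + vecAngle(a[i, j, ], am[i, j, ])
    expect_equal(meanAngularError(N, M), acc / 49, tolerance = 1e-12)
    expect_error(meanAngularError(N, flatNormalMap(3)), "mismatch")
})
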