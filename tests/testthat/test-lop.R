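# Local Orientation Patterns.

test_that("pattern function 1 thresholds the dot product with >=", {
    n <- c(0.1, 0.2, sqrt(0.95))
    expect_equal(patternFn1(n, n, 0.9), 1L)
    expect_equal(patternFn1(c(1, 0, 0), c(0, 1, 0), 0.5), 0L)
    # boundary: dot exactly tau counts as 1
    a <- c(0, 0, 1); b <- c(sin(pi / 3), 0, cos(pi / 3))
    expect_equal(patternFn1(a, b, 0.5), 1L)
    expect_error(patternFn1(a, b, 2), "tau")
})

test_that("pattern function 2 follows the four-way azimuth/polar split", {
    n <- c(0.3, -0.1, sqrt(0.9))
    expect_equal(patternFn2(n, n), 3L)  # both >= branches on ties
    # case 0: centre strictly below in azimuth and polar angle
    n0 <- c(cos(0.5) * sin(0.2), sin(0.5) * sin(0.2), cos(0.2))
    ni <- c(cos(1.0) * sin(0.4), sin(1.0) * sin(0.4), cos(0.4))
    expect_equal(patternFn2(n0, ni), 0L)
    # exhaustive agreement with a straight transcription
    set.seed(51)
    A <- randNormals(1000); B <- randNormals(1000)
    for (i in seq_len(1000)) {
        t0 <- atan2(A[i, 2], A[i, 1]); ti <- atan2(B[i, 2], B[i, 1])
        p0 <- acos(A[i, 3]); pi_ <- acos(B[i, 3])
        want <- if (t0 < ti && p0 < pi_) 0L else
                if (t0 < ti && p0 >= pi_) 1L else
                if (t0 >= ti && p0 < pi_) 2L else 3L
        expect_identical(patternFn2(A[i, ], B[i, ]), want)
    }
})

test_that("global threshold averages the evaluated centre-neighbour dots", {
    expect_equal(globalThreshold(flatNormalMap(8)), 1)
    # two-normal checkerboard, 4-point integer circle: explicit enumeration
    n1 <- c(sin(0.25), 0, cos(0.25)); n2 <- c(0, sin(0.4), cos(0.4))
    H <- 8L
    a <- array(0, c(H, H, 3))
    pick <- outer(1:H, 1:H, function(i, j) (i + j) %% 2L)
    for (k in 1:3) a[, , k] <- n1[k] * (pick == 0) + n2[k] * (pick == 1)
    N <- NormalMap(a, renormalise = TRUE)
    cfg <- lopConfig(nPoints = 4L, radius = 1)
    got <- globalThreshold(N, cfg)
    an <- normals(N)
    offs <- list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))  # E, S, W, N
    acc <- c()
    for (i in 2:(H - 1)) for (j in 2:(H - 1)) for (o in offs)
        acc <- c(acc, sum(an[i, j, ] * an[i + o[1], j + o[2], ]))
    expect_equal(got, mean(acc), tolerance = 1e-12)
    expect_true(got >= -1 && got <= 1)
    # local mode returns a per-pixel threshold map in [-1, 1]
    tl <- globalThreshold(N, lopConfig(nPoints = 4L, radius = 1,
                                       thresholdMode = "local_map"))
    expect_equal(dim(tl), c(H - 2L, H - 2L))
    expect_true(all(tl >= -1 & tl <= 1))
})

test_that("constant maps give the all-ones texture unit for both functions", {
    N <- flatNormalMap(10)
    L1 <- lopImage(N, lopConfig(nPoints = 8L, radius = 1, patternFn = 1L,
                                threshold = 0.5))
    expect_equal(unique(as.vector(L1[!is.na(L1)])), 255)  # sum 2^(i-1)
    L2 <- lopImage(N, lopConfig(nPoints = 8L, radius = 1, patternFn = 2L))
    expect_equal(unique(as.vector(L2[!is.na(L2)])), 65535)  # sum 3*4^(i-1)
})

test_that("texture-unit values stay within n^N - 1 on random maps", {
    N <- randNormalMap(14, 14, seed = 52)
    for (pf in 1:2) for (r in c(1, 2)) {
        L <- lopImage(N, lopConfig(nPoints = 8L, radius = r,
                                   patternFn = pf))
        v <- L[!is.na(L)]
        expect_true(all(v >= 0 & v <= (if (pf == 1) 2 else 4)^8 - 1))
        expect_true(all(v == floor(v)))
    }
    expect_error(lopImage(flatNormalMap(3), lopConfig(radius = 2)),
                 "smaller")
})

test_that("LOP image equals a straight Eq transcription on an 11x11 map", {
    N <- randNormalMap(11, 11, amp = 2, seed = 53)
    a <- normals(N)
    offs <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))  # 4-point circle
    for (pf in 1:2) {
        cfg <- lopConfig(nPoints = 4L, radius = 1, patternFn = pf,
                         threshold = if (pf == 1L) 0.999 else NULL)
        L <- lopImage(N, cfg)
        nB <- if (pf == 1L) 2 else 4
        for (i in 2:10) for (j in 2:10) {
            val <- 0
            for (q in seq_along(offs)) {
                # circle point q at angle 2*pi*(q-1)/4: (dx, dy) per offs
                ni <- a[i + offs[[q]][2], j + offs[[q]][1], ]
                fi <- if (pf == 1L) patternFn1(a[i, j, ], ni, 0.999)
                      else patternFn2(a[i, j, ], ni)
                val <- val + fi * nB^(q - 1)
            }
            expect_equal(L[i, j], val)
        }
    }
})

test_that("histograms have length n^N, conserve mass, single bin for flats", {
    N <- randNormalMap(12, 12, seed = 54)
    cfg1 <- lopConfig(nPoints = 8L, radius = 1, patternFn = 1L)
    h1 <- lopHistogram(lopImage(N, cfg1), cfg1)
    expect_length(h1, 256L)
    expect_equal(sum(h1), 100)            # (12-2)^2 interior pixels
    cfg2 <- lopConfig(nPoints = 8L, radius = 1, patternFn = 2L)
    h2 <- lopHistogram(lopImage(N, cfg2), cfg2)
    expect_length(h2, 65536L)
    expect_equal(sum(h2), 100)
    hf <- lopHistogram(lopImage(flatNormalMap(10), cfg1), cfg1)
    expect_equal(sum(hf > 0), 1L)
    expect_equal(unname(hf["255"]), 64)
})

test_that("raising the threshold can only clear pattern bits", {
    N <- randNormalMap(13, 13, amp = 2, seed = 55)
    cfgLo <- lopConfig(nPoints = 8L, radius = 1, threshold = 0.9)
    cfgHi <- lopConfig(nPoints = 8L, radius = 1, threshold = 0.99)
    lo <- lopImage(N, cfgLo); hi <- lopImage(N, cfgHi)
    ok <- !is.na(lo)
    expect_true(all(bitwAnd(as.integer(lo[ok]), as.integer(hi[ok])) ==
                    as.integer(hi[ok])))
})

test_that("pore patches have higher pf2 histogram entropy than smooth skin", {
    entropy <- function(h) {
        p <- h[h > 0] / sum(h)
        -sum(p * log(p))
    }
    cfg <- lopConfig(nPoints = 8L, radius = 1, patternFn = 2L)
    diffs <- vapply(1:5, function(s) {
        pp <- makePatch("pores", 5L, size = 32L, seed = s)
        ps <- makePatch("smooth", 5L, size = 32L, seed = s)
        entropy(lopDescriptor(patchNormalMap(pp), cfg)) -
            entropy(lopDescriptor(patchNormalMap(ps), cfg))
    }, numeric(1))
    expect_gt(mean(diffs), 0)
})
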