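# Shared fixtures, all generated in code.

# Random unit normals within `spread` radians of the +z pole.
randNormals <- function(n, spread = pi / 3) {
    phi <- stats::runif(n, 0, 2 * pi)
    ang <- stats::runif(n, 0, spread)
    cbind(sin(ang) * cos(phi), sin(ang) * sin(phi), cos(ang))
}

# Smooth random normal map from a filtered-noise height field.
randNormalMap <- function(H, W = H, amp = 1.5, sigma = max(2, H / 6),
                          seed = 1) {
    set.seed(seed)
    h <- matrix(rnorm(H * W), H, W)
    k <- exp(-(seq(-ceiling(2 * sigma), ceiling(2 * sigma)))^2 /
                 (2 * sigma^2))
    k <- k / sum(k)
    sm <- function(m) {
        A <- sapply(seq_len(nrow(m)), function(i) {
            idx <- i + seq_along(k) - (length(k) + 1) / 2
            idx <- pmin(pmax(idx, 1), nrow(m))
            colSums(m[idx, , drop = FALSE] * k)
        })
        t(A)
    }
    h <- sm(t(sm(t(sm(t(sm(t(h))))))))
    h <- amp * (h - mean(h)) / max(sd(h), 1e-12)
    normalMapFromHeight(h)
}

# Flat LabeledPatch with unit albedo (for rendering tests).
flatPatch <- function(H, W = H, albedo = 1) {
    new("LabeledPatch", normal = flatNormalMap(H, W),
        albedo = matrix(albedo, H, W), height = matrix(0, H, W),
        condition = "smooth", severity = 1L, ratings = numeric(0))
}

# Angle between two unit vectors.
vecAngle <- function(a, b) acos(min(max(sum(a * b), -1), 1))

maxAngularError <- function(A, B) {
    a <- normals(A); b <- normals(B)
    d <- a[, , 1] * b[, , 1] + a[, , 2] * b[, , 2] + a[, , 3] * b[, , 3]
    max(acos(pmin(pmax(d, -1), 1)))
}
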