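# BTF texton gold-standard baseline: multi-illumination / multi-view
# intensity images filtered with a 14-filter bank at three scales
# (42 responses per pixel per image), stacked across imaging conditions
# and quantised into a k-means texton dictionary.

#' Leung-Malik style filter bank
#'
#' Per scale: 6 oriented first-derivative-of-Gaussian (edge) filters with
#' 3:1 elongation, 4 difference-of-Gaussian and 4 Gaussian filters on a
#' sigma ladder - 14 filters, times 3 scales = 42. The oriented and DoG
#' filters are zero mean. Exact sigma values are configuration, not ground
#' truth; the counts are the contract.
#'
#' @param scales numeric vector of base scales (default 3 octaves).
#' @param size kernel half-width cap in pixels.
#' @return list of kernel matrices with a \code{"meta"} attribute.
#' @export
lmFilterBank <- function(scales = c(1, 2, 4), size = 12L) {
    kernels <- list()
    meta <- list()
    for (s in scales) {
        hw <- min(as.integer(size), as.integer(ceiling(4 * s)))
        g <- expand.grid(x = -hw:hw, y = -hw:hw)
        # 6 oriented edge filters (y-derivative of an elongated Gaussian)
        for (o in 1:6) {
            th <- pi * (o - 1) / 6
            xp <- g$x * cos(th) + g$y * sin(th)
            yp <- -g$x * sin(th) + g$y * cos(th)
            k <- -yp / s^2 * exp(-(xp^2 / (2 * (3 * s)^2) +
                                   yp^2 / (2 * s^2)))
            k <- matrix(k - mean(k), 2L * hw + 1L)
            kernels[[length(kernels) + 1L]] <- k / sum(abs(k))
            meta[[length(meta) + 1L]] <- list(type = "edge", scale = s,
                                              theta = th)
        }
        # 4 difference-of-Gaussian filters
        for (f in c(0.6, 0.9, 1.2, 1.5)) {
            r2 <- g$x^2 + g$y^2
            s1 <- f * s; s2 <- 1.6 * f * s
            k <- exp(-r2 / (2 * s1^2)) / (2 * pi * s1^2) -
                 exp(-r2 / (2 * s2^2)) / (2 * pi * s2^2)
            k <- matrix(k - mean(k), 2L * hw + 1L)
            kernels[[length(kernels) + 1L]] <- k / sum(abs(k))
            meta[[length(meta) + 1L]] <- list(type = "dog", scale = s,
                                              sigma = s1)
        }
        # 4 Gaussian (low-pass) filters
        for (f in c(0.6, 0.9, 1.2, 1.5)) {
            k <- exp(-(g$x^2 + g$y^2) / (2 * (f * s)^2))
            k <- matrix(k, 2L * hw + 1L)
            kernels[[length(kernels) + 1L]] <- k / sum(k)
            meta[[length(meta) + 1L]] <- list(type = "gauss", scale = s,
                                              sigma = f * s)
        }
    }
    attr(kernels, "meta") <- meta
    kernels
}

#' Per-pixel filter-bank response vectors
#'
#' Convolves a greyscale image with every kernel of the bank (replicated
#' borders) and returns one response vector per pixel: 42 elements for the
#' default three-scale, 14-filter bank, independent of image size.
#'
#' @param img numeric matrix (greyscale image).
#' @param bank a filter bank from [lmFilterBank()].
#' @return numeric matrix, pixels (row-major) x filters.
#' @export
filterBankResponses <- function(img, bank = lmFilterBank()) {
    out <- vapply(bank,
                  function(k) as.vector(.filter2(img, k,
                                                 boundary = "replicate")),
                  numeric(length(img)))
    colnames(out) <- paste0("f", seq_along(bank))
    out
}

#' BTF image stack
#'
#' A set of co-registered greyscale images of the same surface patch under
#' V viewpoints and L light directions.
#'
#' @param images list of numeric matrices of identical dimensions, ordered
#'   view-major.
#' @param views,lights integers with \code{views * lights == length(images)}.
#' @return list of class \code{BTFStack}.
#' @export
btfStack <- function(images, views, lights) {
    if (length(images) != views * lights)
        stop("need views * lights images")
    d <- dim(images[[1]])
    if (!all(vapply(images, function(m) all(dim(m) == d), logical(1))))
        stop("images must be co-registered (identical dimensions)")
    structure(list(images = images, views = as.integer(views),
                   lights = as.integer(lights)),
              class = "BTFStack")
}

#' Stacked per-pixel responses of a BTF stack
#'
#' Concatenates the 42 filter responses of every image in the stack:
#' 42 * V * L responses per pixel (882 for 3 views x 7 lights, 588 for
#' 2 x 7).
#'
#' @param stack a [btfStack()].
#' @param bank a filter bank from [lmFilterBank()].
#' @return numeric matrix, pixels x (42 * V * L).
#' @export
stackResponses <- function(stack, bank = lmFilterBank()) {
    stopifnot(inherits(stack, "BTFStack"))
    do.call(cbind, lapply(stack$images, filterBankResponses, bank = bank))
}

#' Texton histogram of response vectors
#'
#' k-means quantisation of per-pixel response vectors into a texton
#' dictionary (fitted on the training corpus and reused at test time) and
#' the histogram of texton labels, length k.
#'
#' @param vectors numeric matrix, pixels x responses.
#' @param k number of textons.
#' @param centers optional pre-fitted dictionary.
#' @param seed integer seed for the self-fit case.
#' @return numeric length-k histogram with the dictionary in
#'   \code{attr(, "centers")}.
#' @export
textonHistogram <- function(vectors, k = 200L, centers = NULL, seed = 1L) {
    q <- quantiseHistogram(vectors, k = k, centers = centers, seed = seed)
    h <- q$counts
    attr(h, "centers") <- q$centers
    attr(h, "descriptor") <- "btf_texton"
    h
}
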