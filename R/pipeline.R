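# End-to-end evaluation: consensus labels with rater exclusion, SVM-weight
# feature ranking, MLP classification under stratified 10-fold
# cross-validation, per-class and support-weighted F-measures. All
# data-dependent fitting (feature selection, scaling, k-means
# dictionaries) happens inside training folds only.

#' Precision, recall and F-measure of a prediction
#'
#' F = 2PR/(P + R) per class (0 when P + R = 0), plus the support-weighted
#' and unweighted (macro) means over classes.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @return list with \code{perClass} (data.frame), \code{weightedF},
#'   \code{macroF} and the pooled \code{confusion} table.
#' @export
fMeasure <- function(pred, truth) {
    lv <- sort(unique(c(as.character(pred), as.character(truth))))
    pred <- factor(as.character(pred), levels = lv)
    truth <- factor(as.character(truth), levels = lv)
    cm <- table(pred = pred, truth = truth)
    tp <- diag(cm)
    prec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
    rec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
    f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    support <- colSums(cm)
    keep <- support > 0
    list(perClass = data.frame(class = lv, precision = as.numeric(prec),
                               recall = as.numeric(rec), f = as.numeric(f),
                               support = as.numeric(support)),
         weightedF = sum(f[keep] * support[keep]) / sum(support[keep]),
         macroF = mean(f[keep]),
         confusion = cm)
}

#' Consensus labels with iterative rater exclusion
#'
#' Raters are excluded successively in ascending order of their mean
#' correlation with the remaining raters; the procedure keeps the largest
#' rater subset whose mean pairwise correlation reaches the threshold
#' (default 0.5). If no subset of >= 2 raters reaches it, all raters are
#' kept with a warning. Consensus labels are the rounded means of the
#' retained raters' scores.
#'
#' @param ratings numeric matrix, items x raters.
#' @param threshold minimum mean inter-rater correlation.
#' @param method correlation method (default "spearman").
#' @return list with \code{labels}, \code{retained} (column indices),
#'   \code{excluded} (in exclusion order), \code{meanCor} of the retained
#'   set and \code{converged}.
#' @export
raterConsensus <- function(ratings, threshold = 0.5,
                           method = c("spearman", "kendall", "pearson")) {
    method <- match.arg(method)
    nR <- ncol(ratings)
    if (nR < 2L) stop("need at least 2 raters")
    cm <- suppressWarnings(stats::cor(ratings, method = method))
    cm[!is.finite(cm)] <- 0
    meanPair <- function(idx) {
        if (length(idx) < 2L) return(NA_real_)
        sub <- cm[idx, idx]
        mean(sub[upper.tri(sub)])
    }
    active <- seq_len(nR)
    excluded <- integer(0)
    sets <- list(active)
    while (length(active) > 2L) {
        toOthers <- vapply(active, function(r)
            mean(cm[r, setdiff(active, r)]), numeric(1))
        drop <- active[which.min(toOthers)]
        excluded <- c(excluded, drop)
        active <- setdiff(active, drop)
        sets[[length(sets) + 1L]] <- active
    }
    ok <- vapply(sets, function(s) meanPair(s) >= threshold, logical(1))
    if (any(ok)) {
        retained <- sets[[which(ok)[1]]]  # largest qualifying subset
        converged <- TRUE
    } else {
        warning("no rater subset of >= 2 reaches mean correlation ",
                threshold, "; keeping all raters")
        retained <- seq_len(nR)
        converged <- FALSE
    }
    labels <- pmin(pmax(round(rowMeans(ratings[, retained, drop = FALSE])),
                        1), 5)
    list(labels = labels, retained = retained, excluded = excluded,
         meanCor = meanPair(retained), converged = converged)
}

#' Rank features by linear-SVM weights and keep the top k
#'
#' One linear SVM per class (one-vs-rest) on standardised training
#' features; features are ranked by the summed absolute hyperplane weights
#' over classes. Fit on training folds only.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels.
#' @param k number of features to keep (64 by default).
#' @param cost SVM cost parameter.
#' @return integer vector of selected column indices (ranked), with the
#'   full score vector in \code{attr(, "scores")}.
#' @export
svmRankSelect <- function(X, y, k = 64L, cost = 1) {
    k <- as.integer(k)
    p <- ncol(X)
    if (k >= p) {
        if (k > p) warning("k exceeds the number of features; keeping all")
        idx <- seq_len(p)
        attr(idx, "scores") <- rep(NA_real_, p)
        return(idx)
    }
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    live <- sd > 0
    Xs <- sweep(sweep(X[, live, drop = FALSE], 2, mu[live]), 2, sd[live],
                "/")
    y <- factor(y)
    score <- numeric(sum(live))
    for (cl in levels(y)) {
        yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
        if (length(unique(yb)) < 2L) next
        fit <- e1071::svm(Xs, yb, kernel = "linear", cost = cost,
                          scale = FALSE)
        w <- t(fit$coefs) %*% fit$SV
        score <- score + abs(as.numeric(w))
    }
    full <- numeric(p)
    full[live] <- score
    idx <- order(full, decreasing = TRUE)[seq_len(k)]
    attr(idx, "scores") <- full
    idx
}

#' Stratified fold assignment
#'
#' @param y labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer fold ids (1..folds) per sample.
#' @export
stratifiedFolds <- function(y, folds = 10L, seed = 1L) {
    folds <- as.integer(folds)
    y <- factor(y)
    if (any(table(y) < 2L))
        stop("stratification error: every class needs >= 2 samples")
    set.seed(.subSeed(seed, 33L))
    out <- integer(length(y))
    for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        out[idx] <- rep_len(seq_len(folds), length(idx))
    }
    out
}

# Train feature selection + MLP on the training rows of X and predict the
# test rows. Hidden size defaults to the mean of the class count and the
# post-selection attribute count.
.foldFit <- function(Xtr, ytr, Xte, selectK, hidden = NULL, seed = 1L,
                     decay = 0.1, maxit = 200L) {
    ytr <- factor(ytr)
    sel <- if (ncol(Xtr) > selectK) svmRankSelect(Xtr, ytr, k = selectK)
           else seq_len(ncol(Xtr))
    Xtr <- Xtr[, sel, drop = FALSE]
    Xte <- Xte[, sel, drop = FALSE]
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sd, "/")
    nClasses <- nlevels(ytr)
    if (is.null(hidden)) hidden <- ceiling((nClasses + ncol(Xtr)) / 2)
    set.seed(.subSeed(seed, 55L))
    fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = hidden,
                      softmax = nClasses > 1L, decay = decay, maxit = maxit,
                      MaxNWts = 100000L, trace = FALSE)
    pr <- stats::predict(fit, Xte)
    levels(ytr)[max.col(pr, ties.method = "first")]
}

#' Cross-validated MLP classification of a feature table
#'
#' Stratified k-fold cross-validation: within each fold, SVM-weight feature
#' selection to \code{selectK} features, per-feature standardisation and a
#' single-hidden-layer perceptron (hidden size = mean of class count and
#' post-selection attribute count) are fitted on the training rows only.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels (severity ratings or classes).
#' @param folds number of folds (default 10).
#' @param seed integer seed (folding and MLP initialisation).
#' @param selectK features kept by SVM ranking (64 by default).
#' @param hidden hidden-layer size override.
#' @param decay,maxit MLP weight decay and iteration cap.
#' @return an \linkS4class{EvalReport}.
#' @export
classifyCV <- function(X, y, folds = 10L, seed = 1L, selectK = 64L,
                       hidden = NULL, decay = 0.1, maxit = 200L) {
    X <- as.matrix(X)
    foldId <- stratifiedFolds(y, folds, seed)
    pred <- character(length(y))
    for (f in sort(unique(foldId))) {
        te <- foldId == f
        pred[te] <- .foldFit(X[!te, , drop = FALSE], y[!te],
                             X[te, , drop = FALSE], selectK = selectK,
                             hidden = hidden,
                             seed = .subSeed(seed, 200L + f),
                             decay = decay, maxit = maxit)
    }
    fm <- fMeasure(pred, y)
    new("EvalReport", perClass = fm$perClass, weightedF = fm$weightedF,
        macroF = fm$macroF, confusion = fm$confusion,
        folds = as.integer(foldId), seed = as.integer(seed),
        config = list(selectK = selectK, hidden = hidden, decay = decay,
                      maxit = maxit))
}

#' Cross-validated evaluation of a normal-field descriptor
#'
#' Computes a descriptor for every patch and runs [classifyCV()]. All
#' corpus-level fitting happens inside training folds only: the k-means
#' dictionaries of the rotation-fields and BTF-texton descriptors are
#' refitted per fold, and the LOP dot-product threshold (pattern function 1
#' without an explicit threshold) is the mean of the training patches'
#' global thresholds, so the absolute roughness signal is retained and
#' nothing leaks across the fold boundary. Descriptors without corpus
#' statistics (LOP with a fixed threshold or pattern function 2, APDI with
#' its fixed binning range) use per-patch features directly.
#'
#' @param patches list of \linkS4class{LabeledPatch} (or NormalMaps).
#' @param y labels, one per patch.
#' @param method "rotation_fields", "lop", "apdi" or "btf".
#' @param params named list of descriptor parameters overriding the
#'   defaults (see Details in the descriptor functions).
#' @param folds,seed,selectK as in [classifyCV()].
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateDescriptor <- function(patches, y,
                               method = c("rotation_fields", "lop", "apdi",
                                          "btf"),
                               params = list(), folds = 10L, seed = 1L,
                               selectK = 64L) {
    method <- match.arg(method)
    maps <- lapply(patches, function(p)
        if (is(p, "LabeledPatch")) patchNormalMap(p) else p)
    if (method == "lop") {
        prm <- utils::modifyList(list(nPoints = 8L, radius = 1,
                                      patternFn = 1L), params)
        cfg <- do.call(lopConfig, prm)
        nBins <- (if (cfg$patternFn == 1L) 2 else 4)^cfg$nPoints
        if (cfg$patternFn == 2L || !is.null(cfg$threshold)) {
            # no corpus-level fitting: per-patch features suffice
            X <- t(vapply(maps, function(N)
                as.numeric(lopDescriptor(N, cfg)), numeric(nBins)))
            return(classifyCV(X, y, folds = folds, seed = seed,
                              selectK = selectK))
        }
        # pattern function 1 with a derived threshold: the dot-product
        # threshold is a corpus statistic, fitted on training folds only
        # so severity information in the absolute dot level is retained
        perPatchTau <- vapply(maps, function(N) globalThreshold(N, cfg),
                              numeric(1))
        builder <- function(trainIdx, foldSeed) {
            cfgFold <- cfg
            cfgFold$threshold <- mean(perPatchTau[trainIdx])
            t(vapply(maps, function(N)
                as.numeric(lopDescriptor(N, cfgFold)), numeric(nBins)))
        }
    }
    else if (method == "apdi") {
        prm <- utils::modifyList(
            list(depth = 4L, bins = 64L, variant = "modified_arc",
                 meanMode = "local", window = 15L,
                 range = c(-pi / 2, pi / 2)), params)
        X <- t(vapply(maps, function(N) {
            P <- apdiPyramid(N, depth = prm$depth, variant = prm$variant,
                             meanMode = prm$meanMode, window = prm$window)
            as.numeric(apdiFeatures(P, bins = prm$bins, range = prm$range))
        }, numeric(prm$depth * prm$bins)))
        return(classifyCV(X, y, folds = folds, seed = seed,
                          selectK = selectK))
    }
    else if (method == "rotation_fields") {
        prm <- utils::modifyList(list(levels = 3L, k = 50L, r = 3L,
                                      window = c(3L, 3L),
                                      smoothMethod = "euclidean",
                                      maxFit = 10000L), params)
        vecs <- lapply(maps, function(N) {
            pyr <- rotationPyramid(N, levels = prm$levels, r = prm$r,
                                   method = prm$smoothMethod)
            lapply(pyr@fields, neighbourhoodVectors, window = prm$window)
        })
        builder <- function(trainIdx, foldSeed) {
            X <- matrix(0, length(maps), prm$levels * prm$k)
            for (l in seq_len(prm$levels)) {
                trv <- do.call(rbind, lapply(vecs[trainIdx], `[[`, l))
                ctr <- fitDictionary(trv, prm$k, seed = foldSeed + l,
                                     maxFit = prm$maxFit)
                for (i in seq_along(maps)) {
                    q <- quantiseHistogram(vecs[[i]][[l]], centers = ctr)
                    X[i, (l - 1L) * prm$k + seq_len(prm$k)] <- q$counts
                }
            }
            X
        }
    } else {  # btf
        prm <- utils::modifyList(list(k = 50L, views = 2L, lights = 7L,
                                      maxFit = 10000L), params)
        bank <- lmFilterBank()
        vecs <- lapply(patches, function(p) {
            stk <- makeBTFStack(p, views = prm$views, lights = prm$lights)
            stackResponses(stk, bank)
        })
        builder <- function(trainIdx, foldSeed) {
            trv <- do.call(rbind, vecs[trainIdx])
            ctr <- fitDictionary(trv, prm$k, seed = foldSeed,
                                 maxFit = prm$maxFit)
            t(vapply(vecs, function(v)
                as.numeric(quantiseHistogram(v, centers = ctr)$counts),
                numeric(prm$k)))
        }
    }
    foldId <- stratifiedFolds(y, folds, seed)
    pred <- character(length(y))
    for (f in sort(unique(foldId))) {
        te <- foldId == f
        X <- builder(which(!te), .subSeed(seed, 300L + f))
        pred[te] <- .foldFit(X[!te, , drop = FALSE], y[!te],
                             X[te, , drop = FALSE], selectK = selectK,
                             seed = .subSeed(seed, 400L + f))
    }
    fm <- fMeasure(pred, y)
    new("EvalReport", perClass = fm$perClass, weightedF = fm$weightedF,
        macroF = fm$macroF, confusion = fm$confusion,
        folds = as.integer(foldId), seed = as.integer(seed),
        config = list(method = method, params = params, selectK = selectK))
}
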