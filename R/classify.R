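#' Ward-linkage hierarchical clustering cut at a fixed cluster count
#'
#' Agglomerative clustering (Ward criterion on Euclidean distances, the
#' \code{ward.D2} linkage of [stats::hclust()]) halted at exactly
#' \code{nClusters} clusters — the dendrogram cutoff used to match the
#' number of phases in the ground-truth taxonomy.
#'
#' @param embedding samples-by-dimensions matrix.
#' @param nClusters number of clusters (1 to the number of samples).
#' @return Integer vector of cluster labels in 1..nClusters, with
#'   attributes \code{nClusters} and \code{linkage}.
#' @export
clusterHierarchical <- function(embedding, nClusters) {
    embedding <- as.matrix(embedding)
    if (nClusters < 1) stop("nClusters must be >= 1")
    if (nClusters > nrow(embedding))
        stop("nClusters cannot exceed the number of samples")
    labels <- cutree(hclust(dist(embedding), method = "ward.D2"),
                     k = nClusters)
    structure(as.integer(labels), nClusters = as.integer(nClusters),
              linkage = "ward")
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths)
# minimizing total cost of a square assignment. Rows -> columns; O(n^3).
hungarianAssign <- function(cost) {
    n <- nrow(cost)
    stopifnot(ncol(cost) == n)
    u <- numeric(n + 1); v <- numeric(n + 1)
    p <- integer(n + 1)  # p[j] = row assigned to column j (0 = none)
    way <- integer(n + 1)
    for (i in seq_len(n)) {
        p[1] <- i
        j0 <- 1L  # column index offset by 1 (1 = virtual column)
        minv <- rep(Inf, n + 1)
        used <- rep(FALSE, n + 1)
        repeat {
            used[j0] <- TRUE
            i0 <- p[j0]; delta <- Inf; j1 <- 0L
            for (j in seq_len(n) + 1L) {
                if (used[j]) next
                cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
                if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
                if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
            }
            for (j in seq_len(n + 1)) {
                if (used[j]) {
                    if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
                    v[j] <- v[j] - delta
                } else minv[j] <- minv[j] - delta
            }
            j0 <- j1
            if (p[j0] == 0L) break
        }
        repeat {
            j1 <- way[j0]
            p[j0] <- p[j1]
            j0 <- j1
            if (j0 == 1L) break
        }
    }
    assignment <- integer(n)
    for (j in seq_len(n) + 1L) if (p[j] > 0) assignment[p[j]] <- j - 1L
    assignment  # assignment[row] = column
}

#' Classification accuracy under optimal label assignment
#'
#' Fraction of samples on which the predicted clustering agrees with the
#' ground truth after mapping clusters to truth classes by the one-to-one
#' assignment that maximizes agreement (Hungarian algorithm on the
#' contingency table). Invariant to relabeling of either input.
#'
#' @param predicted,truth equal-length label vectors (any atomic type).
#' @return Accuracy in [0, 1].
#' @examples
#' accuracyVsTruth(c(2, 2, 1, 1), c("a", "a", "b", "b"))  # 1
#' @export
accuracyVsTruth <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        stop("predicted and truth must have equal length")
    tab <- table(factor(predicted), factor(truth))
    k <- max(dim(tab))
    counts <- matrix(0, k, k)
    counts[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    assign <- hungarianAssign(max(counts) - counts)
    matched <- sum(counts[cbind(seq_len(k), assign)])
    matched / length(truth)
}

#' Soft-margin SVM accuracy under stratified cross-validation
#'
#' Radial-basis-function support vector machine trained at each cost value
#' and scored by mean held-out accuracy over a stratified k-fold split; the
#' supervised cross-check for the unsupervised pipeline. Classes with fewer
#' samples than folds trigger a warning and have their samples spread
#' round-robin across folds.
#'
#' @param features samples-by-features matrix.
#' @param truth class labels.
#' @param costValues soft-margin cost values C to evaluate.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the fold split.
#' @return Named numeric vector: mean held-out accuracy per cost value.
#' @export
svmCrossvalAccuracy <- function(features, truth, costValues = c(0.1, 1, 10,
                                100), folds = 5, seed = NULL) {
    features <- as.matrix(features)
    truth <- factor(truth)
    stopifnot(nrow(features) == length(truth), nrow(features) >= folds)
    if (!is.null(seed)) set.seed(seed)
    if (any(table(truth) < folds))
        warning("some classes have fewer samples than folds; ",
                "their samples are spread round-robin")
    fold <- integer(length(truth))
    for (cl in levels(truth)) {
        idx <- sample(which(truth == cl))
        fold[idx] <- rep_len(sample(folds), length(idx))
    }
    acc <- vapply(costValues, function(C) {
        mean(vapply(seq_len(folds), function(f) {
            test <- which(fold == f)
            if (!length(test)) return(NA_real_)
            train <- which(fold != f)
            fit <- e1071::svm(features[train, , drop = FALSE],
                              droplevels(truth[train]), kernel = "radial",
                              cost = C, scale = FALSE)
            pred <- predict(fit, features[test, , drop = FALSE])
            mean(as.character(pred) == as.character(truth[test]))
        }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    stats::setNames(acc, paste0("C=", costValues))
}
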