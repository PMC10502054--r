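# shared helpers for building small populations and point sets in code

makePopulation <- function(pos, types = rep("blue", nrow(pos)),
                           pol = matrix(0, nrow(pos), 2),
                           clocks = rep(0, nrow(pos)),
                           offsets = rep(1L, nrow(pos)),
                           boxHalfwidth = 20) {
    new("CellPopulation", positions = pos, polarizations = pol,
        types = factor(types, levels = unique(c(types, "blue", "orange"))),
        divisionClocks = clocks, repolarizationOffsets = as.integer(offsets),
        stepIndex = 0, boxHalfwidth = boxHalfwidth)
}

popToDf <- function(pop) {
    data.frame(x = positions(pop)[, 1], y = positions(pop)[, 2],
               cell_type = as.character(cellTypes(pop)))
}

# exhaustive best one-to-one assignment accuracy (oracle, <= 6 clusters)
exhaustiveAccuracy <- function(predicted, truth) {
    tab <- table(factor(predicted), factor(truth))
    k <- max(dim(tab))
    counts <- matrix(0, k, k)
    counts[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
        out
    }
    best <- 0
    for (p in perms(seq_len(k)))
        best <- max(best, sum(counts[cbind(seq_len(k), p)]))
    best / length(truth)
}

# diagram intervals sorted for multiset comparison
sortedIntervals <- function(diag) {
    iv <- intervals(diag)
    iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
}
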