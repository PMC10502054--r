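#' Vietoris-Rips persistence diagrams of a labeled point cloud
#'
#' Computes dimension-0 (connected components) and dimension-1 (loops)
#' persistence of the Euclidean Vietoris-Rips filtration on the positions of
#' one cell-type channel, capped at \code{maxFiltration}. Dimension-0
#' features that never merge below the cap, and loops that are never filled
#' below it, are capped at \code{maxFiltration} by default (set
#' \code{infiniteConvention = "drop"} to discard them instead); under the
#' "cap" convention the H0 diagram has exactly one interval per point.
#'
#' @param points N x 2 coordinate matrix (or data.frame with x, y columns).
#' @param types optional per-cell type labels (required unless
#'   \code{channel = "both"}).
#' @param channel "both" for all cells, otherwise a type label to filter on.
#' @param maxDim highest homology dimension, 0 or 1.
#' @param maxFiltration Rips filtration cap (default 3, twice the
#'   interaction cutoff of the simulation model).
#' @param infiniteConvention "cap" (default) or "drop" for features alive at
#'   the cap.
#' @param method "reduction" for the compiled boundary-matrix path,
#'   "bruteforce" for the plain-R full-boundary-matrix reference path (small
#'   inputs only).
#' @return Named list of [PersistenceDiagram-class] objects ("H0", and "H1"
#'   when \code{maxDim >= 1}).
#' @examples
#' pts <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' computeDiagrams(pts)$H1  # one loop: (1, sqrt(2))
#' @export
computeDiagrams <- function(points, types = NULL, channel = "both",
                            maxDim = 1, maxFiltration = 3,
                            infiniteConvention = c("cap", "drop"),
                            method = c("reduction", "bruteforce")) {
    infiniteConvention <- match.arg(infiniteConvention)
    method <- match.arg(method)
    pts <- selectChannel(points, types, channel)
    mk <- function(iv, dim) new("PersistenceDiagram",
        intervals = iv, dimension = as.integer(dim), channel = channel,
        maxFiltration = maxFiltration)
    empty <- matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("start", "end")))
    if (nrow(pts) == 0) {
        warning("channel '", channel, "' contains no points; ",
                "returning empty diagrams")
        out <- list(H0 = mk(empty, 0))
        if (maxDim >= 1) out$H1 <- mk(empty, 1)
        return(out)
    }
    if (method == "bruteforce") {
        res <- ripsBruteForce(pts, maxFiltration)
    } else {
        raw <- .ripsPairsCpp(as.matrix(pts), maxFiltration, maxDim >= 1)
        res <- list(h0End = raw$h0_end, nInf0 = raw$n_inf0, h1 = raw$h1,
                    h1Capped = raw$h1_capped)
    }
    h0 <- cbind(start = numeric(length(res$h0End)), end = res$h0End)
    if (infiniteConvention == "cap" && res$nInf0 > 0)
        h0 <- rbind(h0, cbind(start = numeric(res$nInf0),
                              end = rep(maxFiltration, res$nInf0)))
    out <- list(H0 = mk(h0, 0))
    if (maxDim >= 1) {
        h1 <- res$h1
        colnames(h1) <- c("start", "end")
        if (infiniteConvention == "cap" && length(res$h1Capped) > 0)
            h1 <- rbind(h1, cbind(start = res$h1Capped,
                                  end = rep(maxFiltration,
                                            length(res$h1Capped))))
        h1 <- h1[h1[, 2] > h1[, 1], , drop = FALSE]
        out$H1 <- mk(h1, 1)
    }
    out
}

selectChannel <- function(points, types, channel, strict = TRUE) {
    if (is.data.frame(points)) {
        if (is.null(types) && "cell_type" %in% names(points))
            types <- points$cell_type
        points <- as.matrix(points[, c("x", "y")])
    }
    if (identical(channel, "both") || identical(channel, "all"))
        return(points)
    if (is.null(types))
        stop("types are required to filter on channel '", channel, "'")
    known <- channel %in% unique(as.character(types)) ||
        (is.factor(types) && channel %in% levels(types))
    if (!known && strict)
        stop("unknown channel '", channel, "'")
    points[as.character(types) == channel, , drop = FALSE]
}

# Plain-R reference path: full boundary-matrix reduction over GF(2) of the
# capped clique complex (vertices, edges, triangles), processed in a total
# order compatible with the filtration. Quadratic-cubic in the simplex
# count; intended for small instances and oracle checks.
ripsBruteForce <- function(pts, cap) {
    n <- nrow(pts)
    d <- as.matrix(dist(pts))
    edges <- which(upper.tri(d) & d <= cap, arr.ind = TRUE)
    ew <- d[edges]
    eord <- order(ew, edges[, 1], edges[, 2])
    edges <- edges[eord, , drop = FALSE]
    ew <- ew[eord]
    m <- nrow(edges)
    eid <- matrix(NA_integer_, n, n)
    for (e in seq_len(m)) {
        eid[edges[e, 1], edges[e, 2]] <- e
        eid[edges[e, 2], edges[e, 1]] <- e
    }
    tris <- list(); tw <- numeric(0)
    if (n >= 3) for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1))
        for (k in (j + 1):n) {
            if (!is.na(eid[i, j]) && !is.na(eid[i, k]) && !is.na(eid[j, k])) {
                tris[[length(tris) + 1L]] <-
                    sort(c(eid[i, j], eid[i, k], eid[j, k]))
                tw <- c(tw, max(d[i, j], d[i, k], d[j, k]))
            }
        }
    # simplex order: vertices (all at 0), then edges, then triangles sorted
    # by (weight, largest face id)
    if (length(tris)) {
        tord <- order(tw, vapply(tris, max, integer(1)))
        tris <- tris[tord]; tw <- tw[tord]
    }
    # reduce edge columns against vertex rows (union-find equivalent):
    # standard reduction of the full matrix, dense over GF(2)
    nSimp <- n + m + length(tris)
    dims <- c(rep(0L, n), rep(1L, m), rep(2L, length(tris)))
    wts <- c(rep(0, n), ew, tw)
    cols <- rep(list(integer(0)), nSimp)
    for (e in seq_len(m)) cols[[n + e]] <- as.integer(edges[e, ])  # vertices
    for (t in seq_along(tris)) cols[[n + m + t]] <- n + tris[[t]]  # edge rows
    pivot <- rep(NA_integer_, nSimp)
    pairs <- matrix(numeric(0), 0, 3)  # dim, start, end
    for (j in seq_len(nSimp)) {
        col <- cols[[j]]
        while (length(col)) {
            low <- max(col)
            if (is.na(pivot[low])) break
            other <- cols[[pivot[low]]]
            col <- as.integer(sort(c(setdiff(col, other),
                                     setdiff(other, col))))
        }
        cols[[j]] <- col
        if (length(col)) {
            low <- max(col)
            pivot[low] <- j
            pairs <- rbind(pairs, c(dims[low], wts[low], wts[j]))
        }
    }
    paired <- !is.na(pivot)
    isDeath <- vapply(seq_len(nSimp), function(j) length(cols[[j]]) > 0,
                      logical(1))
    essential <- which(!paired & !isDeath)
    h0 <- pairs[pairs[, 1] == 0 & pairs[, 3] > pairs[, 2], 3]
    h1 <- pairs[pairs[, 1] == 1 & pairs[, 3] > pairs[, 2], 2:3, drop = FALSE]
    list(h0End = h0, nInf0 = sum(dims[essential] == 0),
         h1 = matrix(h1, ncol = 2), h1Capped = wts[essential[dims[essential]
                                                             == 1]])
}

pixelCenters <- function(gridMin, gridMax, resolution) {
    gridMin + (seq_len(resolution) - 0.5) * (gridMax - gridMin) / resolution
}

#' Persistence image of a diagram
#'
#' Sum of lifespan-weighted Gaussians over the diagram. For dimension 0 the
#' image is a 1-D intensity profile: every interval start is identically 0,
#' so centering mass at the start would collapse the image to one location;
#' Gaussians are therefore centered at the interval end (the merge scale)
#' and weighted by (end - start). For dimension 1 the diagram is transformed
#' to (start, persistence) coordinates and each interval contributes an
#' isotropic 2-D Gaussian centered at (start, end - start), weighted by
#' (end - start), on a square pixel grid.
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param sigma Gaussian bandwidth in filtration units (default 0.1).
#' @param gridMin,gridMax image domain bounds in filtration units.
#' @param resolution pixel count (per axis for 2-D images); default 100 for
#'   dimension 0, 20 for dimension 1.
#' @return A [PersistenceImage-class]; intensities are additive over diagram
#'   union and always nonnegative.
#' @export
persistenceImage <- function(diagram, sigma = 0.1, gridMin = 0, gridMax = 3,
                             resolution = NULL) {
    stopifnot(is(diagram, "PersistenceDiagram"), sigma > 0,
              gridMax > gridMin)
    iv <- diagram@intervals
    if (diagram@dimension == 0L) {
        if (is.null(resolution)) resolution <- 100
        x <- pixelCenters(gridMin, gridMax, resolution)
        vals <- numeric(resolution)
        if (nrow(iv) > 0) {
            w <- iv[, 2] - iv[, 1]
            for (k in seq_len(nrow(iv)))
                vals <- vals + w[k] * dnorm(x, mean = iv[k, 2], sd = sigma)
        }
        new("PersistenceImage", values = vals, dimension = 0L, xAxis = x,
            yAxis = numeric(0), sigma = sigma, normalized = FALSE)
    } else {
        if (is.null(resolution)) resolution <- 20
        x <- pixelCenters(gridMin, gridMax, resolution)
        y <- x
        vals <- matrix(0, resolution, resolution)
        if (nrow(iv) > 0) {
            w <- iv[, 2] - iv[, 1]
            for (k in seq_len(nrow(iv)))
                vals <- vals + w[k] *
                    (dnorm(x, mean = iv[k, 1], sd = sigma) %o%
                     dnorm(y, mean = w[k], sd = sigma))
        }
        new("PersistenceImage", values = vals, dimension = 1L, xAxis = x,
            yAxis = y, sigma = sigma, normalized = FALSE)
    }
}

#' Scale a persistence image to unit maximum intensity
#'
#' Divides every pixel by the maximum intensity so images of point clouds of
#' different size become comparable; an all-zero image is returned
#' unchanged. Idempotent.
#'
#' @param image a [PersistenceImage-class].
#' @return The normalized [PersistenceImage-class].
#' @export
normalizeImage <- function(image) {
    stopifnot(is(image, "PersistenceImage"))
    m <- max(image@values)
    if (m > 0) image@values <- image@values / m
    image@normalized <- TRUE
    image
}

#' Persistence curve of a diagram
#'
#' At each diagonal parameter t, the intervals with start <= t <= end (the
#' \eqn{[0,t] \times [t,\infty)} region) are summarized: "betti" counts
#' them, "life" sums their lifespans (end - start), "gaussian" sums
#' lifespan-weighted Gaussian densities of fixed bandwidth centered at each
#' interval's midpoint.
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param variant "betti", "life" or "gaussian".
#' @param tGrid sorted ascending grid of diagonal parameter values.
#' @param bandwidth Gaussian bandwidth; required for the gaussian variant.
#' @return A [PersistenceCurve-class].
#' @export
persistenceCurve <- function(diagram, variant = c("betti", "life",
                             "gaussian"), tGrid = seq(0, 3, length.out =
                             100), bandwidth = NULL) {
    variant <- match.arg(variant)
    stopifnot(is(diagram, "PersistenceDiagram"), !is.unsorted(tGrid))
    if (variant == "gaussian" && is.null(bandwidth))
        stop("the gaussian variant requires a bandwidth")
    iv <- diagram@intervals
    vals <- vapply(tGrid, function(t) {
        inR <- iv[, 1] <= t & iv[, 2] >= t
        if (!any(inR)) return(0)
        s <- iv[inR, 1]; e <- iv[inR, 2]
        switch(variant,
            betti = sum(inR),
            life = sum(e - s),
            gaussian = sum((e - s) * dnorm(t, mean = (s + e) / 2,
                                           sd = bandwidth)))
    }, numeric(1))
    new("PersistenceCurve", t = tGrid, values = vals, variant = variant,
        bandwidth = if (is.null(bandwidth)) NA_real_ else bandwidth)
}

#' Fixed-length topological feature vector of one labeled point cloud
#'
#' For each requested (channel, homology dimension) block, computes the Rips
#' diagram of that channel and vectorizes it (persistence image pixels or
#' persistence curve values), then concatenates the blocks in the order
#' given: channels in the order requested, dimensions ascending within each
#' channel. The block layout is attached as the "provenance" attribute so
#' feature vectors are only comparable when their provenance agrees.
#'
#' @param points N x 2 coordinates (or data.frame with x, y, cell_type).
#' @param types per-cell type labels (optional for channel "both").
#' @param channels subset of "both" and the type labels.
#' @param dims subset of c(0, 1).
#' @param featurization "images" or "curves".
#' @param normalize divide each persistence image by its maximum intensity
#'   before concatenation.
#' @param maxFiltration,sigma,gridMin,gridMax passed through to the diagram
#'   and image stages.
#' @param resolution1d,resolution2d pixel counts for H0 / H1 images.
#' @param curveVariant,curveBandwidth,tGrid persistence-curve settings.
#' @return Numeric feature vector with a "provenance" attribute
#'   (data.frame: channel, dim, kind, length).
#' @export
buildFeatureVector <- function(points, types = NULL, channels = "both",
        dims = c(0, 1), featurization = c("images", "curves"),
        normalize = FALSE, maxFiltration = 3, sigma = 0.1, gridMin = 0,
        gridMax = 3, resolution1d = 100, resolution2d = 20,
        curveVariant = "betti", curveBandwidth = 0.1,
        tGrid = seq(0, 3, length.out = 100)) {
    featurization <- match.arg(featurization)
    if (!length(channels)) stop("channels must be nonempty")
    blocks <- list()
    prov <- NULL
    for (ch in channels) {
        dg <- computeDiagrams(points, types, channel = ch,
                              maxDim = max(dims),
                              maxFiltration = maxFiltration)
        for (d in sort(dims)) {
            diag <- dg[[paste0("H", d)]]
            v <- if (featurization == "images") {
                img <- persistenceImage(diag, sigma = sigma,
                    gridMin = gridMin, gridMax = gridMax,
                    resolution = if (d == 0) resolution1d else resolution2d)
                if (normalize) img <- normalizeImage(img)
                as.numeric(img@values)
            } else {
                persistenceCurve(diag, variant = curveVariant,
                    tGrid = tGrid, bandwidth = curveBandwidth)@values
            }
            blocks[[length(blocks) + 1L]] <- v
            prov <- rbind(prov, data.frame(channel = ch, dim = d,
                kind = featurization, length = length(v)))
        }
    }
    out <- unlist(blocks, use.names = FALSE)
    attr(out, "provenance") <- prov
    out
}
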