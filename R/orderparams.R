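#' Radial order parameters: pair-correlation function g(r)
#'
#' Density-normalized pair-correlation histogram between a source and a
#' target cell-type channel. Counts of target cells at distance r from each
#' source cell are divided by the source count, the target number density
#' and the annulus area of each bin, so a large uniform pattern gives
#' g(r) close to 1 in every bin and the statistic is invariant to population
#' size at fixed density.
#'
#' @param points N x 2 coordinates (or data.frame with x, y, cell_type).
#' @param types per-cell labels (optional when both channels are "all").
#' @param sourceChannel,targetChannel "all" or a type label.
#' @param breaks radial bin edges, strictly increasing (default 30 bins over
#'   [0, 5]).
#' @param area domain area used for the density; defaults to the bounding
#'   box of all points (pass the true box area when known).
#' @param periodicHalfwidth when the points live in a periodic box, its
#'   halfwidth; distances then use the minimum image and the area defaults
#'   to the box area, removing boundary bias.
#' @return Numeric vector of g(r) per bin (named by bin midpoint). Fewer
#'   than 2 points in the source channel gives a zero vector with a warning.
#' @export
radialOrderFeatures <- function(points, types = NULL, sourceChannel = "all",
                                targetChannel = sourceChannel,
                                breaks = seq(0, 5, length.out = 31),
                                area = NULL, periodicHalfwidth = NULL) {
    stopifnot(all(diff(breaks) > 0))
    allPts <- selectChannel(points, types, "all")
    src <- selectChannel(points, types, sourceChannel, strict = FALSE)
    tgt <- selectChannel(points, types, targetChannel, strict = FALSE)
    mids <- (head(breaks, -1) + breaks[-1]) / 2
    zero <- stats::setNames(numeric(length(mids)), signif(mids, 4))
    if (nrow(src) < 2 || nrow(tgt) < 1) {
        warning("too few points in channel; returning zero vector")
        return(zero)
    }
    if (is.null(area)) {
        if (!is.null(periodicHalfwidth)) area <- (2 * periodicHalfwidth)^2
        else {
            rng <- apply(allPts, 2, range)
            area <- prod(rng[2, ] - rng[1, ])
        }
    }
    same <- identical(sourceChannel, targetChannel)
    dx <- outer(src[, 1], tgt[, 1], "-")
    dy <- outer(src[, 2], tgt[, 2], "-")
    if (!is.null(periodicHalfwidth)) {
        L <- 2 * periodicHalfwidth
        dx <- dx - L * round(dx / L)
        dy <- dy - L * round(dy / L)
    }
    d <- sqrt(dx^2 + dy^2)
    if (same) diag(d) <- NA
    counts <- graphics::hist(d[!is.na(d) & d >= breaks[1] &
                               d < breaks[length(breaks)]],
                             breaks = breaks, plot = FALSE)$counts
    rho <- nrow(tgt) / area
    annulus <- pi * (breaks[-1]^2 - head(breaks, -1)^2)
    g <- counts / (nrow(src) * rho * annulus)
    stats::setNames(g, signif(mids, 4))
}

#' Angular order parameters: hexatic bond-orientational order
#'
#' Per-cell hexatic statistic
#' \eqn{\psi_6(i) = |k^{-1} \sum_j \exp(6 i \theta_{ij})|} over the k
#' nearest neighbours of each cell in the channel; a perfect triangular
#' lattice gives 1, isotropic neighbourhoods give values near
#' \eqn{k^{-1/2}}. Features are the mean of \eqn{\psi_6} followed by its
#' histogram over cells (fractions per bin).
#'
#' @param points N x 2 coordinates (or data.frame with x, y, cell_type).
#' @param types per-cell labels.
#' @param channel "all" or a type label.
#' @param k number of nearest neighbours (default 6; must be >= 3).
#' @param histBreaks histogram bin edges over [0, 1].
#' @return Numeric vector c(mean, histogram fractions); a zero vector with a
#'   warning when fewer than k + 1 points are available.
#' @export
angularOrderFeatures <- function(points, types = NULL, channel = "all",
                                 k = 6,
                                 histBreaks = seq(0, 1, length.out = 11)) {
    stopifnot(k >= 3)
    pts <- selectChannel(points, types, channel, strict = FALSE)
    nb <- length(histBreaks) - 1
    zero <- stats::setNames(numeric(nb + 1),
                            c("mean_psi6", paste0("psi6_bin", seq_len(nb))))
    if (nrow(pts) < k + 1) {
        warning("need at least k + 1 points; returning zero vector")
        return(zero)
    }
    psi <- psi6(pts, k)
    h <- graphics::hist(pmin(psi, 1), breaks = histBreaks,
                        plot = FALSE)$counts
    stats::setNames(c(mean(psi), h / length(psi)), names(zero))
}

#' Per-cell hexatic order
#'
#' @param pts N x 2 coordinate matrix.
#' @param k neighbours per cell.
#' @return Numeric vector of \eqn{\psi_6} values in [0, 1].
#' @export
psi6 <- function(pts, k = 6) {
    n <- nrow(pts)
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    vapply(seq_len(n), function(i) {
        nn <- order(d[i, ])[seq_len(k)]
        th <- atan2(pts[nn, 2] - pts[i, 2], pts[nn, 1] - pts[i, 1])
        Mod(mean(exp(6i * th)))
    }, numeric(1))
}
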