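#' Pattern phase taxonomy
#'
#' Closed label vocabularies for the two sweep scenarios: at constant
#' population size the 12 phases i-xii (dispersed and one-type-clustered
#' states through sorted, intermixed, striped, hexagonal-spot, core-shell
#' and labyrinth organizations); with proliferation the 10 phases v-vii and
#' ix-xv (dispersed states never occur because cells fill space, and two
#' partially sorted phases and a stripes+spots mix appear instead).
#'
#' @param proliferation logical scenario switch.
#' @return Character vector of phase codes, in taxonomy order.
#' @export
taxonomyLabels <- function(proliferation = FALSE) {
    if (proliferation)
        c("v", "vi", "vii", "ix", "x", "xi", "xii", "xiii", "xiv", "xv")
    else
        c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x",
          "xi", "xii")
}

#' Phase descriptions
#' @return Named character vector mapping phase codes to short descriptions.
#' @export
phaseDescriptions <- function() {
    c(i = "both types individually dispersed",
      ii = "blue clusters, orange dispersed",
      iii = "orange clusters, blue dispersed",
      iv = "separately sorted blue and orange clusters",
      v = "intermixed clusters",
      vi = "alternating stripes 1-2 cells thick",
      vii = "orange hexagonal spots in a sparse blue sea / blue interior",
      viii = "blue hexagonal spots surrounded by orange",
      ix = "orange core with blue shell",
      x = "packed orange spots in packed blue",
      xi = "orange hexagonal spots in tightly packed blue",
      xii = "labyrinth / finger-like",
      xiii = "mixed stripes and spots",
      xiv = "partially sorted, blue-rich",
      xv = "partially sorted, orange-rich")
}

rulesCache <- new.env(parent = emptyenv())

#' Load the adhesion-regime rule table
#'
#' The rule table transcribing the adhesion-parameter thresholds that
#' delimit each phase regime. It is shipped as an editable JSON data file:
#' an ordered list of predicates over (J_BB, J_OO, J_BO and their pairwise
#' differences), first match wins, with a catch-all per taxonomy so every
#' parameter triple receives exactly one label.
#'
#' @param file path to a rule JSON file; default the packaged table.
#' @return List of rule records (used by [regimeLabel()]).
#' @export
regimeRules <- function(file = NULL) {
    if (is.null(file)) {
        file <- system.file("extdata", "regime_rules.json",
                            package = "TopoCellSort")
        key <- "default"
        if (!is.null(rulesCache[[key]])) return(rulesCache[[key]])
        rules <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
        rulesCache[[key]] <- rules
        return(rules)
    }
    jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
}

ruleMatches <- function(rule, JBB, JOO, JBO) {
    vals <- list(jbb = JBB, joo = JOO, jbo = JBO,
                 jbb_minus_joo = JBB - JOO, jbb_minus_jbo = JBB - JBO,
                 joo_minus_jbo = JOO - JBO,
                 abs_jbb_minus_joo = abs(JBB - JOO),
                 abs_joo_minus_jbo = abs(JOO - JBO),
                 abs_jbb_minus_jbo = abs(JBB - JBO))
    for (key in names(rule$when)) {
        if (!key %in% names(vals)) stop("unknown rule predicate: ", key)
        bounds <- rule$when[[key]]  # [lo, hi): lo inclusive, hi exclusive
        x <- vals[[key]]
        lo <- bounds[[1]]; hi <- bounds[[2]]
        if (!is.null(lo) && !is.na(lo) && x < lo) return(FALSE)
        if (!is.null(hi) && !is.na(hi) && x >= hi) return(FALSE)
    }
    TRUE
}

#' Phase label of an adhesion-parameter triple
#'
#' Deterministic ground-truth surrogate: looks the parameter triple up in
#' the ordered regime rule table for the appropriate scenario. Rules are
#' total, so every triple receives exactly one label from the scenario's
#' taxonomy.
#'
#' @param JBB,JOO,JBO nonnegative adhesion magnitudes (vectorized).
#' @param proliferation scenario switch selecting the taxonomy.
#' @param rules optionally, a rule table from [regimeRules()].
#' @return Factor of phase codes with the taxonomy as levels.
#' @examples
#' regimeLabel(0.01, 0.01, 0)    # i: everything dispersed
#' regimeLabel(0.09, 0.09, 0)    # iv: separately sorted clusters
#' regimeLabel(0.13, 0.13, 0.05) # v: intermixed clusters
#' @export
regimeLabel <- function(JBB, JOO, JBO, proliferation = FALSE,
                        rules = regimeRules()) {
    stopifnot(all(JBB >= 0), all(JOO >= 0), all(JBO >= 0))
    scen <- if (proliferation) "proliferation" else "constant"
    active <- Filter(function(r) identical(r$taxonomy, scen), rules)
    n <- max(length(JBB), length(JOO), length(JBO))
    JBB <- rep_len(JBB, n); JOO <- rep_len(JOO, n); JBO <- rep_len(JBO, n)
    out <- character(n)
    for (i in seq_len(n)) {
        for (r in active) {
            if (ruleMatches(r, JBB[i], JOO[i], JBO[i])) {
                out[i] <- r$label
                break
            }
        }
        if (out[i] == "")
            stop("rule table is not total at (", JBB[i], ", ", JOO[i],
                 ", ", JBO[i], ")")
    }
    factor(out, levels = taxonomyLabels(proliferation))
}

#' Synthetic multicellular pattern fixtures
#'
#' Fast, deterministic generators for the canonical two-type pattern
#' classes, used to exercise the featurization and classification stages
#' without running long simulations. Geometry is exact at
#' \code{noiseScale = 0}: "sorted" is two disjoint monotype blobs,
#' "checkerboard" alternates types on a square lattice so every nearest
#' neighbour is of the opposite type, "stripes" alternates bands two rows
#' thick, "hex_spots" places minority-type cells on a triangular sublattice
#' of a majority-type triangular lattice, "core_shell" surrounds a minority
#' core with a majority annulus, and "labyrinth" carves serpentine bands
#' through a lattice.
#'
#' @param kind one of "dispersed", "sorted", "intermixed", "checkerboard",
#'   "stripes", "hex_spots", "core_shell", "labyrinth".
#' @param nCells approximate number of cells (>= 10; lattice-based kinds
#'   round to the nearest complete lattice).
#' @param fractions named type fractions (used by the blob-based kinds).
#' @param noiseScale standard deviation of positional jitter.
#' @param seed RNG seed.
#' @return data.frame with columns x, y, cell_type.
#' @examples
#' p <- generatePattern("stripes", nCells = 100, seed = 1)
#' @export
generatePattern <- function(kind = c("dispersed", "sorted", "intermixed",
        "checkerboard", "stripes", "hex_spots", "core_shell", "labyrinth"),
        nCells = 200, fractions = c(blue = 0.6, orange = 0.4),
        noiseScale = 0.05, seed = NULL) {
    kind <- match.arg(kind)
    stopifnot(nCells >= 10)
    if (!is.null(seed)) set.seed(seed)
    counts <- largestRemainderCounts(nCells, fractions)
    names(counts) <- names(fractions)
    out <- switch(kind,
        dispersed = {
            hw <- sqrt(nCells / 0.125) / 2  # uniform at dilute density
            data.frame(x = runif(nCells, -hw, hw),
                       y = runif(nCells, -hw, hw),
                       cell_type = sample(rep(names(counts), counts)))
        },
        sorted = {
            b1 <- sunflowerDisc(counts[1], spacing = 1)
            b2 <- sunflowerDisc(counts[2], spacing = 1)
            gap <- max(b1$r, b2$r) * 2 + 4
            data.frame(
                x = c(b1$x - gap / 2, b2$x + gap / 2),
                y = c(b1$y, b2$y),
                cell_type = rep(names(counts), counts))
        },
        intermixed = {
            b <- sunflowerDisc(nCells, spacing = 1)
            data.frame(x = b$x, y = b$y,
                       cell_type = sample(rep(names(counts), counts)))
        },
        checkerboard = {
            side <- round(sqrt(nCells))
            g <- expand.grid(i = seq_len(side), j = seq_len(side))
            data.frame(x = g$i, y = g$j,
                       cell_type = ifelse((g$i + g$j) %% 2 == 0,
                                          names(fractions)[1],
                                          names(fractions)[2]))
        },
        stripes = {
            side <- round(sqrt(nCells))
            g <- expand.grid(i = seq_len(side), j = seq_len(side))
            data.frame(x = g$i, y = g$j,
                       cell_type = ifelse((g$j - 1) %/% 2 %% 2 == 0,
                                          names(fractions)[1],
                                          names(fractions)[2]))
        },
        hex_spots = {
            g <- triangularLattice(ceiling(sqrt(nCells)), spacing = 1)
            minority <- g$row %% 3 == 0 & g$colIndex %% 3 == 0
            data.frame(x = g$x, y = g$y,
                       cell_type = ifelse(minority, names(fractions)[2],
                                          names(fractions)[1]))
        },
        core_shell = {
            core <- sunflowerDisc(counts[2], spacing = 1)
            nShell <- counts[1]
            rIn <- core$r + 1
            # fill an annulus ring by ring at unit spacing
            xs <- numeric(0); ys <- numeric(0)
            r <- rIn
            while (length(xs) < nShell) {
                m <- max(6, floor(2 * pi * r))
                th <- 2 * pi * seq_len(m) / m
                xs <- c(xs, r * cos(th)); ys <- c(ys, r * sin(th))
                r <- r + 1
            }
            data.frame(x = c(core$x, xs[seq_len(nShell)]),
                       y = c(core$y, ys[seq_len(nShell)]),
                       cell_type = rep(names(counts)[c(2, 1)],
                                       c(counts[2], counts[1])))
        },
        labyrinth = {
            side <- round(sqrt(nCells))
            g <- expand.grid(i = seq_len(side), j = seq_len(side))
            band <- sin(1.2 * g$j + 1.5 * sin(0.5 * g$i))
            data.frame(x = g$i, y = g$j,
                       cell_type = ifelse(band > 0, names(fractions)[1],
                                          names(fractions)[2]))
        })
    if (noiseScale > 0) {
        out$x <- out$x + rnorm(nrow(out), sd = noiseScale)
        out$y <- out$y + rnorm(nrow(out), sd = noiseScale)
    }
    out$cell_type <- factor(out$cell_type, levels = names(fractions))
    out
}

# Vogel spiral packing of n points in a disc at roughly unit spacing.
sunflowerDisc <- function(n, spacing = 1) {
    k <- seq_len(n)
    golden <- pi * (3 - sqrt(5))
    r <- spacing * sqrt(k) / sqrt(pi) * sqrt(pi) * 0.55
    list(x = r * cos(k * golden), y = r * sin(k * golden),
         r = max(r))
}

# rows x rows triangular lattice; returns axial indices for sublattice picks
triangularLattice <- function(rows, spacing = 1) {
    g <- expand.grid(colIndex = seq_len(rows) - 1, row = seq_len(rows) - 1)
    x <- spacing * (g$colIndex + g$row / 2)
    y <- spacing * sqrt(3) / 2 * g$row
    data.frame(x = x, y = y, row = g$row, colIndex = g$colIndex)
}
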