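#' Write cell positions to a delimited text file
#'
#' Plain-text table with header \code{x,y,cell_type}; coordinates are
#' serialized at full double precision so a write/read roundtrip is
#' lossless.
#'
#' @param population a [CellPopulation-class] or a data.frame with columns
#'   x, y, cell_type.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writePositions <- function(population, path) {
    df <- if (is(population, "CellPopulation"))
        data.frame(x = population@positions[, 1],
                   y = population@positions[, 2],
                   cell_type = as.character(population@types))
    else population
    lines <- c("x,y,cell_type",
               sprintf("%.17g,%.17g,%s", df$x, df$y,
                       as.character(df$cell_type)))
    writeLines(lines, path)
    invisible(path)
}

#' Read cell positions written by [writePositions()]
#'
#' Validates the header and coordinate fields; malformed input raises a
#' parse error naming the offending line.
#'
#' @param path input file path.
#' @return data.frame with columns x (numeric), y (numeric), cell_type
#'   (character); zero rows for a header-only file.
#' @export
readPositions <- function(path) {
    lines <- readLines(path)
    if (!length(lines) || !identical(trimws(lines[1]), "x,y,cell_type"))
        stop("parse error at line 1: expected header 'x,y,cell_type'")
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    if (!length(body))
        return(data.frame(x = numeric(0), y = numeric(0),
                          cell_type = character(0)))
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad))
        stop("parse error at line ", bad[1] + 1, ": expected 3 fields")
    x <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
    y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    bad <- which(is.na(x) | is.na(y))
    if (length(bad))
        stop("parse error at line ", bad[1] + 1,
             ": non-numeric coordinate")
    data.frame(x = x, y = y,
               cell_type = vapply(parts, `[`, "", 3))
}

snakeToCamel <- function(x) {
    gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names follow the serialized convention (\code{box_halfwidth},
#' \code{n_cells}, \code{type_fractions}, ...), mapped onto the
#' [simulationConfig()] arguments. Unknown fields raise an error.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return A [simulationConfig()].
#' @export
readSimulationConfig <- function(path) {
    raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::fromJSON(path)
    names(raw) <- snakeToCamel(names(raw))
    known <- names(formals(simulationConfig))
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        stop("unknown configuration fields: ",
             paste(unknown, collapse = ", "))
    if (!is.null(raw$typeFractions))
        raw$typeFractions <- unlist(raw$typeFractions)
    do.call(simulationConfig, raw)
}

#' Build a sweep manifest
#'
#' One row per (adhesion triple, replicate) with a deterministic per-row
#' seed derived from \code{baseSeed} and an output path.
#'
#' @param grid data.frame with columns J_BB, J_OO, J_BO (see
#'   [sweepGrid()]).
#' @param replicates replicate count per triple.
#' @param baseSeed integer; row seeds are
#'   \code{(baseSeed * 1000 + row) \%\% 2^31}.
#' @param outputDir directory prefix used in output paths.
#' @return data.frame: J_BB, J_OO, J_BO, replicate, seed, output_path.
#' @export
sweepManifest <- function(grid, replicates = 1, baseSeed = 1,
                          outputDir = "runs") {
    rows <- grid[rep(seq_len(nrow(grid)), each = replicates), ,
                 drop = FALSE]
    rows$replicate <- rep(seq_len(replicates), nrow(grid))
    rows$seed <- (as.numeric(baseSeed) * 1000 +
                  seq_len(nrow(rows))) %% 2^31
    rows$output_path <- file.path(outputDir,
        sprintf("%g_%g_%g", rows$J_BB, rows$J_OO, rows$J_BO),
        sprintf("rep%d", rows$replicate), "positions.csv")
    rownames(rows) <- NULL
    rows
}

#' Write persistence diagrams to a delimited text file
#'
#' One row per interval with columns \code{dimension,start,end,channel};
#' infinite ends are serialized as \code{inf}.
#'
#' @param diagrams a [PersistenceDiagram-class] or a list of them.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeDiagrams <- function(diagrams, path) {
    if (is(diagrams, "PersistenceDiagram")) diagrams <- list(diagrams)
    lines <- "dimension,start,end,channel"
    for (dg in diagrams) {
        iv <- dg@intervals
        if (!nrow(iv)) next
        ends <- ifelse(is.finite(iv[, 2]), sprintf("%.17g", iv[, 2]), "inf")
        lines <- c(lines, sprintf("%d,%.17g,%s,%s", dg@dimension,
                                  iv[, 1], ends, dg@channel))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read persistence diagrams written by [writeDiagrams()]
#'
#' @param path input file path.
#' @return List of [PersistenceDiagram-class], one per (channel, dimension)
#'   pair present, named \code{<channel>.H<dimension>}. The filtration cap
#'   is not stored in the file; it is restored as the largest finite end.
#' @export
readDiagrams <- function(path) {
    df <- read.csv(path, colClasses = "character")
    if (!identical(names(df), c("dimension", "start", "end", "channel")))
        stop("parse error: expected header 'dimension,start,end,channel'")
    df$dimension <- as.integer(df$dimension)
    df$start <- as.numeric(df$start)
    end <- ifelse(df$end == "inf", Inf, suppressWarnings(as.numeric(df$end)))
    if (anyNA(end)) stop("parse error: non-numeric end value")
    cap <- if (any(is.finite(end))) max(end[is.finite(end)]) else Inf
    out <- list()
    for (ch in unique(df$channel)) for (d in unique(df$dimension[
            df$channel == ch])) {
        sel <- df$channel == ch & df$dimension == d
        out[[paste0(ch, ".H", d)]] <- new("PersistenceDiagram",
            intervals = cbind(start = df$start[sel], end = end[sel]),
            dimension = as.integer(d), channel = ch, maxFiltration = cap)
    }
    out
}
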