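## Plain-text readers and writers: expression matrices as TSV (header
## row of sample identifiers, first column of gene identifiers),
## gold-standard networks as tab-separated edge lists
## (geneA<TAB>geneB<TAB>{0|1}), and deterministic edge-list/SIF output.

#' Read an expression matrix from TSV
#'
#' Expects a rectangular numeric TSV with a header row and an identifier
#' column; `orientation` states whether rows are genes (the usual
#' benchmark layout) or samples. Malformed input (ragged rows,
#' non-numeric or missing cells, duplicate identifiers) is reported with
#' line numbers.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path,
                           orientation = c("genes_in_rows",
                                           "samples_in_rows")) {
    orientation <- match.arg(orientation)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (length(unique(nf)) != 1L)
        stop("ragged rows at line(s) ",
             paste(which(nf != nf[1L]) , collapse = ", "))
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE, row.names = NULL)
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate identifiers at line(s) ",
             paste(which(duplicated(ids)) + 1L, collapse = ", "))
    num <- as.matrix(raw[, -1L, drop = FALSE])
    vals <- suppressWarnings(matrix(as.numeric(num), nrow(num), ncol(num)))
    bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop("non-numeric or missing value at line ", bad[1L, 1L] + 1L,
             ", column '", colnames(num)[bad[1L, 2L]], "'")
    dimnames(vals) <- list(ids, colnames(num))
    if (orientation == "samples_in_rows")
        vals <- t(vals)
    ExpressionMatrix(vals)
}

#' Write an expression matrix as TSV
#'
#' @param data an [ExpressionMatrix-class].
#' @param path output path.
#' @param digits significant digits for numeric output.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(data, path, digits = 6L) {
    v <- exprValues(data)
    df <- data.frame(gene = rownames(v),
                     signif(v, digits), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a gold-standard network
#'
#' Parses a tab-separated edge list with rows
#' `geneA<TAB>geneB<TAB>{0|1}`; pairs labelled 1 become skeleton edges
#' and unlisted pairs are negatives. Unknown genes, malformed rows, or a
#' pair listed twice with conflicting labels are errors (with line
#' numbers).
#'
#' @param path file path.
#' @param vertices character vector of all gene identifiers.
#' @return A [Skeleton-class].
#' @export
readGoldStandard <- function(path, vertices) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    seen <- new.env(parent = emptyenv())
    edges <- matrix(character(0), 0L, 2L)
    for (ln in seq_along(lines)) {
        f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
        if (length(f) != 3L || !(f[3L] %in% c("0", "1")))
            stop("malformed row at line ", ln)
        if (!all(f[1:2] %in% vertices))
            stop("unknown gene identifier at line ", ln)
        if (f[1L] == f[2L])
            stop("self-loop at line ", ln)
        i <- match(f[1L], vertices); j <- match(f[2L], vertices)
        key <- paste(min(i, j), max(i, j))
        prev <- seen[[key]]
        if (!is.null(prev) && prev != f[3L])
            stop("conflicting labels for pair at line ", ln)
        seen[[key]] <- f[3L]
        if (f[3L] == "1" && is.null(prev))
            edges <- rbind(edges, f[1:2])
    }
    Skeleton(vertices, edges)
}

#' Write a network as an edge list or SIF file
#'
#' Writes deterministic, lexicographically ordered output. The edge-list
#' format has columns `from`, `to`, `directed` (1 for a [Dag-class], 0
#' for a [Skeleton-class]); SIF uses the interaction type `regulates`
#' for directed and `adjacent` for undirected edges.
#'
#' @param graph a [Dag-class] or [Skeleton-class].
#' @param path output path.
#' @param format `"edgelist"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(graph, path, format = c("edgelist", "sif")) {
    format <- match.arg(format)
    e <- edgeMatrix(graph)
    directed <- is(graph, "Dag")
    if (nrow(e) > 0L)
        e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    if (format == "edgelist") {
        writeLines("from\tto\tdirected", con)
        if (nrow(e) > 0L)
            writeLines(paste(e[, 1L], e[, 2L], as.integer(directed),
                             sep = "\t"), con)
    } else {
        rel <- if (directed) "regulates" else "adjacent"
        if (nrow(e) > 0L)
            writeLines(paste(e[, 1L], rel, e[, 2L], sep = "\t"), con)
    }
    invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path edge-list file path.
#' @param vertices character vector of all gene identifiers.
#' @return A [Dag-class] or [Skeleton-class], according to the
#'   `directed` column.
#' @export
readNetwork <- function(path, vertices) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (!all(c("from", "to", "directed") %in% colnames(df)))
        stop("not an edge-list file")
    e <- as.matrix(df[, c("from", "to"), drop = FALSE])
    if (nrow(df) > 0L && all(df$directed == "1"))
        Dag(vertices, e)
    else
        Skeleton(vertices, e)
}
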