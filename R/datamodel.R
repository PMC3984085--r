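#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with genes in rows and samples in columns.
#' @param genes,samples optional identifier vectors overriding the
#'   dimnames of `values`; samples default to `S1..Sm` when absent.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("G", 1:3), NULL))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, genes = rownames(values),
                             samples = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(samples))
        samples <- paste0("S", seq_len(ncol(values)))
    if (is.null(genes))
        stop("gene identifiers are required")
    dimnames(values) <- list(as.character(genes), as.character(samples))
    storage.mode(values) <- "double"
    new("ExpressionMatrix", values = values)
}

#' Build an ExpressionMatrix from a SummarizedExperiment
#'
#' Takes the named assay (genes in rows) of a SummarizedExperiment as an
#' expression matrix.
#'
#' @param se a `SummarizedExperiment`.
#' @param assay assay name or index, default the first assay.
#' @return An [ExpressionMatrix-class].
#' @export
fromSummarizedExperiment <- function(se, assay = 1L) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
        stop("the SummarizedExperiment package is required for this coercion")
    ExpressionMatrix(SummarizedExperiment::assay(se, assay))
}

#' @describeIn ExpressionMatrix gene identifiers
#' @param x an object.
#' @name geneNames
#' @export
setMethod("geneNames", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn ExpressionMatrix sample identifiers
#' @name sampleNames
#' @export
setMethod("sampleNames", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn ExpressionMatrix number of genes
#' @name nGenes
#' @export
setMethod("nGenes", "ExpressionMatrix", function(x) nrow(x@values))

#' @describeIn ExpressionMatrix number of samples
#' @name nSamples
#' @export
setMethod("nSamples", "ExpressionMatrix", function(x) ncol(x@values))

#' @describeIn ExpressionMatrix the underlying genes x samples matrix
#' @name exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix:", nrow(object@values), "genes x",
        ncol(object@values), "samples\n")
    cat("genes:", paste(utils::head(rownames(object@values), 5L),
                        collapse = ", "),
        if (nrow(object@values) > 5L) "...\n" else "\n")
})

#' Construct a Skeleton
#'
#' Edges are canonicalised (lower-order endpoint first, rows sorted,
#' duplicates collapsed), so any listing of the same unordered pairs
#' yields an identical object.
#'
#' @param vertices character vector of gene identifiers.
#' @param edges two-column character matrix (or empty) of unordered pairs.
#' @return A [Skeleton-class] object.
#' @examples
#' Skeleton(c("A", "B", "C"), rbind(c("B", "A"), c("B", "C")))
#' @export
Skeleton <- function(vertices, edges = matrix(character(0), 0L, 2L)) {
    vertices <- as.character(vertices)
    edges <- .canonicalEdges(as.matrix(edges), vertices)
    new("Skeleton", vertices = vertices, edges = edges)
}

.canonicalEdges <- function(edges, vertices) {
    if (length(edges) == 0L)
        return(matrix(character(0), 0L, 2L))
    mode(edges) <- "character"
    i <- match(edges[, 1L], vertices)
    j <- match(edges[, 2L], vertices)
    if (anyNA(i) || anyNA(j))
        stop("edge endpoint not in vertex set")
    flip <- i > j
    edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
    ii <- pmin(i, j); jj <- pmax(i, j)
    keep <- !duplicated(paste(ii, jj))
    edges <- edges[keep, , drop = FALSE]
    ord <- order(ii[keep], jj[keep])
    unname(edges[ord, , drop = FALSE])
}

#' Complete skeleton over a vertex set
#'
#' @param vertices character vector of gene identifiers.
#' @return A [Skeleton-class] containing every unordered pair.
#' @export
completeSkeleton <- function(vertices) {
    n <- length(vertices)
    if (n < 2L)
        return(Skeleton(vertices))
    idx <- utils::combn(n, 2L)
    Skeleton(vertices, cbind(vertices[idx[1L, ]], vertices[idx[2L, ]]))
}

#' Construct a Dag
#'
#' @param vertices character vector of gene identifiers.
#' @param edges two-column character matrix of directed edges (from, to).
#' @return A [Dag-class] object; construction fails if the edges contain
#'   a directed cycle.
#' @examples
#' Dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
Dag <- function(vertices, edges = matrix(character(0), 0L, 2L)) {
    vertices <- as.character(vertices)
    edges <- as.matrix(edges)
    if (length(edges) == 0L) {
        edges <- matrix(character(0), 0L, 2L)
    } else {
        mode(edges) <- "character"
        i <- match(edges[, 1L], vertices)
        j <- match(edges[, 2L], vertices)
        if (anyNA(i) || anyNA(j))
            stop("edge endpoint not in vertex set")
        ord <- order(i, j)
        edges <- unname(edges[ord, , drop = FALSE])
    }
    colnames(edges) <- NULL
    new("Dag", vertices = vertices, edges = edges)
}

#' @describeIn Skeleton vertex identifiers
#' @param x an object.
#' @name vertexNames
#' @export
setMethod("vertexNames", "Skeleton", function(x) x@vertices)

#' @rdname vertexNames
#' @export
setMethod("vertexNames", "Dag", function(x) x@vertices)

#' @describeIn Skeleton two-column edge matrix
#' @name edgeMatrix
#' @export
setMethod("edgeMatrix", "Skeleton", function(x) x@edges)

#' @rdname edgeMatrix
#' @export
setMethod("edgeMatrix", "Dag", function(x) x@edges)

#' @describeIn Skeleton number of edges
#' @name edgeCount
#' @export
setMethod("edgeCount", "Skeleton", function(x) nrow(x@edges))

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "Dag", function(x) nrow(x@edges))

#' @describeIn Dag named list mapping each vertex to its parents
#' @name parentSets
#' @export
setMethod("parentSets", "Dag", function(x) {
    ps <- lapply(stats::setNames(x@vertices, x@vertices),
                 function(v) character(0))
    if (nrow(x@edges) > 0L) {
        sp <- split(x@edges[, 1L], factor(x@edges[, 2L], levels = x@vertices))
        ps[names(sp)] <- lapply(sp, as.character)
    }
    ps
})

#' @describeIn Dag the undirected skeleton underlying a DAG
#' @name skeleton
#' @export
setMethod("skeleton", "Dag", function(x) Skeleton(x@vertices, x@edges))

#' @rdname skeleton
#' @export
setMethod("skeleton", "Skeleton", function(x) x)

setMethod("show", "Skeleton", function(object) {
    cat("Skeleton:", length(object@vertices), "vertices,",
        nrow(object@edges), "undirected edges\n")
})

setMethod("show", "Dag", function(object) {
    cat("Dag:", length(object@vertices), "vertices,",
        nrow(object@edges), "directed edges\n")
})

#' Sample covariance model of an expression matrix
#'
#' Computes the gene-by-gene sample covariance matrix (unbiased n-1
#' denominator) that backs all Gaussian entropy, MI and CMI computations.
#'
#' @param data an [ExpressionMatrix-class].
#' @return A [CovarianceModel-class].
#' @examples
#' em <- ExpressionMatrix(matrix(rnorm(30), 3, 10,
#'     dimnames = list(paste0("G", 1:3), NULL)))
#' covarianceModel(em)
#' @export
covarianceModel <- function(data) {
    stopifnot(is(data, "ExpressionMatrix"))
    if (nSamples(data) < 2L)
        stop("insufficient samples")
    cv <- stats::cov(t(exprValues(data)))
    new("CovarianceModel", cov = cv, nSamples = nSamples(data))
}

#' @describeIn covarianceModel number of samples behind the model
#' @param x a CovarianceModel.
#' @export
setMethod("nSamples", "CovarianceModel", function(x) x@nSamples)

#' Covariance matrix accessor
#'
#' @param model a [CovarianceModel-class].
#' @return the symmetric gene x gene covariance matrix.
#' @export
covMatrix <- function(model) model@cov

setMethod("show", "CovarianceModel", function(object) {
    cat("CovarianceModel:", nrow(object@cov), "genes,",
        object@nSamples, "samples\n")
})

#' @describeIn DiscretizedMatrix integer level matrix
#' @param x an object.
#' @name levelMatrix
#' @export
setMethod("levelMatrix", "DiscretizedMatrix", function(x) x@levels)

#' @describeIn DiscretizedMatrix observed distinct levels per gene
#' @name levelCardinality
#' @export
setMethod("levelCardinality", "DiscretizedMatrix", function(x) x@cardinality)

#' @rdname geneNames
#' @export
setMethod("geneNames", "DiscretizedMatrix", function(x) rownames(x@levels))

#' @rdname nSamples
#' @export
setMethod("nSamples", "DiscretizedMatrix", function(x) ncol(x@levels))

setMethod("show", "DiscretizedMatrix", function(object) {
    cat("DiscretizedMatrix:", nrow(object@levels), "genes x",
        ncol(object@levels), "samples;",
        object@nominalLevels, "nominal levels\n")
})

#' Search configuration for hill climbing
#'
#' @param restarts number of random restarts (the default 50 matches the
#'   standard random-restart protocol for MIT-scored hill climbing).
#' @param maxIterations cap on accepted moves per climb; `NA` means
#'   `10 * n^2`.
#' @param seed integer base seed.
#' @param moveSet `"full"` or `"orient_only"`.
#' @return A [SearchConfig-class].
#' @export
SearchConfig <- function(restarts = 50L, maxIterations = NA_integer_,
                         seed = 1L, moveSet = c("full", "orient_only")) {
    moveSet <- match.arg(moveSet)
    new("SearchConfig", restarts = as.integer(restarts),
        maxIterations = as.integer(maxIterations),
        seed = as.integer(seed), moveSet = moveSet)
}
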