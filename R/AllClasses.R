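#' @import methods
NULL

#' ExpressionMatrix: continuous gene-by-sample expression data
#'
#' A genes x samples matrix of continuous, unitless expression levels with
#' unique gene identifiers as row names and sample identifiers as column
#' names. All downstream inference (covariance estimation, MI/CMI tests,
#' discretization) starts from this container.
#'
#' @slot values numeric matrix, genes in rows, samples in columns; no
#'   missing entries.
#'
#' @seealso [ExpressionMatrix()], [covarianceModel()], [discretizeExpression()]
#' @name ExpressionMatrix-class
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v)))
        return("expression values must be finite with no missing entries")
    if (nrow(v) < 2L)
        return("at least 2 genes are required")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("gene and sample identifiers are required as dimnames")
    if (anyDuplicated(rownames(v)))
        return("gene identifiers must be unique")
    TRUE
})

#' DiscretizedMatrix: integer-level expression data
#'
#' The result of equal-width or equal-frequency discretization: an integer
#' matrix of levels (same shape as the source [ExpressionMatrix]) together
#' with the per-gene number of distinct observed levels, used as the
#' variable cardinality by the MIT score.
#'
#' @slot levels integer matrix of levels, each in `[1, cardinality[gene]]`.
#' @slot cardinality named integer vector, observed distinct levels per gene.
#' @slot nominalLevels integer, the requested number of bins (lambda).
#'
#' @name DiscretizedMatrix-class
#' @aliases DiscretizedMatrix-class
#' @exportClass DiscretizedMatrix
setClass("DiscretizedMatrix",
    representation(levels = "matrix", cardinality = "integer",
                   nominalLevels = "integer"))

setValidity("DiscretizedMatrix", function(object) {
    lv <- object@levels
    if (!is.integer(lv))
        return("'levels' must be an integer matrix")
    if (is.null(rownames(lv)))
        return("gene identifiers are required as row names")
    if (length(object@cardinality) != nrow(lv))
        return("one cardinality per gene is required")
    if (!identical(names(object@cardinality), rownames(lv)))
        return("cardinality names must match gene identifiers")
    if (any(lv < 1L))
        return("levels must be >= 1")
    if (any(lv > object@nominalLevels))
        return("levels must not exceed the nominal level count")
    if (any(object@cardinality < 1L))
        return("cardinalities must be >= 1")
    TRUE
})

#' Skeleton: undirected graph over genes
#'
#' An undirected edge set over a fixed vertex set, representing the
#' skeleton of a regulatory network (edges without orientation). Edges are
#' stored canonically: within each row the endpoint earlier in the vertex
#' order comes first, and rows are sorted, so two skeletons over the same
#' vertices are identical iff their edge matrices are.
#'
#' @slot vertices character vector of gene identifiers.
#' @slot edges character matrix with two columns, one row per undirected
#'   edge; no self-loops, no duplicates.
#'
#' @seealso [Skeleton()], [completeSkeleton()], [skeleton()]
#' @name Skeleton-class
#' @aliases Skeleton-class
#' @exportClass Skeleton
setClass("Skeleton", representation(vertices = "character", edges = "matrix"))

setValidity("Skeleton", function(object) {
    e <- object@edges
    v <- object@vertices
    if (anyDuplicated(v))
        return("vertices must be unique")
    if (ncol(e) != 2L)
        return("'edges' must have two columns")
    if (nrow(e) > 0L) {
        if (!all(e %in% v))
            return("edges must reference known vertices")
        if (any(e[, 1L] == e[, 2L]))
            return("self-loops are not allowed")
        i <- match(e[, 1L], v); j <- match(e[, 2L], v)
        if (any(i > j))
            return("edges must be stored with the lower-order endpoint first")
        if (anyDuplicated(paste(e[, 1L], e[, 2L])))
            return("duplicate edges are not allowed")
    }
    TRUE
})

#' Dag: directed acyclic graph over genes
#'
#' A directed graph over a fixed vertex set, guaranteed acyclic by the
#' validity method (checked on every construction and mutation). Parent
#' sets are derived from the edge list via [parentSets()].
#'
#' @slot vertices character vector of gene identifiers.
#' @slot edges character matrix with columns `from`, `to`.
#'
#' @seealso [Dag()], [parentSets()], [skeleton()], [randomDag()]
#' @name Dag-class
#' @aliases Dag-class
#' @exportClass Dag
setClass("Dag", representation(vertices = "character", edges = "matrix"))

setValidity("Dag", function(object) {
    e <- object@edges
    v <- object@vertices
    if (anyDuplicated(v))
        return("vertices must be unique")
    if (ncol(e) != 2L)
        return("'edges' must have two columns (from, to)")
    if (nrow(e) > 0L) {
        if (!all(e %in% v))
            return("edges must reference known vertices")
        if (any(e[, 1L] == e[, 2L]))
            return("self-loops are not allowed")
        if (anyDuplicated(paste(e[, 1L], e[, 2L])))
            return("duplicate edges are not allowed")
    }
    g <- igraph::graph_from_data_frame(
        data.frame(from = e[, 1L], to = e[, 2L]),
        directed = TRUE, vertices = v)
    if (!igraph::is_dag(g))
        return("graph contains a directed cycle")
    TRUE
})

#' CovarianceModel: sample covariance of an expression matrix
#'
#' Gene-by-gene sample covariance matrix (unbiased, n-1 denominator)
#' backing the Gaussian entropy / MI / CMI closed forms. MI and CMI are
#' ratios of determinants, so the denominator convention cancels; it is
#' fixed here for reproducibility.
#'
#' @slot cov symmetric numeric matrix of sample covariances.
#' @slot nSamples integer, number of samples the covariances were
#'   estimated from.
#'
#' @seealso [covarianceModel()], [mutualInformation()]
#' @name CovarianceModel-class
#' @aliases CovarianceModel-class
#' @exportClass CovarianceModel
setClass("CovarianceModel",
    representation(cov = "matrix", nSamples = "integer"))

setValidity("CovarianceModel", function(object) {
    s <- object@cov
    if (!isSymmetric(unname(s), tol = 1e-8))
        return("covariance matrix must be symmetric")
    if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
        return("covariance matrix needs matching gene dimnames")
    if (object@nSamples < 2L)
        return("insufficient samples")
    TRUE
})

#' IndependenceDecision: outcome of a (conditional) independence test
#'
#' @slot statistic numeric, the MI or CMI value in nats.
#' @slot order integer, size of the conditioning set.
#' @slot independent logical decision.
#' @slot pValue numeric, the Fisher-z p-value in `pvalue` mode, `NA`
#'   in threshold mode.
#'
#' @seealso [independenceTest()]
#' @name IndependenceDecision-class
#' @aliases IndependenceDecision-class
#' @exportClass IndependenceDecision
setClass("IndependenceDecision",
    representation(statistic = "numeric", order = "integer",
                   independent = "logical", pValue = "numeric"))

setValidity("IndependenceDecision", function(object) {
    if (object@statistic < -1e-12)
        return("MI/CMI statistic must be nonnegative (up to tolerance)")
    if (object@order < 0L)
        return("conditioning order must be nonnegative")
    TRUE
})

#' ConfusionMetrics: skeleton evaluation against a gold standard
#'
#' Confusion counts over all unordered gene pairs, plus the derived
#' measures: accuracy (ACC), false positive rate (FPR), false discovery
#' rate (FDR), positive predictive value (PPV), F-score, Matthews
#' correlation coefficient (MCC) and true positive rate (TPR). Counts may
#' be fractional after averaging across runs.
#'
#' @slot tp,fp,tn,fn numeric counts.
#' @slot acc,fpr,fdr,ppv,f,mcc,tpr numeric derived measures.
#'
#' @seealso [confusion()], [confusionFromCounts()]
#' @name ConfusionMetrics-class
#' @aliases ConfusionMetrics-class
#' @exportClass ConfusionMetrics
setClass("ConfusionMetrics",
    representation(tp = "numeric", fp = "numeric", tn = "numeric",
                   fn = "numeric", acc = "numeric", fpr = "numeric",
                   fdr = "numeric", ppv = "numeric", f = "numeric",
                   mcc = "numeric", tpr = "numeric"))

setValidity("ConfusionMetrics", function(object) {
    cts <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(cts < 0))
        return("counts must be nonnegative")
    TRUE
})

#' SearchConfig: hill-climbing search settings
#'
#' @slot restarts integer, number of random restarts (default 50).
#' @slot maxIterations integer, safety cap on accepted moves per climb;
#'   `NA` means 10 * n^2 for n vertices.
#' @slot seed integer, base seed for restart initialisation.
#' @slot moveSet `"full"` (add/delete/reverse) or `"orient_only"`
#'   (reversals only, preserving the skeleton).
#'
#' @seealso [SearchConfig()], [restartedSearch()]
#' @name SearchConfig-class
#' @aliases SearchConfig-class
#' @exportClass SearchConfig
setClass("SearchConfig",
    representation(restarts = "integer", maxIterations = "integer",
                   seed = "integer", moveSet = "character"))

setValidity("SearchConfig", function(object) {
    if (object@restarts < 1L)
        return("at least one restart is required")
    if (!object@moveSet %in% c("full", "orient_only"))
        return("moveSet must be 'full' or 'orient_only'")
    TRUE
})
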