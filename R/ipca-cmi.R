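## IPCA-CMI: path-consistency pruning interleaved with MIT-scored
## hill-climbing orientation. After each pruning order the skeleton is
## re-oriented (reversal-only hill climbing from 50 random orientations),
## and the next order's conditioning candidates for an edge (X, Y) are
## the variables adjacent to X *or* Y in the oriented graph, filtered by
## a blocked-path weight against the median weight. The conditioning-set
## pool is thus intermediate between the full PC algorithm (all
## neighbours) and PCA-CMI (common neighbours only).

#' WeightTable: blocked-path weights around one edge
#'
#' For an edge (X, Y) of the current oriented graph, the candidate
#' conditioning variables (all Z adjacent to X or Y, excluding X and Y)
#' with their blocked-path weights `w(Z)`, the median threshold `k`, and
#' the selected set `K = {Z : w(Z) >= k}` from which conditioning subsets
#' are drawn.
#'
#' @slot centerPair character(2), the edge endpoints (X, Y).
#' @slot weights named integer vector of blocked-path counts.
#' @slot k numeric median threshold (mean of the two central values for
#'   an even candidate count).
#' @slot selected character vector, the selected set.
#'
#' @seealso [selectedSet()], [blockedPathWeight()]
#' @name WeightTable-class
#' @aliases WeightTable-class
#' @exportClass WeightTable
setClass("WeightTable",
    representation(centerPair = "character", weights = "integer",
                   k = "numeric", selected = "character"))

setValidity("WeightTable", function(object) {
    if (length(object@centerPair) != 2L)
        return("centerPair must name two genes")
    if (length(object@weights) && is.null(names(object@weights)))
        return("weights must be named by gene")
    if (!setequal(object@selected,
                  names(object@weights)[object@weights >= object@k]))
        return("selected set must be the genes with weight >= k")
    TRUE
})

setMethod("show", "WeightTable", function(object) {
    cat("WeightTable for edge", object@centerPair[1L], "--",
        object@centerPair[2L], "| k =", object@k, "\n")
    print(object@weights)
    cat("selected:", paste(object@selected, collapse = ", "), "\n")
})

## directed-edge lookup set for a Dag
.edgeKeys <- function(dag) {
    e <- edgeMatrix(dag)
    if (nrow(e) == 0L) character(0) else paste(e[, 1L], e[, 2L], sep = "\r")
}

## all simple undirected x--y paths in `dag` (vertex-name vectors of
## length >= 3, i.e. excluding the direct edge), up to lengthCap edges
.pathsBetween <- function(dag, x, y, lengthCap) {
    g <- igraph::graph_from_data_frame(
        data.frame(from = edgeMatrix(dag)[, 1L],
                   to = edgeMatrix(dag)[, 2L]),
        directed = FALSE, vertices = vertexNames(dag))
    p <- igraph::all_simple_paths(g, from = x, to = y, cutoff = lengthCap)
    p <- lapply(p, function(v) igraph::as_ids(v))
    p[vapply(p, function(v) length(v) >= 3L, logical(1))]
}

#' Blocked-path weight of a conditioning candidate
#'
#' Counts the simple undirected paths between `x` and `y` (up to
#' `lengthCap` edges, excluding the direct edge) in the current oriented
#' graph that are blocked by conditioning on `z` alone: paths on which
#' `z` appears as a chain or fork node. Paths on which `z` is a collider
#' are not blocked by conditioning on it and contribute nothing. A high
#' weight marks a variable through which much of the indirect x--y
#' connectivity flows -- a good separator candidate, in the spirit of
#' d-separation.
#'
#' @param z candidate gene; must be adjacent to `x` or `y` in the
#'   skeleton of `dag`.
#' @param x,y the edge endpoints.
#' @param dag the current oriented graph (a [Dag-class]).
#' @param lengthCap maximum path length in edges (default 4, bounding the
#'   enumeration on dense graphs).
#' @return integer path count.
#' @export
blockedPathWeight <- function(z, x, y, dag, lengthCap = 4L) {
    if (z %in% c(x, y))
        stop("z must differ from x and y")
    adj <- .skeletonAdjacency(dag)
    if (!(z %in% adj[[x]] || z %in% adj[[y]]))
        stop("z must be adjacent to x or y")
    keys <- .edgeKeys(dag)
    paths <- .pathsBetween(dag, x, y, lengthCap)
    w <- 0L
    for (p in paths) {
        pos <- match(z, p)
        if (is.na(pos) || pos == 1L || pos == length(p))
            next
        collider <- paste(p[pos - 1L], z, sep = "\r") %in% keys &&
                    paste(p[pos + 1L], z, sep = "\r") %in% keys
        if (!collider)
            w <- w + 1L
    }
    w
}

.skeletonAdjacency <- function(dag) {
    v <- vertexNames(dag)
    adj <- lapply(stats::setNames(v, v), function(.) character(0))
    e <- edgeMatrix(dag)
    for (r in seq_len(nrow(e))) {
        adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
        adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
    }
    adj
}

#' Selected conditioning set for an edge
#'
#' Builds the [WeightTable-class] for the edge (x, y): candidates are all
#' variables adjacent to x or y in the skeleton of the oriented graph
#' (excluding x and y); `k` is the median of their blocked-path weights
#' ([blockedPathWeight()], counting blocked indirect x--y paths); the
#' selected set keeps candidates with weight at least `k`. An empty
#' candidate pool yields an empty selected set.
#'
#' @inheritParams blockedPathWeight
#' @return A [WeightTable-class].
#' @export
selectedSet <- function(x, y, dag, lengthCap = 4L) {
    adj <- .skeletonAdjacency(dag)
    cand <- setdiff(union(adj[[x]], adj[[y]]), c(x, y))
    ## keep data/vertex order
    cand <- vertexNames(dag)[vertexNames(dag) %in% cand]
    if (length(cand) == 0L)
        return(new("WeightTable", centerPair = c(x, y),
                   weights = integer(0), k = 0, selected = character(0)))
    keys <- .edgeKeys(dag)
    paths <- .pathsBetween(dag, x, y, lengthCap)
    w <- stats::setNames(integer(length(cand)), cand)
    for (p in paths) {
        inner <- p[-c(1L, length(p))]
        for (z in intersect(inner, cand)) {
            pos <- match(z, p)
            collider <- paste(p[pos - 1L], z, sep = "\r") %in% keys &&
                        paste(p[pos + 1L], z, sep = "\r") %in% keys
            if (!collider)
                w[[z]] <- w[[z]] + 1L
        }
    }
    k <- stats::median(as.numeric(w))
    new("WeightTable", centerPair = c(x, y), weights = w, k = k,
        selected = names(w)[w >= k])
}

#' IPCA-CMI: hybrid network inference
#'
#' Order 0 prunes the complete graph by marginal MI against `theta`, then
#' orients the skeleton by reversal-only hill climbing under the MIT
#' score (from `config@restarts` random orientations), giving the
#' oriented graph D0. At each order `i >= 1`, every remaining edge
#' (X, Y) draws its conditioning candidates from the [selectedSet()] of
#' the previous oriented graph; if the selected set has at least `i`
#' members, the maximum order-i CMI over its i-subsets is compared with
#' `theta` and the edge is removed when smaller. After the sweep the
#' pruned skeleton is re-oriented. The algorithm stops at the first order
#' where no edge has a large enough selected set. CMI tests always use
#' the continuous data; discretization (`lam`, `discMethod`) feeds only
#' the MIT score.
#'
#' @param data an [ExpressionMatrix-class].
#' @param theta nonnegative MI/CMI threshold.
#' @param alphaScore chi-square significance level of the MIT penalty.
#' @param config a [SearchConfig-class]; the move set is forced to
#'   `orient_only` (the hill climber only reverses skeleton edges).
#' @param lam number of discretization levels for the MIT score.
#' @param discMethod `"ewd"` or `"efd"`.
#' @param lengthCap maximum blocked-path length (edges).
#' @param maxOrder optional cap on the conditioning order; `maxOrder = 0`
#'   stops after the order-0 prune and orientation.
#' @return list with `dag` (the final oriented graph, a [Dag-class]),
#'   `orderReached`, and `log` (per-order edge counts and best scores).
#' @examples
#' fix <- dreamShapeFixture(10)
#' res <- ipcaCMI(fix$data, theta = 0.05,
#'                config = SearchConfig(restarts = 5L, seed = 1L))
#' res$dag
#' @export
ipcaCMI <- function(data, theta = 0.05, alphaScore = 0.999,
                    config = SearchConfig(moveSet = "orient_only"),
                    lam = 10L, discMethod = c("ewd", "efd"),
                    lengthCap = 4L, maxOrder = NULL) {
    discMethod <- match.arg(discMethod)
    if (theta < 0)
        stop("theta must be nonnegative")
    config@moveSet <- "orient_only"
    model <- covarianceModel(data)
    g <- geneNames(data)
    n <- length(g)
    ddata <- discretizeExpression(data, discMethod, lam)
    cache <- newScoreCache()
    adj <- matrix(TRUE, n, n, dimnames = list(g, g))
    diag(adj) <- FALSE
    for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
        mi <- tryCatch(mutualInformation(g[a], g[b], model),
                       error = function(e) {
                           warning("degenerate covariance for edge ",
                                   g[a], "--", g[b], "; edge kept")
                           Inf
                       })
        if (mi < theta)
            adj[a, b] <- adj[b, a] <- FALSE
    }
    skelFromAdj <- function() {
        idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
        Skeleton(g, cbind(g[idx[, 1L]], g[idx[, 2L]]))
    }
    orient <- function(skel) restartedSearch(skel, ddata, alphaScore,
                                             config, cache = cache)
    res <- orient(skelFromAdj())
    dagPrev <- res$dag
    runLog <- data.frame(order = 0L, edges = edgeCount(dagPrev),
                         score = res$score)
    orderReached <- 0L
    i <- 1L
    repeat {
        if (!is.null(maxOrder) && i > maxOrder)
            break
        anyBig <- FALSE
        removed <- FALSE
        for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
            if (!adj[a, b])
                next
            wt <- selectedSet(g[a], g[b], dagPrev, lengthCap)
            K <- wt@selected
            if (length(K) < i)
                next
            anyBig <- TRUE
            mx <- .maxCMI(g[a], g[b], K, i, model)
            if (mx < theta) {
                adj[a, b] <- adj[b, a] <- FALSE
                removed <- TRUE
            }
        }
        if (!anyBig)
            break
        res <- orient(skelFromAdj())
        dagPrev <- res$dag
        runLog <- rbind(runLog,
                        data.frame(order = i, edges = edgeCount(dagPrev),
                                   score = res$score))
        orderReached <- i
        i <- i + 1L
    }
    list(dag = dagPrev, orderReached = orderReached, log = runLog)
}

#' Averaged IPCA-CMI evaluation over repeated runs
#'
#' The hill climber starts from random orientations, so the inferred
#' graph is a random variable; the standard protocol runs the whole
#' pipeline repeatedly and averages the confusion counts and derived
#' metrics arithmetically against a gold-standard skeleton. Run `r` uses
#' base seed `seed + r`.
#'
#' @param data an [ExpressionMatrix-class].
#' @param truth gold-standard [Skeleton-class] over the same genes.
#' @param nRuns number of runs to average (default 100).
#' @param seed integer base seed.
#' @param ... further arguments passed to [ipcaCMI()] (`theta`,
#'   `alphaScore`, `lam`, `discMethod`, `lengthCap`, `maxOrder`).
#' @param restarts random restarts per hill climb.
#' @return A [ConfusionMetrics-class] with arithmetically averaged slots.
#' @export
repeatedRuns <- function(data, truth, nRuns = 100L, seed = 0L,
                         restarts = 50L, ...) {
    if (nRuns < 1L)
        stop("nRuns must be at least 1")
    slots <- c("tp", "fp", "tn", "fn", "acc", "fpr", "fdr", "ppv", "f",
               "mcc", "tpr")
    acc <- stats::setNames(numeric(length(slots)), slots)
    for (r in seq_len(nRuns)) {
        cfg <- SearchConfig(restarts = restarts, seed = seed + r,
                            moveSet = "orient_only")
        res <- ipcaCMI(data, config = cfg, ...)
        cm <- confusion(skeleton(res$dag), truth)
        for (s in slots)
            acc[[s]] <- acc[[s]] + slot(cm, s)
    }
    acc <- acc / nRuns
    new("ConfusionMetrics", tp = acc[["tp"]], fp = acc[["fp"]],
        tn = acc[["tn"]], fn = acc[["fn"]], acc = acc[["acc"]],
        fpr = acc[["fpr"]], fdr = acc[["fdr"]], ppv = acc[["ppv"]],
        f = acc[["f"]], mcc = acc[["mcc"]], tpr = acc[["tpr"]])
}
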