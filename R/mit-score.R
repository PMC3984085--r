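## MIT score for discrete data: each node contributes 2N times its
## empirical mutual information with its parent set, penalised by
## chi-square quantiles whose degrees of freedom follow the canonical
## decreasing-cardinality parent permutation. The score is decomposable
## (sum of local scores) and not score-equivalent, which is what lets
## hill climbing distinguish X -> Y from Y -> X.

#' LocalScore: one node's contribution to the MIT score
#'
#' @slot node gene identifier.
#' @slot parents character vector of parent genes.
#' @slot value numeric, `miTerm - penaltyTerm` (0 for an orphan node).
#' @slot miTerm numeric, `2 * N * MI_D(node; parents)`.
#' @slot penaltyTerm numeric, sum of chi-square quantiles.
#'
#' @seealso [localMIT()]
#' @name LocalScore-class
#' @aliases LocalScore-class
#' @exportClass LocalScore
setClass("LocalScore",
    representation(node = "character", parents = "character",
                   value = "numeric", miTerm = "numeric",
                   penaltyTerm = "numeric"))

setValidity("LocalScore", function(object) {
    if (abs(object@value - (object@miTerm - object@penaltyTerm)) > 1e-9)
        return("value must equal miTerm - penaltyTerm")
    if (length(object@parents) == 0L && object@value != 0)
        return("an orphan node scores 0")
    TRUE
})

setMethod("show", "LocalScore", function(object) {
    cat("LocalScore", object@node, "| {",
        paste(object@parents, collapse = ", "), "}:",
        format(object@value), "\n")
})

#' Create a local-score cache
#'
#' An environment memoising local MIT scores by (node, parent-set) key;
#' pass it to [localMIT()], [totalMIT()], [deltaMove()] and the search
#' functions so repeated queries are bit-identical and computed once.
#'
#' @return an environment usable as a score cache.
#' @export
newScoreCache <- function() new.env(parent = emptyenv())

## joint parent configuration labels for a set of rows of the level matrix
.parentConfig <- function(lv, parents) {
    if (length(parents) == 1L)
        return(lv[parents, ])
    do.call(paste, c(lapply(parents, function(p) lv[p, ]), sep = "\r"))
}

.empiricalMI <- function(nodeIdx, parentIdx, lv) {
    if (length(parentIdx) == 0L)
        return(0)
    N <- ncol(lv)
    tab <- table(lv[nodeIdx, ], .parentConfig(lv, parentIdx))
    ni <- rowSums(tab)
    nj <- colSums(tab)
    idx <- which(tab > 0, arr.ind = TRUE)
    n <- tab[idx]
    sum(n / N * log(N * n / (ni[idx[, 1L]] * nj[idx[, 2L]])))
}

#' Empirical mutual information of a node with its parent set
#'
#' `MI_D(X; Pa) = (1/N) * sum_jk N_jk * ln(N * N_jk / (N_j * N_k))` over
#' the contingency table of the node's levels against joint parent
#' configurations, with `0 * ln(0) = 0`. An empty parent set gives 0.
#'
#' @param node gene identifier.
#' @param parents character vector of parent genes (possibly empty).
#' @param ddata a [DiscretizedMatrix-class].
#' @return empirical mutual information in nats (nonnegative).
#' @export
empiricalMI <- function(node, parents, ddata) {
    lv <- levelMatrix(ddata)
    .empiricalMI(match(node, rownames(lv)),
                 match(parents, rownames(lv)), lv)
}

.dofSequence <- function(nodeIdx, parentIdx, card) {
    ri <- card[nodeIdx]
    rp <- card[parentIdx]
    ## canonical permutation: decreasing cardinality, ties by gene order
    ord <- order(-rp, parentIdx)
    rp <- as.numeric(rp[ord])
    ## doubles: the cumulative products overflow 32-bit integers for
    ## high-degree nodes
    cumprev <- c(1, cumprod(rp))[seq_along(rp)]
    (ri - 1) * (rp - 1) * cumprev
}

#' Degrees-of-freedom sequence for the MIT penalty
#'
#' With parents ordered by decreasing level cardinality (ties broken by
#' gene order), the j-th penalty term has
#' `l_j = (r_node - 1) * (r_(j) - 1) * prod_{k < j} r_(k)` degrees of
#' freedom, where `r` denotes observed level cardinalities. The output is
#' invariant to the order in which parents are supplied.
#'
#' @inheritParams empiricalMI
#' @return numeric vector of integral degrees of freedom, one per parent
#'   (doubles, since the cumulative cardinality products can exceed the
#'   32-bit integer range).
#' @export
dofSequence <- function(node, parents, ddata) {
    if (length(parents) == 0L)
        stop("dofSequence requires a nonempty parent set")
    g <- geneNames(ddata)
    .dofSequence(match(node, g), match(parents, g),
                 unname(levelCardinality(ddata)))
}

.localMIT <- function(nodeIdx, parentIdx, lv, card, alphaScore, cache = NULL) {
    if (length(parentIdx) == 0L)
        return(0)
    parentIdx <- sort(parentIdx)
    if (!is.null(cache)) {
        key <- paste0(nodeIdx, "|", paste(parentIdx, collapse = ","))
        hit <- cache[[key]]
        if (!is.null(hit))
            return(hit)
    }
    miTerm <- 2 * ncol(lv) * .empiricalMI(nodeIdx, parentIdx, lv)
    dof <- .dofSequence(nodeIdx, parentIdx, card)
    penalty <- sum(stats::qchisq(alphaScore, df = dof))
    val <- miTerm - penalty
    if (!is.null(cache))
        cache[[key]] <- val
    val
}

#' Local MIT score of a node given its parents
#'
#' `2 * N * MI_D(node; parents) - sum_j qchisq(alphaScore, l_j)` with the
#' degrees of freedom of [dofSequence()]. An orphan node scores 0. A
#' parent with a single observed level contributes nothing (zero degrees
#' of freedom and no information).
#'
#' @inheritParams empiricalMI
#' @param alphaScore chi-square significance level in (0, 1); default
#'   0.999.
#' @param cache optional [newScoreCache()] environment.
#' @return A [LocalScore-class].
#' @export
localMIT <- function(node, parents, ddata, alphaScore = 0.999,
                     cache = NULL) {
    if (alphaScore <= 0 || alphaScore >= 1)
        stop("alphaScore must lie in (0, 1)")
    lv <- levelMatrix(ddata)
    card <- unname(levelCardinality(ddata))
    nodeIdx <- match(node, rownames(lv))
    parentIdx <- match(parents, rownames(lv))
    if (anyNA(c(nodeIdx, parentIdx)))
        stop("unknown gene identifier")
    if (length(parentIdx) == 0L)
        return(new("LocalScore", node = node, parents = character(0),
                   value = 0, miTerm = 0, penaltyTerm = 0))
    miTerm <- 2 * ncol(lv) * .empiricalMI(nodeIdx, parentIdx, lv)
    penalty <- sum(stats::qchisq(alphaScore,
                                 df = .dofSequence(nodeIdx, parentIdx, card)))
    val <- .localMIT(nodeIdx, parentIdx, lv, card, alphaScore, cache)
    new("LocalScore", node = node, parents = as.character(parents),
        value = val, miTerm = miTerm, penaltyTerm = penalty)
}

#' Total MIT score of a DAG
#'
#' The decomposable total: the sum over nodes of their local MIT scores.
#'
#' @param dag a [Dag-class] over the genes of `ddata`.
#' @param ddata a [DiscretizedMatrix-class].
#' @inheritParams localMIT
#' @return numeric total score.
#' @export
totalMIT <- function(dag, ddata, alphaScore = 0.999, cache = NULL) {
    if (alphaScore <= 0 || alphaScore >= 1)
        stop("alphaScore must lie in (0, 1)")
    lv <- levelMatrix(ddata)
    card <- unname(levelCardinality(ddata))
    ps <- parentSets(dag)
    g <- rownames(lv)
    tot <- 0
    for (v in names(ps))
        tot <- tot + .localMIT(match(v, g), match(ps[[v]], g),
                               lv, card, alphaScore, cache)
    tot
}

#' Score change of a single hill-climbing move
#'
#' Returns `score(dag after move) - score(dag before move)` touching only
#' the affected local scores: the child for an addition or deletion, both
#' endpoints for a reversal (which is a deletion of `x -> y` followed by
#' an addition of `y -> x`). Acyclicity of the resulting graph is the
#' caller's responsibility; edge existence is checked here.
#'
#' @param dag a [Dag-class].
#' @param move `"add"`, `"delete"` or `"reverse"`.
#' @param x,y gene identifiers; the move concerns the edge `x -> y`.
#' @inheritParams totalMIT
#' @return numeric score difference.
#' @export
deltaMove <- function(dag, move = c("add", "delete", "reverse"), x, y,
                      ddata, alphaScore = 0.999, cache = NULL) {
    move <- match.arg(move)
    lv <- levelMatrix(ddata)
    card <- unname(levelCardinality(ddata))
    g <- rownames(lv)
    ps <- parentSets(dag)
    xi <- match(x, g); yi <- match(y, g)
    if (is.na(xi) || is.na(yi) || xi == yi)
        stop("illegal move: bad endpoints")
    paY <- match(ps[[y]], g)
    paX <- match(ps[[x]], g)
    hasEdge <- xi %in% paY
    loc <- function(node, pa) .localMIT(node, pa, lv, card, alphaScore, cache)
    switch(move,
        add = {
            if (hasEdge) stop("illegal move: edge already present")
            loc(yi, c(paY, xi)) - loc(yi, paY)
        },
        delete = {
            if (!hasEdge) stop("illegal move: edge absent")
            loc(yi, setdiff(paY, xi)) - loc(yi, paY)
        },
        reverse = {
            if (!hasEdge) stop("illegal move: edge absent")
            (loc(yi, setdiff(paY, xi)) - loc(yi, paY)) +
                (loc(xi, c(paX, yi)) - loc(xi, paX))
        })
}
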