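## Greedy hill climbing over DAGs under the MIT score. Moves are edge
## additions, deletions and reversals (or reversals only, when the job is
## to orient a fixed skeleton); the greatest strictly improving move is
## taken, ties broken lexicographically by (move type, from, to) in gene
## order, and the climb stops when no legal move improves the score.
## Random restarts escape local optima. The inner loop keeps an integer
## parent/child-list representation with a DFS reachability check for
## acyclicity; igraph is used at the object boundary.

.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    force(expr)
}

## is `to` reachable from `from` following child pointers?
.reachable <- function(children, from, to) {
    if (from == to)
        return(TRUE)
    seen <- logical(length(children))
    stack <- from
    while (length(stack)) {
        v <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        for (w in children[[v]]) {
            if (w == to)
                return(TRUE)
            if (!seen[w]) {
                seen[w] <- TRUE
                stack <- c(stack, w)
            }
        }
    }
    FALSE
}

.childrenFromParents <- function(parents) {
    n <- length(parents)
    children <- rep(list(integer(0)), n)
    for (v in seq_len(n))
        for (p in parents[[v]])
            children[[p]] <- c(children[[p]], v)
    children
}

.dagToParents <- function(dag) {
    v <- vertexNames(dag)
    ps <- parentSets(dag)
    lapply(ps, function(p) match(p, v))
}

.parentsToDag <- function(parents, vertices) {
    from <- integer(0); to <- integer(0)
    for (v in seq_along(parents)) {
        from <- c(from, parents[[v]])
        to <- c(to, rep(v, length(parents[[v]])))
    }
    Dag(vertices, cbind(vertices[from], vertices[to]))
}

## core greedy climb on integer structures; returns list(parents, score)
.climb <- function(parents, lv, card, alphaScore, cache, moveSet,
                   maxIter) {
    n <- length(parents)
    children <- .childrenFromParents(parents)
    loc <- function(node, pa) .localMIT(node, pa, lv, card, alphaScore, cache)
    score <- 0
    for (v in seq_len(n))
        score <- score + loc(v, parents[[v]])
    tol <- 1e-12
    iter <- 0L
    repeat {
        iter <- iter + 1L
        if (iter > maxIter)
            break
        best <- tol
        bestMove <- NULL
        consider <- function(delta, type, x, y) {
            if (delta > best) {
                best <<- delta
                bestMove <<- list(type = type, x = x, y = y)
            }
        }
        ## lexicographic enumeration: add < delete < reverse, then (x, y)
        if (moveSet == "full") {
            for (x in seq_len(n)) for (y in seq_len(n)) {
                if (x == y || x %in% parents[[y]] || y %in% parents[[x]])
                    next
                if (.reachable(children, y, x))    # would close a cycle
                    next
                consider(loc(y, c(parents[[y]], x)) - loc(y, parents[[y]]),
                         "add", x, y)
            }
            for (x in seq_len(n)) for (y in seq_len(n)) {
                if (!(x %in% parents[[y]]))
                    next
                consider(loc(y, setdiff(parents[[y]], x)) -
                             loc(y, parents[[y]]),
                         "delete", x, y)
            }
        }
        for (x in seq_len(n)) for (y in seq_len(n)) {
            if (!(x %in% parents[[y]]))
                next
            ## reversal is legal iff no other directed path x ~> y
            children[[x]] <- setdiff(children[[x]], y)
            ok <- !.reachable(children, x, y)
            children[[x]] <- c(children[[x]], y)
            if (!ok)
                next
            delta <- (loc(y, setdiff(parents[[y]], x)) -
                          loc(y, parents[[y]])) +
                     (loc(x, c(parents[[x]], y)) - loc(x, parents[[x]]))
            consider(delta, "reverse", x, y)
        }
        if (is.null(bestMove))
            break
        x <- bestMove$x; y <- bestMove$y
        switch(bestMove$type,
            add = {
                parents[[y]] <- c(parents[[y]], x)
                children[[x]] <- c(children[[x]], y)
            },
            delete = {
                parents[[y]] <- setdiff(parents[[y]], x)
                children[[x]] <- setdiff(children[[x]], y)
            },
            reverse = {
                parents[[y]] <- setdiff(parents[[y]], x)
                children[[x]] <- setdiff(children[[x]], y)
                parents[[x]] <- c(parents[[x]], y)
                children[[y]] <- c(children[[y]], x)
            })
        score <- score + best
    }
    list(parents = parents, score = score)
}

#' Random DAG
#'
#' Draws a random DAG by sampling a random topological order and, for each
#' vertex, a uniform number of parents (up to `maxParents`) among its
#' predecessors. Acyclic by construction and deterministic per seed.
#'
#' @param vertices character vector of gene identifiers.
#' @param seed integer seed.
#' @param maxParents maximum in-degree.
#' @return A [Dag-class].
#' @export
randomDag <- function(vertices, seed, maxParents = 3L) {
    if (maxParents < 0L)
        stop("maxParents must be nonnegative")
    n <- length(vertices)
    .withSeed(seed, {
        perm <- sample.int(n)
        edges <- matrix(character(0), 0L, 2L)
        for (j in seq_len(n)[-1L]) {
            k <- sample.int(min(maxParents, j - 1L) + 1L, 1L) - 1L
            if (k > 0L) {
                pa <- perm[sample.int(j - 1L, k)]
                edges <- rbind(edges,
                               cbind(vertices[pa], vertices[perm[j]]))
            }
        }
        Dag(vertices, edges)
    })
}

#' Random acyclic orientation of a skeleton
#'
#' Orients every skeleton edge along a random vertex permutation, which
#' cannot create a cycle; the result's skeleton equals the input.
#'
#' @param skel a [Skeleton-class].
#' @param seed integer seed.
#' @return A [Dag-class].
#' @export
randomOrientation <- function(skel, seed) {
    v <- vertexNames(skel)
    e <- edgeMatrix(skel)
    .withSeed(seed, {
        pos <- sample.int(length(v))
        names(pos) <- v
        if (nrow(e) > 0L) {
            flip <- pos[e[, 1L]] > pos[e[, 2L]]
            e[flip, ] <- e[flip, c(2L, 1L), drop = FALSE]
        }
        Dag(v, e)
    })
}

#' Greedy hill climb from an initial DAG
#'
#' Repeatedly applies the single legal move (addition, deletion or
#' reversal; reversals only in `orient_only` mode) with the greatest
#' strictly positive score improvement until none exists. Ties are broken
#' lexicographically by (move type, from, to), making the climb
#' deterministic.
#'
#' @param initial a [Dag-class] starting point.
#' @param ddata a [DiscretizedMatrix-class].
#' @param alphaScore chi-square significance level of the MIT penalty.
#' @param config a [SearchConfig-class]; `moveSet` selects full moves or
#'   skeleton-preserving reversals.
#' @param cache optional [newScoreCache()].
#' @return list with elements `dag` (the local optimum) and `score`.
#' @export
hillClimb <- function(initial, ddata, alphaScore = 0.999,
                      config = SearchConfig(), cache = NULL) {
    v <- vertexNames(initial)
    lv <- levelMatrix(ddata)
    if (!identical(sort(v), sort(rownames(lv))))
        stop("DAG vertices must match the genes of the discretized data")
    ## index rows in the DAG's vertex order so integer node indices (and
    ## cache keys) are consistent across all climbs sharing a cache
    lv <- lv[v, , drop = FALSE]
    card <- unname(levelCardinality(ddata)[v])
    parents <- .dagToParents(initial)
    maxIter <- config@maxIterations
    if (is.na(maxIter))
        maxIter <- 10L * length(v)^2
    res <- .climb(parents, lv, card, alphaScore, cache, config@moveSet,
                  maxIter)
    list(dag = .parentsToDag(res$parents, v), score = res$score)
}

#' Hill climbing with random restarts
#'
#' Runs `config@restarts` independent climbs from random initial points
#' (random DAGs for the full move set; random acyclic orientations of
#' `skel` in `orient_only` mode) with restart seeds `seed + 1, seed + 2,
#' ...`, and returns the best-scoring result (first found on ties).
#'
#' @param skel a [Skeleton-class]; required in `orient_only` mode, and
#'   used as the vertex set otherwise. May be `NULL` with `vertices`
#'   given for a full-move search.
#' @param vertices vertex set for full-move search when `skel` is `NULL`.
#' @inheritParams hillClimb
#' @return list with elements `dag` and `score`.
#' @export
restartedSearch <- function(skel = NULL, ddata, alphaScore = 0.999,
                            config = SearchConfig(), vertices = NULL,
                            cache = NULL) {
    if (is.null(cache))
        cache <- newScoreCache()
    if (config@moveSet == "orient_only" && is.null(skel))
        stop("orient_only search requires a skeleton")
    v <- if (!is.null(skel)) vertexNames(skel) else vertices
    best <- NULL
    for (i in seq_len(config@restarts)) {
        start <- if (config@moveSet == "orient_only")
            randomOrientation(skel, config@seed + i)
        else
            randomDag(v, config@seed + i)
        res <- hillClimb(start, ddata, alphaScore, config, cache)
        if (is.null(best) || res$score > best$score)
            best <- res
    }
    best
}
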