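## Seeded generators of ground-truth DAGs and linear-Gaussian
## structural-equation expression data shaped like the standard
## benchmark inputs (n genes x n samples, values rescaled to [0, 1]),
## so every stage of the pipeline is testable without external data.

#' Generate a random ground-truth network
#'
#' Draws a uniform random DAG with exactly `nEdges` edges: a random
#' topological order is sampled, then `nEdges` vertex pairs are drawn
#' uniformly without replacement from all pairs and oriented along the
#' order. Deterministic per seed.
#'
#' @param nGenes number of genes.
#' @param nEdges number of edges, at most `nGenes * (nGenes - 1) / 2`.
#' @param seed integer seed.
#' @return A [Dag-class] with gene names `G1..Gn`.
#' @export
generateNetwork <- function(nGenes, nEdges, seed) {
    maxE <- nGenes * (nGenes - 1) / 2
    if (nEdges > maxE)
        stop("infeasible edge count")
    v <- paste0("G", seq_len(nGenes))
    nEdges <- as.integer(nEdges)
    .withSeed(seed, {
        perm <- sample.int(nGenes)
        pairs <- utils::combn(nGenes, 2L)
        pick <- if (nEdges > 0L) sample.int(ncol(pairs), nEdges)
                else integer(0)
        from <- integer(nEdges); to <- integer(nEdges)
        for (e in seq_len(nEdges)) {
            a <- pairs[1L, pick[e]]; b <- pairs[2L, pick[e]]
            ## orient along the sampled topological order
            if (which(perm == a) < which(perm == b)) {
                from[e] <- a; to[e] <- b
            } else {
                from[e] <- b; to[e] <- a
            }
        }
        Dag(v, cbind(v[from], v[to]))
    })
}

#' Simulate expression data from a linear-Gaussian SEM
#'
#' Each gene is the coefficient-weighted sum of its parents plus
#' Gaussian noise, sampled in topological order; coefficients have
#' magnitudes uniform in `coefRange` with random sign. With
#' `rescale = TRUE` each gene is mapped linearly to `[0, 1]`, matching
#' the range convention of the benchmark expression sets (a monotone
#' per-gene map, so correlations and MI/CMI are unchanged).
#'
#' @param dag a [Dag-class] ground truth.
#' @param nSamples number of samples (columns).
#' @param coefRange length-2 numeric, magnitude range of SEM
#'   coefficients.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @param rescale map each gene to `[0, 1]`?
#' @return An [ExpressionMatrix-class].
#' @export
simulateExpression <- function(dag, nSamples, coefRange = c(0.5, 1.5),
                               noiseSd = 1, seed = 1L, rescale = TRUE) {
    if (noiseSd <= 0)
        stop("noiseSd must be positive")
    v <- vertexNames(dag)
    n <- length(v)
    ps <- parentSets(dag)
    g <- igraph::graph_from_data_frame(
        data.frame(from = edgeMatrix(dag)[, 1L],
                   to = edgeMatrix(dag)[, 2L]),
        directed = TRUE, vertices = v)
    topo <- igraph::as_ids(igraph::topo_sort(g))
    .withSeed(seed, {
        x <- matrix(0, n, nSamples, dimnames = list(v, NULL))
        for (node in topo) {
            val <- stats::rnorm(nSamples, sd = noiseSd)
            for (p in ps[[node]]) {
                coef <- stats::runif(1L, coefRange[1L], coefRange[2L]) *
                    sample(c(-1, 1), 1L)
                val <- val + coef * x[p, ]
            }
            x[node, ] <- val
        }
        if (rescale) {
            for (i in seq_len(n)) {
                rng <- range(x[i, ])
                if (rng[2L] > rng[1L])
                    x[i, ] <- (x[i, ] - rng[1L]) / (rng[2L] - rng[1L])
            }
        }
        colnames(x) <- paste0("S", seq_len(nSamples))
        ExpressionMatrix(x)
    })
}

#' Packaged benchmark-shaped fixtures
#'
#' `sosShapeFixture()` returns a fixed 9-gene, 24-edge truth with a 9 x 9
#' expression matrix (the shape of the E. coli SOS repair data);
#' `dreamShapeFixture(n)` returns an n-gene truth with an n x n matrix
#' for n in 10, 50, 100 (10, 77 and 166 edges respectively, the standard
#' in-silico benchmark sizes). Seeds are fixed, so the fixtures are
#' identical across processes.
#'
#' @param n network size for the in-silico shape: 10, 50 or 100.
#' @param nSamples optional sample-count override (default: `n` samples
#'   for `dreamShapeFixture`, 9 for `sosShapeFixture`).
#' @return list with `truth` (a [Dag-class]) and `data`
#'   (an [ExpressionMatrix-class]).
#' @export
dreamShapeFixture <- function(n = 10L, nSamples = n) {
    edges <- c(`10` = 10L, `50` = 77L, `100` = 166L)[as.character(n)]
    if (is.na(edges))
        stop("n must be one of 10, 50, 100")
    truth <- generateNetwork(n, edges, seed = 20140000L + n)
    data <- simulateExpression(truth, nSamples, seed = 20149999L + n)
    list(truth = truth, data = data)
}

#' @rdname dreamShapeFixture
#' @export
sosShapeFixture <- function(nSamples = 9L) {
    truth <- generateNetwork(9L, 24L, seed = 1973L)
    data <- simulateExpression(truth, nSamples, seed = 1974L)
    list(truth = truth, data = data)
}
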