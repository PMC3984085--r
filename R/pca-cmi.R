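## Path-consistency pruning with Gaussian CMI tests: starting from the
## complete undirected graph, edges whose maximum order-i CMI over
## conditioning subsets drawn from the common neighbours of the two
## endpoints falls below the threshold are removed, order by order.

## max CMI over all i-subsets of `candidates`; NA-but-kept on degenerate
## covariance (the edge survives, with a warning)
.maxCMI <- function(a, b, candidates, i, model) {
    subsets <- utils::combn(candidates, i, simplify = FALSE)
    failed <- FALSE
    mx <- -Inf
    for (s in subsets) {
        val <- tryCatch(conditionalMutualInformation(a, b, s, model),
                        error = function(e) {
                            failed <<- TRUE
                            NA_real_
                        })
        if (!is.na(val) && val > mx)
            mx <- val
    }
    if (failed) {
        warning("degenerate covariance in a CMI test for edge ", a, "--",
                b, "; edge kept")
        return(Inf)
    }
    mx
}

#' PCA-CMI: path-consistency skeleton learning with CMI tests
#'
#' Starts with the complete undirected graph. At order 0 the edge (X, Y)
#' is removed when `MI(X, Y) < theta`. At order `i >= 1`, for each
#' remaining edge with at least `i` common neighbours, all order-i CMIs
#' conditioned on i-subsets of the common neighbours are computed and the
#' edge is removed when the maximum falls below `theta`. Deletions take
#' effect immediately within an order (edges are visited in gene-pair
#' order), and the algorithm stops at the first order for which no edge
#' has enough common neighbours.
#'
#' @param data an [ExpressionMatrix-class].
#' @param theta nonnegative MI/CMI threshold (the conventional values are
#'   0.05 for small dense networks, 0.1 for larger sparse ones, 0.01 for
#'   the 9-gene SOS data).
#' @param maxOrder optional cap on the conditioning order; `NULL` means
#'   run until the natural stop. `maxOrder = 0` performs only the
#'   marginal-MI pruning.
#' @return list with `skeleton` (a [Skeleton-class]) and `orderReached`,
#'   the highest conditioning order actually executed.
#' @examples
#' fix <- dreamShapeFixture(10)
#' res <- pcaCMI(fix$data, theta = 0.05)
#' res$skeleton
#' @export
pcaCMI <- function(data, theta = 0.05, maxOrder = NULL) {
    if (theta < 0)
        stop("theta must be nonnegative")
    model <- covarianceModel(data)
    g <- geneNames(data)
    n <- length(g)
    adj <- matrix(TRUE, n, n, dimnames = list(g, g))
    diag(adj) <- FALSE
    ## order 0: marginal MI against theta
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
    orderReached <- 0L
    i <- 1L
    repeat {
        if (!is.null(maxOrder) && i > maxOrder)
            break
        anyBig <- FALSE
        for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
            if (!adj[a, b])
                next
            common <- which(adj[a, ] & adj[b, ])
            common <- setdiff(common, c(a, b))
            if (length(common) < i)
                next
            anyBig <- TRUE
            mx <- .maxCMI(g[a], g[b], g[common], i, model)
            if (mx < theta)
                adj[a, b] <- adj[b, a] <- FALSE
        }
        if (!anyBig)
            break
        orderReached <- i
        i <- i + 1L
    }
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    list(skeleton = Skeleton(g, cbind(g[idx[, 1L]], g[idx[, 2L]])),
         orderReached = orderReached)
}
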