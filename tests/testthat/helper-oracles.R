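# Independent oracles kept deliberately naive: definitional double loops,
# exhaustive enumeration, closed forms. They never share code with the
# package internals they check.

# definitional sample covariance (n-1 denominator), double loop
bruteCovariance <- function(m) {
    n <- nrow(m); k <- ncol(m)
    out <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        mi <- mean(m[i, ]); mj <- mean(m[j, ])
        out[i, j] <- sum((m[i, ] - mi) * (m[j, ] - mj)) / (k - 1)
    }
    out
}

# 2x2 determinant by cofactor expansion
det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]

# random positive-definite covariance with unit-ish scale
randomPD <- function(p) {
    a <- matrix(rnorm(p * p), p)
    crossprod(a) / p + diag(p) * 0.5
}

# brute-force count of labeled DAGs on n nodes: enumerate all 2^(n(n-1))
# digraphs over the off-diagonal cells and keep the acyclic ones (igraph
# is the acyclicity oracle)
countDagsBrute <- function(n) {
    cells <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
    m <- nrow(cells)
    count <- 0L
    for (mask in 0:(2^m - 1)) {
        on <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
        g <- igraph::make_empty_graph(n, directed = TRUE)
        if (length(on) > 0L)
            g <- igraph::add_edges(g, t(cells[on, , drop = FALSE]))
        if (igraph::is_dag(g))
            count <- count + 1L
    }
    count
}

# tiny ExpressionMatrix helper
em <- function(values, genes = paste0("G", seq_len(nrow(values)))) {
    ExpressionMatrix(matrix(values, nrow = length(genes),
                            dimnames = list(genes, NULL)))
}

# three-gene chain X -> Y -> Z with unit coefficients and unit noise
chainData <- function(nSamples, seed) {
    truth <- Dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
    d <- simulateExpression(truth, nSamples, coefRange = c(1, 1),
                            noiseSd = 1, seed = seed, rescale = FALSE)
    list(truth = truth, data = d)
}
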