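dm <- function(levels, lam = max(levels)) {
    lv <- levels
    storage.mode(lv) <- "integer"
    card <- apply(lv, 1L, function(r) length(unique(r)))
    new("DiscretizedMatrix", levels = lv,
        cardinality = stats::setNames(as.integer(card), rownames(lv)),
        nominalLevels = as.integer(lam))
}

test_that("empirical MI from counts: product tables, identity, duplicates", {
    # node independent of parent: a product contingency table
    prod <- dm(rbind(A = rep(1:2, each = 4), B = rep(1:2, times = 4)))
    expect_equal(empiricalMI("A", "B", prod), 0, tolerance = 1e-12)
    # binary node identical to its parent on a 4/4 split
    eq <- dm(rbind(A = rep(1:2, each = 4), B = rep(1:2, each = 4)))
    expect_equal(empiricalMI("A", "B", eq), log(2), tolerance = 1e-12)
    expect_equal(empiricalMI("A", character(0), eq), 0)
    # adding a duplicate parent leaves the counts, hence MI, unchanged
    set.seed(3)
    lv <- rbind(A = sample(1:3, 12, TRUE), B = sample(1:2, 12, TRUE))
    dup <- dm(rbind(lv, C = lv["B", ]))
    expect_equal(empiricalMI("A", c("B", "C"), dup),
                 empiricalMI("A", "B", dup), tolerance = 1e-12)
    # brute-force oracle over the 2-way contingency table
    tab <- table(lv["A", ], lv["B", ])
    N <- sum(tab)
    oracle <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
        if (tab[i, j] > 0)
            oracle <- oracle + tab[i, j] / N *
                log(N * tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
    expect_equal(empiricalMI("A", "B", dm(lv)), oracle, tolerance = 1e-12)
})

test_that("degrees of freedom follow the decreasing-cardinality permutation", {
    d <- dm(rbind(A = c(1, 2, 1, 2, 1, 2),      # node, 2 levels
                  B = c(1, 2, 3, 1, 2, 3),      # parent, 3 levels
                  C = c(1, 1, 2, 2, 1, 2)))     # parent, 2 levels
    expect_identical(dofSequence("A", "C", d), 1)
    expect_equal(dofSequence("A", c("B", "C"), d), c(2, 3))
    # input order never matters
    expect_equal(dofSequence("A", c("C", "B"), d),
                 dofSequence("A", c("B", "C"), d))
})

test_that("local MIT score: worked value, orphans, degenerate parents", {
    eq <- dm(rbind(A = rep(1:2, each = 4), B = rep(1:2, each = 4)))
    ls <- localMIT("A", "B", eq, alphaScore = 0.999)
    expect_equal(ls@miTerm, 16 * log(2), tolerance = 1e-9)
    expect_equal(ls@penaltyTerm, qchisq(0.999, 1), tolerance = 1e-9)
    expect_equal(ls@value, 0.2628, tolerance = 1e-3)
    expect_equal(localMIT("A", character(0), eq)@value, 0)
    # a single-level parent contributes nothing
    con <- dm(rbind(A = rep(1:2, each = 4), B = rep(1:2, each = 4),
                    C = rep(1L, 8)))
    expect_equal(localMIT("A", c("B", "C"), con)@value,
                 localMIT("A", "B", con)@value, tolerance = 1e-12)
    expect_error(localMIT("A", "B", eq, alphaScore = 1.2), "alphaScore")
})

test_that("total score decomposes and matches an independent re-derivation", {
    set.seed(9)
    lv <- rbind(A = sample(1:2, 20, TRUE), B = sample(1:3, 20, TRUE),
                C = sample(1:2, 20, TRUE))
    d <- dm(lv)
    dag <- Dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B"),
                                       c("A", "C")))
    empty <- Dag(c("A", "B", "C"))
    expect_equal(totalMIT(empty, d), 0)
    locals <- vapply(c("A", "B", "C"), function(v)
        localMIT(v, parentSets(dag)[[v]], d)@value, numeric(1))
    expect_equal(totalMIT(dag, d), sum(locals), tolerance = 1e-12)
    # full re-derivation from contingency tables for node B
    N <- 20
    tab <- table(lv["B", ], paste(lv["A", ], lv["C", ]))
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
        if (tab[i, j] > 0)
            mi <- mi + tab[i, j] / N *
                log(N * tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
    rB <- length(unique(lv["B", ]))
    rA <- length(unique(lv["A", ])); rC <- length(unique(lv["C", ]))
    # decreasing cardinality ties broken by gene order: A before C
    dofs <- if (rA >= rC) c((rB - 1) * (rA - 1), (rB - 1) * (rC - 1) * rA)
            else c((rB - 1) * (rC - 1), (rB - 1) * (rA - 1) * rC)
    expect_equal(localMIT("B", c("A", "C"), d)@value,
                 2 * N * mi - sum(qchisq(0.999, dofs)), tolerance = 1e-9)
})

test_that("move deltas equal full rescoring and compose correctly", {
    set.seed(41)
    lv <- matrix(sample(1:3, 5 * 30, TRUE), 5, 30,
                 dimnames = list(paste0("G", 1:5), NULL))
    d <- dm(lv)
    dag <- randomDag(paste0("G", 1:5), seed = 2L, maxParents = 2L)
    e <- edgeMatrix(dag)
    x <- e[1L, 1L]; y <- e[1L, 2L]
    # add then delete the same edge: deltas cancel
    topo <- igraph::as_ids(igraph::topo_sort(igraph::graph_from_data_frame(
        data.frame(from = e[, 1L], to = e[, 2L]), directed = TRUE,
        vertices = vertexNames(dag))))
    pairs <- t(combn(topo, 2L))   # topo-consistent: addition stays acyclic
    free <- !paste(pairs[, 1L], pairs[, 2L]) %in%
        c(paste(e[, 1L], e[, 2L]), paste(e[, 2L], e[, 1L]))
    nonEdge <- pairs[which(free)[1L], ]
    dAdd <- deltaMove(dag, "add", nonEdge[1L], nonEdge[2L], d)
    after <- Dag(vertexNames(dag), rbind(e, nonEdge))
    expect_equal(deltaMove(after, "delete", nonEdge[1L], nonEdge[2L], d),
                 -dAdd, tolerance = 1e-12)
    # reversal is a deletion followed by an addition
    delThenAdd <- Dag(vertexNames(dag), e[-1L, , drop = FALSE])
    expect_equal(deltaMove(dag, "reverse", x, y, d),
                 deltaMove(dag, "delete", x, y, d) +
                 deltaMove(delThenAdd, "add", y, x, d), tolerance = 1e-12)
    expect_error(deltaMove(dag, "delete", nonEdge[1L], nonEdge[2L], d),
                 "illegal move")
})

test_that("the score is not invariant under edge reversal", {
    # X and Z both feed Y; reversing X -> Y changes the family structure
    set.seed(7)
    x <- sample(1:2, 40, TRUE); z <- sample(1:2, 40, TRUE)
    y <- ifelse(x == z, 1L, 2L)   # XOR-like: Y depends jointly on X, Z
    d <- dm(rbind(X = x, Y = y, Z = z))
    v <- c("X", "Y", "Z")
    s1 <- totalMIT(Dag(v, rbind(c("X", "Y"), c("Z", "Y"))), d)
    s2 <- totalMIT(Dag(v, rbind(c("Y", "X"), c("Z", "Y"))), d)
    expect_gt(abs(s1 - s2), 1e-6)
})

test_that("cached local scores are bit-identical to uncached ones", {
    set.seed(13)
    lv <- matrix(sample(1:3, 4 * 25, TRUE), 4, 25,
                 dimnames = list(paste0("G", 1:4), NULL))
    d <- dm(lv)
    cache <- newScoreCache()
    a <- localMIT("G1", c("G2", "G3"), d, cache = cache)@value
    b <- localMIT("G1", c("G3", "G2"), d, cache = cache)@value
    expect_identical(a, b)
    expect_identical(a, localMIT("G1", c("G2", "G3"), d)@value)
    expect_gt(length(ls(cache)), 0L)
})
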