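discFix <- function(nGenes = 4L, nSamples = 40L, seed = 1L) {
    truth <- generateNetwork(nGenes, nGenes, seed = seed)
    d <- simulateExpression(truth, nSamples, seed = seed + 100L)
    list(truth = truth, ddata = equalWidth(d, 4L))
}

test_that("random DAGs are acyclic, seeded, and respect maxParents", {
    v <- paste0("G", 1:5)
    expect_identical(edgeCount(randomDag(v, 3L, maxParents = 0L)), 0L)
    expect_identical(edgeMatrix(randomDag(v, 7L)),
                     edgeMatrix(randomDag(v, 7L)))
    # validity would reject a cyclic draw; construct 300 and recheck with
    # the igraph oracle
    for (s in 1:300) {
        d <- randomDag(v, s)
        g <- igraph::graph_from_data_frame(
            data.frame(from = edgeMatrix(d)[, 1L],
                       to = edgeMatrix(d)[, 2L]),
            directed = TRUE, vertices = v)
        expect_true(igraph::is_dag(g))
        expect_true(all(vapply(parentSets(d), length, 1L) <= 3L))
    }
})

test_that("random orientations preserve the skeleton and avoid cycles", {
    skel <- completeSkeleton(paste0("G", 1:4))    # triangle-rich
    for (s in 1:20) {
        d <- randomOrientation(skel, s)
        expect_identical(edgeMatrix(skeleton(d)), edgeMatrix(skel))
    }
    expect_identical(edgeCount(randomOrientation(Skeleton("A"), 1L)), 0L)
})

test_that("hill climbing recovers a strong two-gene dependence", {
    set.seed(2)
    x <- rnorm(60)
    d <- ExpressionMatrix(rbind(X = x, Y = x + rnorm(60, sd = 0.1)))
    dd <- equalWidth(d, 4L)
    res <- hillClimb(Dag(c("X", "Y")), dd, config = SearchConfig())
    expect_identical(edgeCount(res$dag), 1L)
    # exhaustive oracle over the three possible structures
    v <- c("X", "Y")
    scores <- c(totalMIT(Dag(v), dd),
                totalMIT(Dag(v, rbind(c("X", "Y"))), dd),
                totalMIT(Dag(v, rbind(c("Y", "X"))), dd))
    expect_equal(res$score, max(scores), tolerance = 1e-9)
})

test_that("a local optimum is returned unchanged with its own score", {
    fix <- discFix(seed = 3L)
    first <- hillClimb(Dag(vertexNames(fix$truth)), fix$ddata)
    again <- hillClimb(first$dag, fix$ddata)
    expect_identical(edgeMatrix(again$dag), edgeMatrix(first$dag))
    expect_equal(again$score, first$score, tolerance = 1e-12)
})

test_that("climbing improves the score over the start, orient-only keeps the skeleton", {
    fix <- discFix(nGenes = 5L, seed = 4L)
    skel <- skeleton(fix$truth)
    init <- randomOrientation(skel, 9L)
    cfg <- SearchConfig(moveSet = "orient_only")
    res <- hillClimb(init, fix$ddata, config = cfg)
    expect_gte(res$score, totalMIT(init, fix$ddata))
    expect_identical(edgeMatrix(skeleton(res$dag)), edgeMatrix(skel))
    best <- restartedSearch(skel, fix$ddata, config = SearchConfig(
        restarts = 10L, seed = 5L, moveSet = "orient_only"))
    expect_identical(edgeMatrix(skeleton(best$dag)), edgeMatrix(skel))
})

test_that("one restart equals a single climb; more restarts never hurt", {
    fix <- discFix(seed = 6L)
    skel <- skeleton(fix$truth)
    one <- restartedSearch(skel, fix$ddata, config = SearchConfig(
        restarts = 1L, seed = 11L, moveSet = "orient_only"))
    single <- hillClimb(randomOrientation(skel, 12L), fix$ddata,
                        config = SearchConfig(moveSet = "orient_only"))
    expect_equal(one$score, single$score, tolerance = 1e-12)
    expect_identical(edgeMatrix(one$dag), edgeMatrix(single$dag))
    five <- restartedSearch(skel, fix$ddata, config = SearchConfig(
        restarts = 5L, seed = 11L, moveSet = "orient_only"))
    expect_gte(five$score, one$score)
})
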