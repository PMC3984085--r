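test_that("blocked-path weights follow chain/fork vs collider semantics", {
    v <- c("X", "Y", "Z")
    chain <- Dag(v, rbind(c("X", "Z"), c("Z", "Y"), c("X", "Y")))
    expect_gte(blockedPathWeight("Z", "X", "Y", chain), 1L)
    collide <- Dag(v, rbind(c("X", "Z"), c("Y", "Z"), c("X", "Y")))
    expect_identical(blockedPathWeight("Z", "X", "Y", collide), 0L)
    fork <- Dag(v, rbind(c("Z", "X"), c("Z", "Y"), c("X", "Y")))
    expect_identical(blockedPathWeight("Z", "X", "Y", fork), 1L)
    # unattached candidate: error (not adjacent to either endpoint)
    d4 <- Dag(c(v, "W"), rbind(c("X", "Y")))
    expect_error(blockedPathWeight("W", "X", "Y", d4), "adjacent")
    expect_error(blockedPathWeight("X", "X", "Y", chain), "differ")
})

test_that("selected sets obey the median rule and adjacency", {
    # star around X: all candidates adjacent, no indirect X--Y paths,
    # so every weight is 0, k = 0, and everything is selected
    v <- paste0("G", 1:5)
    star <- Dag(v, rbind(c("G1", "G2"), c("G1", "G3"), c("G1", "G4"),
                         c("G1", "G5")))
    wt <- selectedSet("G1", "G2", star)
    expect_true(all(wt@weights == 0L))
    expect_identical(wt@k, 0)
    expect_setequal(wt@selected, c("G3", "G4", "G5"))
    # candidate pool is the union of the endpoint neighbourhoods
    d <- Dag(v, rbind(c("G3", "G1"), c("G1", "G2"), c("G2", "G4"),
                      c("G5", "G1"), c("G5", "G2")))
    wt2 <- selectedSet("G1", "G2", d)
    expect_setequal(names(wt2@weights), c("G3", "G4", "G5"))
    common <- "G5"   # the only common neighbour
    expect_true(all(common %in% names(wt2@weights)))
    # all-equal weights select every candidate
    tri <- Dag(c("A", "B", "C"), rbind(c("A", "C"), c("C", "B"),
                                       c("A", "B")))
    wt3 <- selectedSet("A", "B", tri)
    expect_setequal(wt3@selected, "C")
})

test_that("huge theta empties the graph at order zero", {
    d <- chainData(40L, seed = 3L)$data
    res <- ipcaCMI(d, theta = 1e6,
                   config = SearchConfig(restarts = 2L, seed = 1L))
    expect_identical(edgeCount(res$dag), 0L)
    expect_identical(res$orderReached, 0L)
})

test_that("order-0 skeletons of IPCA-CMI and PCA-CMI coincide", {
    for (s in 1:4) {
        truth <- generateNetwork(8L, 9L, seed = 30L + s)
        d <- simulateExpression(truth, 120L, seed = 90L + s)
        a <- pcaCMI(d, 0.05, maxOrder = 0L)$skeleton
        b <- ipcaCMI(d, 0.05, maxOrder = 0L,
                     config = SearchConfig(restarts = 2L, seed = s))$dag
        expect_identical(edgeMatrix(skeleton(b)), edgeMatrix(a))
    }
})

test_that("the pipeline is deterministic and non-increasing in edges", {
    truth <- generateNetwork(8L, 10L, seed = 5L)
    d <- simulateExpression(truth, 150L, seed = 6L)
    cfg <- SearchConfig(restarts = 5L, seed = 42L)
    r1 <- ipcaCMI(d, 0.05, config = cfg)
    r2 <- ipcaCMI(d, 0.05, config = cfg)
    expect_identical(edgeMatrix(r1$dag), edgeMatrix(r2$dag))
    expect_identical(r1$log, r2$log)
    expect_true(all(diff(r1$log$edges) <= 0))
    # conditioning never grows the skeleton relative to order 0
    r0 <- ipcaCMI(d, 0.05, maxOrder = 0L, config = cfg)
    expect_lte(edgeCount(r1$dag), edgeCount(r0$dag))
})

test_that("averaging over repeated runs behaves like a mean", {
    truth <- generateNetwork(6L, 6L, seed = 8L)
    d <- simulateExpression(truth, 100L, seed = 9L)
    ts <- skeleton(truth)
    one <- repeatedRuns(d, ts, nRuns = 1L, seed = 3L, restarts = 2L,
                        theta = 0.05)
    direct <- confusion(skeleton(ipcaCMI(d, 0.05, config = SearchConfig(
        restarts = 2L, seed = 4L))$dag), ts)
    expect_equal(one@tp, direct@tp)
    expect_equal(one@f, direct@f)
    three <- repeatedRuns(d, ts, nRuns = 3L, seed = 3L, restarts = 2L,
                          theta = 0.05)
    runs <- vapply(1:3, function(r) confusion(skeleton(
        ipcaCMI(d, 0.05, config = SearchConfig(restarts = 2L,
                                               seed = 3L + r))$dag),
        ts)@tp, numeric(1))
    expect_equal(three@tp, mean(runs))
    expect_gte(three@tp, min(runs))
    expect_lte(three@tp, max(runs))
})
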