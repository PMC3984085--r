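cmFrom <- function(cv, n = 100L) {
    g <- paste0("G", seq_len(nrow(cv)))
    dimnames(cv) <- list(g, g)
    new("CovarianceModel", cov = cv, nSamples = as.integer(n))
}

test_that("Gaussian entropy matches the closed form", {
    expect_equal(gaussianEntropy(matrix(1)), 0.5 * log(2 * pi * exp(1)),
                 tolerance = 1e-12)
    # independent coordinates: entropies add
    expect_equal(gaussianEntropy(diag(2)),
                 2 * gaussianEntropy(matrix(1)), tolerance = 1e-12)
    s <- matrix(c(1, 0.5, 0.5, 1), 2)
    expect_equal(det(s), det2(s))   # cofactor oracle agrees
    expect_equal(gaussianEntropy(s),
                 0.5 * log((2 * pi * exp(1))^2 * 0.75), tolerance = 1e-12)
    expect_error(gaussianEntropy(matrix(c(1, 1, 1, 1), 2)), "degenerate")
})

test_that("MI closed form, symmetry and entropy decomposition", {
    model <- cmFrom(matrix(c(1, 0.5, 0.5, 1), 2))
    expect_equal(mutualInformation("G1", "G2", model),
                 -0.5 * log(1 - 0.25), tolerance = 1e-12)
    expect_equal(mutualInformation("G1", "G2", model), 0.143841,
                 tolerance = 1e-5)
    zero <- cmFrom(diag(2))
    expect_equal(mutualInformation("G1", "G2", zero), 0, tolerance = 1e-12)
    set.seed(5)
    for (rep in 1:10) {
        model <- cmFrom(randomPD(4))
        s <- covMatrix(model)
        expect_equal(mutualInformation("G1", "G3", model),
                     mutualInformation("G3", "G1", model))
        expect_equal(mutualInformation("G1", "G2", model),
                     gaussianEntropy(s["G1", "G1", drop = FALSE]) +
                     gaussianEntropy(s["G2", "G2", drop = FALSE]) -
                     gaussianEntropy(s[c("G1", "G2"), c("G1", "G2")]),
                     tolerance = 1e-9)
    }
    degen <- cmFrom(diag(c(0, 1)))
    expect_error(mutualInformation("G1", "G2", degen), "degenerate")
})

test_that("CMI equals the entropy combination and reduces to MI", {
    cv <- matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3)
    model <- cmFrom(cv)
    s <- covMatrix(model)
    combo <- gaussianEntropy(s[c(1, 3), c(1, 3)]) +
        gaussianEntropy(s[c(2, 3), c(2, 3)]) -
        gaussianEntropy(s[3, 3, drop = FALSE]) - gaussianEntropy(s)
    expect_equal(conditionalMutualInformation("G1", "G2", "G3", model),
                 combo, tolerance = 1e-12)
    expect_equal(conditionalMutualInformation("G1", "G2", character(0),
                                              model),
                 mutualInformation("G1", "G2", model))
    expect_error(conditionalMutualInformation("G1", "G2", "G1", model),
                 "conditioning")
})

test_that("chain rule holds on random positive-definite fixtures", {
    set.seed(17)
    for (rep in 1:20) {
        model <- cmFrom(randomPD(3))
        s <- covMatrix(model)
        lhs <- mutualInformation("G1", "G2", model) +
            conditionalMutualInformation("G1", "G3", "G2", model)
        rhs <- gaussianEntropy(s[1, 1, drop = FALSE]) +
            gaussianEntropy(s[2:3, 2:3]) - gaussianEntropy(s)
        expect_equal(lhs, rhs, tolerance = 1e-9)
    }
})

test_that("CMI is invariant under per-gene rescaling", {
    set.seed(23)
    m <- matrix(rnorm(4 * 40), 4, 40)
    base <- conditionalMutualInformation("G1", "G2", c("G3", "G4"),
                                         covarianceModel(em(m)))
    for (rep in 1:5) {
        sc <- runif(4, 0.1, 10)
        scaled <- conditionalMutualInformation(
            "G1", "G2", c("G3", "G4"), covarianceModel(em(m * sc)))
        expect_equal(scaled, base, tolerance = 1e-9)
    }
})

test_that("d-separated CMI shrinks with sample size (Monte Carlo)", {
    meds <- vapply(c(50L, 200L, 800L), function(n) {
        stats::median(vapply(1:50, function(s) {
            d <- chainData(n, seed = 5000L + 17L * s + n)
            conditionalMutualInformation("X", "Z", "Y",
                                         covarianceModel(d$data))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(meds) < 0))
})

test_that("independence decisions in threshold and p-value mode", {
    ind <- cmFrom(diag(2))
    dep <- cmFrom(matrix(c(1, 0.5, 0.5, 1), 2))
    expect_true(independenceTest("G1", "G2", model = ind,
                                 theta = 0.05)@independent)
    d <- independenceTest("G1", "G2", model = dep, theta = 0.05)
    expect_false(d@independent)
    expect_equal(d@statistic, 0.143841, tolerance = 1e-5)
    # null limit: rho -> 0 gives p -> 1 regardless of n
    p <- independenceTest("G1", "G2", model = ind, mode = "pvalue",
                          alphaTest = 0.05)
    expect_equal(p@pValue, 1, tolerance = 1e-9)
    expect_true(p@independent)
    small <- cmFrom(diag(2), n = 3L)
    expect_error(independenceTest("G1", "G2", model = small,
                                  mode = "pvalue"), "insufficient samples")
})
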