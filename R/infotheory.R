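## Gaussian closed forms for entropy, MI and CMI, and the (conditional)
## independence decision used by the path-consistency algorithms. All
## quantities are in nats.

.DEGENERATE_DET <- 1e-300

.subDet <- function(model, genes) {
    d <- det(model@cov[genes, genes, drop = FALSE])
    if (!is.finite(d) || d < .DEGENERATE_DET)
        stop("degenerate covariance")
    d
}

#' Differential entropy of a Gaussian vector
#'
#' `H = 1/2 * ln((2 * pi * e)^p * det(Sigma))` for a p-dimensional Gaussian
#' with covariance `Sigma`.
#'
#' @param sigma symmetric covariance (sub)matrix with positive determinant.
#' @return entropy in nats.
#' @examples
#' gaussianEntropy(matrix(1))          # 0.5 * log(2 * pi * exp(1))
#' gaussianEntropy(diag(2))            # exactly twice the 1-D value
#' @export
gaussianEntropy <- function(sigma) {
    sigma <- as.matrix(sigma)
    if (!isSymmetric(unname(sigma), tol = 1e-8))
        stop("covariance submatrix must be symmetric")
    d <- det(sigma)
    if (!is.finite(d) || d < .DEGENERATE_DET)
        stop("degenerate covariance")
    p <- nrow(sigma)
    0.5 * (p * log(2 * pi * exp(1)) + log(d))
}

#' Gaussian mutual information between two genes
#'
#' `MI(X;Y) = 1/2 * ln(var(X) * var(Y) / det(Sigma_XY))`, the Gaussian
#' closed form; equals `H(X) + H(Y) - H(X,Y)`.
#'
#' @param x,y gene identifiers.
#' @param model a [CovarianceModel-class].
#' @return mutual information in nats (nonnegative up to rounding).
#' @examples
#' cv <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("A","B"), c("A","B")))
#' model <- new("CovarianceModel", cov = cv, nSamples = 10L)
#' mutualInformation("A", "B", model)   # -0.5 * log(1 - 0.25)
#' @export
mutualInformation <- function(x, y, model) {
    s <- model@cov
    if (s[x, x] < .DEGENERATE_DET || s[y, y] < .DEGENERATE_DET)
        stop("degenerate gene")
    0.5 * log(s[x, x] * s[y, y] / .subDet(model, c(x, y)))
}

#' Gaussian conditional mutual information
#'
#' `CMI(X;Y|Z) = 1/2 * ln(det(S_XZ) * det(S_YZ) / (det(S_Z) * det(S_XYZ)))`
#' for the Gaussian model; reduces to [mutualInformation()] when `zSet`
#' is empty, and is zero iff X and Y are conditionally independent given Z.
#'
#' @param x,y gene identifiers (not in `zSet`).
#' @param zSet character vector of conditioning genes (possibly empty).
#' @param model a [CovarianceModel-class].
#' @return conditional mutual information in nats.
#' @export
conditionalMutualInformation <- function(x, y, zSet, model) {
    if (x %in% zSet || y %in% zSet)
        stop("x and y must not be part of the conditioning set")
    if (length(zSet) == 0L)
        return(mutualInformation(x, y, model))
    0.5 * log(.subDet(model, c(x, zSet)) * .subDet(model, c(y, zSet)) /
              (.subDet(model, zSet) * .subDet(model, c(x, y, zSet))))
}

#' (Conditional) independence decision
#'
#' Decides conditional independence of two genes given a conditioning set.
#' In `threshold` mode (the primary mode) the genes are declared
#' independent when the raw MI/CMI statistic falls below `theta`; this is
#' the decision rule the path-consistency pruning uses with the standard
#' thresholds 0.05 / 0.1 / 0.01. In `pvalue` mode a Fisher-z test is
#' applied: the statistic is mapped back to an implied correlation
#' `rho = sqrt(1 - exp(-2 * CMI))`, the z statistic
#' `atanh(rho) * sqrt(n - |Z| - 3)` is compared with the standard normal,
#' and independence is accepted when the two-sided p-value is at least
#' `alphaTest`.
#'
#' @param x,y gene identifiers.
#' @param zSet conditioning genes (possibly empty).
#' @param model a [CovarianceModel-class].
#' @param theta nonnegative threshold on the MI/CMI statistic.
#' @param mode `"threshold"` (default) or `"pvalue"`.
#' @param alphaTest significance level for `pvalue` mode.
#' @return An [IndependenceDecision-class].
#' @export
independenceTest <- function(x, y, zSet = character(0), model,
                             theta = 0.05,
                             mode = c("threshold", "pvalue"),
                             alphaTest = 0.05) {
    mode <- match.arg(mode)
    stat <- conditionalMutualInformation(x, y, zSet, model)
    ord <- length(zSet)
    if (mode == "threshold") {
        if (theta < 0)
            stop("theta must be nonnegative")
        return(new("IndependenceDecision", statistic = stat,
                   order = as.integer(ord), independent = stat < theta,
                   pValue = NA_real_))
    }
    if (alphaTest <= 0 || alphaTest >= 1)
        stop("alphaTest must lie in (0, 1)")
    nEff <- model@nSamples - ord - 3
    if (nEff <= 0)
        stop("insufficient samples for order")
    rho <- sqrt(max(0, 1 - exp(-2 * stat)))
    z <- 0.5 * log((1 + rho) / max(1 - rho, .Machine$double.xmin)) *
        sqrt(nEff)
    p <- 2 * (1 - stats::pnorm(z))
    new("IndependenceDecision", statistic = stat, order = as.integer(ord),
        independent = p >= alphaTest, pValue = p)
}

setMethod("show", "IndependenceDecision", function(object) {
    cat("IndependenceDecision: statistic =", format(object@statistic),
        "(order", paste0(object@order, ");"),
        if (object@independent) "independent" else "dependent", "\n")
})
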