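## Equal-width and equal-frequency discretization of continuous expression
## data. The MIT score deals with discrete variables only, so continuous
## expression is binned into lambda levels per gene before scoring; CMI
## tests always stay on the continuous scale.

#' Equal-width discretization (EWD)
#'
#' Per gene, the range `[min, max]` is split into `lam` intervals of equal
#' width `w = (max - min) / lam` with cut points at `min + j * w`. Bins are
#' half-open `[low, high)` with the final bin closed, so a value on a cut
#' point belongs to the upper bin; the minimum maps to level 1 and the
#' maximum to level `lam`. A constant gene collapses to a single level
#' (with a warning).
#'
#' @param data an [ExpressionMatrix-class].
#' @param lam number of bins, at least 2. The conventional choice for
#'   expression values rescaled to `[0, 1]` is 10.
#' @return A [DiscretizedMatrix-class].
#' @examples
#' em <- ExpressionMatrix(matrix(seq(0, 1, length.out = 10), 2, 5,
#'     byrow = TRUE, dimnames = list(c("G1", "G2"), NULL)))
#' levelMatrix(equalWidth(em, 5))
#' @export
equalWidth <- function(data, lam) {
    stopifnot(is(data, "ExpressionMatrix"))
    lam <- as.integer(lam)
    if (lam < 2L)
        stop("lam must be at least 2")
    v <- exprValues(data)
    lv <- matrix(1L, nrow(v), ncol(v), dimnames = dimnames(v))
    for (g in seq_len(nrow(v))) {
        lo <- min(v[g, ]); hi <- max(v[g, ])
        if (hi == lo) {
            warning("constant gene '", rownames(v)[g],
                    "' collapsed to a single level")
            next
        }
        w <- (hi - lo) / lam
        lv[g, ] <- pmin(pmax(floor((v[g, ] - lo) / w) + 1, 1L), lam)
    }
    storage.mode(lv) <- "integer"
    card <- apply(lv, 1L, function(r) length(unique(r)))
    new("DiscretizedMatrix", levels = lv,
        cardinality = stats::setNames(as.integer(card), rownames(v)),
        nominalLevels = lam)
}

#' Equal-frequency discretization (EFD)
#'
#' Per gene, the sorted values are split into `lam` groups whose sizes
#' differ by at most one (the first `n %% lam` groups take the extra
#' value). Ties are kept together: every occurrence of a value receives
#' the level of its first sorted occurrence, so equal values always share
#' a level and discretization is monotone.
#'
#' @param data an [ExpressionMatrix-class].
#' @param lam number of groups, between 2 and the number of samples.
#' @return A [DiscretizedMatrix-class].
#' @export
equalFrequency <- function(data, lam) {
    stopifnot(is(data, "ExpressionMatrix"))
    lam <- as.integer(lam)
    if (lam < 2L)
        stop("lam must be at least 2")
    v <- exprValues(data)
    m <- ncol(v)
    if (lam > m)
        stop("lam must not exceed the number of samples")
    base <- m %/% lam
    sizes <- rep(base, lam) + c(rep(1L, m %% lam), rep(0L, lam - m %% lam))
    posLevel <- rep(seq_len(lam), times = sizes)
    lv <- matrix(1L, nrow(v), m, dimnames = dimnames(v))
    for (g in seq_len(nrow(v))) {
        ord <- order(v[g, ])                       # stable: ties by index
        sorted <- v[g, ord]
        lev <- posLevel
        # tie runs take the level of their first sorted position
        first <- c(TRUE, sorted[-1L] != sorted[-m])
        lev <- lev[cummax(seq_len(m) * first)]
        lv[g, ord] <- lev
    }
    storage.mode(lv) <- "integer"
    card <- apply(lv, 1L, function(r) length(unique(r)))
    new("DiscretizedMatrix", levels = lv,
        cardinality = stats::setNames(as.integer(card), rownames(v)),
        nominalLevels = lam)
}

#' Discretize an expression matrix
#'
#' Dispatches to [equalWidth()] or [equalFrequency()].
#'
#' @param data an [ExpressionMatrix-class].
#' @param method `"ewd"` or `"efd"`.
#' @param lam number of levels.
#' @return A [DiscretizedMatrix-class].
#' @export
discretizeExpression <- function(data, method = c("ewd", "efd"), lam = 10L) {
    method <- match.arg(method)
    if (method == "ewd") equalWidth(data, lam) else equalFrequency(data, lam)
}
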