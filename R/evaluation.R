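## Skeleton evaluation: confusion counts over all unordered gene pairs,
## the standard derived measures, and the hypergeometric
## subgraph-selection probability used to compare inferred networks
## (smaller = a prediction less likely to arise by drawing edges at
## random).

.deriveMetrics <- function(tp, fp, tn, fn) {
    total <- tp + fp + tn + fn
    safe <- function(num, den, what) {
        if (den == 0) {
            warning("zero denominator for ", what, "; reporting 0")
            return(0)
        }
        num / den
    }
    ppv <- safe(tp, tp + fp, "PPV")
    tpr <- safe(tp, tp + fn, "TPR")
    list(
        acc = safe(tp + tn, total, "ACC"),
        fpr = safe(fp, fp + tn, "FPR"),
        fdr = safe(fp, fp + tp, "FDR"),
        ppv = ppv,
        tpr = tpr,
        f = safe(2 * ppv * tpr, ppv + tpr, "F"),
        mcc = {
            den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) *
                sqrt(tn + fn)
            if (den == 0) {
                warning("zero denominator for MCC; reporting 0")
                0
            } else (tp * tn - fp * fn) / den
        })
}

.confusionMetrics <- function(tp, fp, tn, fn) {
    m <- .deriveMetrics(tp, fp, tn, fn)
    new("ConfusionMetrics", tp = tp, fp = fp, tn = tn, fn = fn,
        acc = m$acc, fpr = m$fpr, fdr = m$fdr, ppv = m$ppv, f = m$f,
        mcc = m$mcc, tpr = m$tpr)
}

#' Confusion metrics of a predicted skeleton
#'
#' Counts TP/FP/TN/FN over all `n(n-1)/2` unordered gene pairs of the
#' shared vertex set and derives ACC, FPR, FDR, PPV, F, MCC and TPR. A
#' zero denominator yields 0 with a warning.
#'
#' @param predicted,truth [Skeleton-class] objects over the same vertex
#'   set.
#' @return A [ConfusionMetrics-class].
#' @export
confusion <- function(predicted, truth) {
    if (!setequal(vertexNames(predicted), vertexNames(truth)))
        stop("predicted and truth skeletons must share a vertex set")
    v <- vertexNames(truth)
    key <- function(s) {
        e <- edgeMatrix(s)
        if (nrow(e) == 0L) return(character(0))
        i <- match(e[, 1L], v); j <- match(e[, 2L], v)
        paste(pmin(i, j), pmax(i, j))
    }
    p <- key(predicted); t <- key(truth)
    total <- length(v) * (length(v) - 1L) / 2
    tp <- length(intersect(p, t))
    fp <- length(setdiff(p, t))
    fn <- length(setdiff(t, p))
    tn <- total - tp - fp - fn
    .confusionMetrics(tp, fp, tn, fn)
}

#' Confusion metrics from printed counts
#'
#' Reconstructs the full metric row from the usual published summary:
#' network size, number of true edges, and the TP/FP counts. Counts may
#' be fractional (averaged over runs).
#'
#' @param tp,fp true/false positive counts.
#' @param nGenes number of genes (so `nGenes * (nGenes - 1) / 2` pairs).
#' @param mTrue number of edges in the gold standard.
#' @return A [ConfusionMetrics-class].
#' @examples
#' confusionFromCounts(tp = 7, fp = 1, nGenes = 10, mTrue = 10)
#' @export
confusionFromCounts <- function(tp, fp, nGenes, mTrue) {
    total <- nGenes * (nGenes - 1) / 2
    fn <- mTrue - tp
    tn <- total - mTrue - fp
    if (fn < 0 || tn < 0 || tp < 0 || fp < 0)
        stop("inconsistent counts")
    .confusionMetrics(tp, fp, tn, fn)
}

setMethod("show", "ConfusionMetrics", function(object) {
    cat(sprintf(
        "ConfusionMetrics: TP=%g FP=%g TN=%g FN=%g\n", object@tp,
        object@fp, object@tn, object@fn))
    cat(sprintf(
        "  ACC=%.3f FPR=%.3f FDR=%.3f PPV=%.3f F=%.3f MCC=%.3f TPR=%.3f\n",
        object@acc, object@fpr, object@fdr, object@ppv, object@f,
        object@mcc, object@tpr))
})

#' Coerce ConfusionMetrics to a one-row data.frame
#'
#' @param x a [ConfusionMetrics-class].
#' @return data.frame with columns tp, fp, tn, fn, acc, fpr, fdr, ppv,
#'   f, mcc, tpr.
#' @export
metricsAsDataFrame <- function(x) {
    data.frame(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn, acc = x@acc,
               fpr = x@fpr, fdr = x@fdr, ppv = x@ppv, f = x@f,
               mcc = x@mcc, tpr = x@tpr)
}

#' Subgraph-selection probability
#'
#' The hypergeometric point probability of drawing exactly `tp` true and
#' `fp` false edges when choosing `tp + fp` of the `P = n(n-1)/2`
#' possible edges of which `mTrue` are true:
#' `C(mTrue, tp) * C(P - mTrue, fp) / C(P, tp + fp)`, computed in log
#' space so networks with hundreds of genes pose no overflow problem.
#' Smaller values indicate predictions further from what random edge
#' selection would produce.
#'
#' @param nGenes number of genes.
#' @param mTrue number of true edges.
#' @param tp,fp integer counts with `0 <= tp <= mTrue` and
#'   `0 <= fp <= P - mTrue`.
#' @return probability in `[0, 1]`.
#' @examples
#' subgraphProbability(10, 10, tp = 7, fp = 1)
#' @export
subgraphProbability <- function(nGenes, mTrue, tp, fp) {
    P <- nGenes * (nGenes - 1) / 2
    if (tp < 0 || tp > mTrue || fp < 0 || fp > P - mTrue)
        stop("counts out of range")
    exp(lchoose(mTrue, tp) + lchoose(P - mTrue, fp) -
        lchoose(P, tp + fp))
}
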