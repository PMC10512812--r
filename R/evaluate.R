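#' @importFrom stats median
NULL

#' ROC curve and AUC for a scored binary contrast
#'
#' Computes the empirical ROC curve (thresholds descending, higher score
#' predicting the positive class) and its area. The AUC is the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted half (midranks); this equals the trapezoidal
#' area under the empirical ROC.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector; TRUE/1 = positive class.
#' @return list with \code{auc} and \code{points}, a data.frame of
#'   (\code{fpr}, \code{tpr}) from (0,0) to (1,1).
#' @examples
#' rocAuc(c(0.9, 0.3, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.logical(labels)
    if (anyNA(scores) || anyNA(labels))
        stop("NA in scores or labels", call. = FALSE)
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present", call. = FALSE)
    r <- rank(scores)  # midranks
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ## empirical ROC: sweep unique thresholds from high to low
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; l <- labels[ord]
    keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
    tpr <- cumsum(l)[keep] / n1
    fpr <- cumsum(!l)[keep] / n0
    list(auc = auc,
         points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Pearson correlation between panel scores and recurrence time
#'
#' Pearson correlation with the usual t-based two-sided p-value,
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 degrees of freedom. Pairs
#' with a missing value are dropped. A constant input has no defined
#' correlation and is reported as missing with a warning.
#'
#' @param scores,time numeric vectors of equal length.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
scoreTimeCorrelation <- function(scores, time) {
    ok <- !is.na(scores) & !is.na(time)
    x <- scores[ok]; y <- time[ok]
    n <- length(x)
    if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant input; correlation undefined")
        return(list(r = NA_real_, p = NA_real_, n = n))
    }
    r <- cor(x, y)
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    list(r = r, p = 2 * pt(-abs(t), df = n - 2), n = n)
}

#' Median-split comparison of scores and recurrence times
#'
#' Splits samples at the median of one variable and Welch-compares the
#' other between the halves. A time split puts \code{time <= median} into
#' the short-time group A; a score split puts \code{score >= median} into
#' the high-score group A (the conventions under which higher scores are
#' expected to accompany shorter recurrence). The median is the standard
#' sample median (midpoint of the central order statistics for even n).
#'
#' @param split numeric vector split at its median.
#' @param compare numeric vector compared between the halves.
#' @param type \code{"time"} or \code{"score"} (controls which side of the
#'   median joins group A, see above).
#' @return list with \code{type}, \code{threshold}, \code{idxA},
#'   \code{idxB}, group means/medians of \code{compare}, \code{t},
#'   \code{df}, \code{p}.
#' @export
medianSplitCompare <- function(split, compare, type = c("time", "score")) {
    type <- match.arg(type)
    ok <- !is.na(split) & !is.na(compare)
    split <- split[ok]; compare <- compare[ok]
    if (length(split) < 4L) stop("need at least 4 samples", call. = FALSE)
    med <- median(split)
    inA <- if (type == "time") split <= med else split >= med
    if (!any(inA) || all(inA))
        stop("median split leaves an empty group (heavy ties at the median)",
             call. = FALSE)
    a <- compare[inA]; b <- compare[!inA]
    wt <- .welch(a, b)
    list(type = type, threshold = med,
         idxA = which(ok)[inA], idxB = which(ok)[!inA],
         meanA = mean(a), meanB = mean(b),
         medianA = median(a), medianB = median(b),
         t = wt$t, df = wt$df, p = wt$p)
}

.tryNA <- function(expr) tryCatch(expr, error = function(e) NULL)

#' Full panel evaluation over a stratified bulk cohort
#'
#' Scores the cohort for a gene panel (z-scored over all samples, see
#' \code{\link{panelScoreBulk}}) and assembles the complete performance
#' report: Welch score comparisons and AUCs for the tumor-vs-normal,
#' recurrent-vs-non-recurrent and HT_YES-vs-HT_NO contrasts (positive
#' class: tumor, recurrent, HT_YES — higher score predicting the worse
#' outcome), plus, within the recurrent and HT_YES strata, the
#' score-vs-recurrence-time Pearson correlation and both median-split
#' comparisons. Contrasts whose strata are empty or degenerate are
#' reported as missing and the run continues. The report is deterministic
#' for fixed inputs.
#'
#' @param x SummarizedExperiment with assay \code{expr} and phenotype
#'   colData (see \code{\link{readBulkCohort}}).
#' @param panel a \linkS4class{GeneSet} or character vector.
#' @param strata optional precomputed strata (see
#'   \code{\link{stratifyCohort}}).
#' @param outDir optional directory; when given, writes
#'   \code{report.tsv}, \code{report.json} and per-contrast ROC point
#'   files.
#' @return list with \code{scores}, \code{contrasts} (data.frame),
#'   \code{timeAnalyses} (per stratum: \code{correlation},
#'   \code{timeSplit}, \code{scoreSplit}), \code{roc} (per contrast).
#' @export
evaluatePanel <- function(x, panel, strata = NULL, outDir = NULL) {
    if (is.null(strata)) strata <- stratifyCohort(x)
    scores <- panelScoreBulk(x, panel)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    contrasts <- list(
        tumor_vs_normal = c("tumor", "normal"),
        recurrent_vs_non_recurrent = c("recurrent", "non_recurrent"),
        HT_YES_vs_HT_NO = c("HT_YES", "HT_NO"))
    rows <- list(); roc <- list()
    for (nm in names(contrasts)) {
        pos <- strata[[contrasts[[nm]][1L]]]
        neg <- strata[[contrasts[[nm]][2L]]]
        cmp <- .tryNA(compareScores(scores, pos, neg))
        rr <- .tryNA(rocAuc(scores[c(pos, neg)],
                            rep(c(TRUE, FALSE), c(length(pos), length(neg)))))
        rows[[nm]] <- data.frame(
            contrast = nm, n_pos = length(pos), n_neg = length(neg),
            mean_pos = if (is.null(cmp)) NA_real_ else cmp$meanA,
            mean_neg = if (is.null(cmp)) NA_real_ else cmp$meanB,
            t = if (is.null(cmp)) NA_real_ else cmp$t,
            p = if (is.null(cmp)) NA_real_ else cmp$p,
            auc = if (is.null(rr)) NA_real_ else rr$auc)
        if (!is.null(rr)) roc[[nm]] <- rr$points
    }
    contrastTab <- do.call(rbind, rows)
    rownames(contrastTab) <- NULL
    timeAnalyses <- list()
    for (g in c("recurrent", "HT_YES")) {
        ids <- strata[[g]]
        tm <- cd[ids, "recurrence_time_days"]
        sc <- scores[ids]
        timeAnalyses[[g]] <- list(
            correlation = .tryNA(scoreTimeCorrelation(sc, tm)),
            timeSplit = .tryNA(medianSplitCompare(tm, sc, "time")),
            scoreSplit = .tryNA(medianSplitCompare(sc, tm, "score")))
    }
    report <- list(panel = if (is(panel, "GeneSet")) setName(panel) else
                       "custom",
                   scores = scores, contrasts = contrastTab,
                   timeAnalyses = timeAnalyses, roc = roc)
    if (!is.null(outDir)) .writeEvaluationReport(report, outDir)
    report
}

.writeEvaluationReport <- function(report, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.table(report$contrasts, file.path(outDir, "report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    js <- report
    js$scores <- as.list(report$scores)
    js$roc <- NULL
    jsonlite::write_json(js, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    for (nm in names(report$roc))
        write.table(report$roc[[nm]],
                    file.path(outDir, paste0("roc_", nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}
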