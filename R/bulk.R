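#' @importFrom stats pt p.adjust var median
NULL

#' Stratify a bulk cohort by phenotype rules
#'
#' Applies the phenotype rules that define the analysis groups: normal
#' samples are \code{sample_type == "Solid Tissue Normal"}; every other
#' sample is tumor; recurrent / non-recurrent are tumor samples with
#' recurrence YES / NO; HT_YES and HT_NO are the recurrent and
#' non-recurrent samples whose therapy type contains "Hormone Therapy"
#' (substring, case-insensitive, since several therapies can be recorded
#' together). Samples with a missing field are excluded from the dependent
#' strata only, so {normal, tumor} always partitions the cohort.
#'
#' @param x a SummarizedExperiment from \code{\link{readBulkCohort}} /
#'   \code{\link{simulateBulk}}, or a data.frame of phenotypes with sample
#'   ids as rownames and columns \code{sample_type}, \code{recurrence},
#'   \code{therapy_type}.
#' @return named list of sample-id character vectors: \code{normal},
#'   \code{tumor}, \code{recurrent}, \code{non_recurrent}, \code{HT_YES},
#'   \code{HT_NO}.
#' @examples
#' ph <- data.frame(sample_type = c("Solid Tissue Normal", "Primary Tumor"),
#'                  recurrence = c(NA, "YES"),
#'                  therapy_type = c(NA, "Hormone Therapy"),
#'                  row.names = c("s1", "s2"))
#' stratifyCohort(ph)
#' @export
stratifyCohort <- function(x) {
    ph <- if (is(x, "SummarizedExperiment"))
        as.data.frame(SummarizedExperiment::colData(x)) else as.data.frame(x)
    ids <- rownames(ph)
    if (is.null(ids)) stop("phenotype table needs sample ids", call. = FALSE)
    st <- as.character(ph$sample_type)
    rec <- toupper(as.character(ph$recurrence))
    tt <- as.character(ph$therapy_type)
    isNormal <- !is.na(st) & st == "Solid Tissue Normal"
    isTumor <- !isNormal
    isRec <- isTumor & !is.na(rec) & rec == "YES"
    isNonRec <- isTumor & !is.na(rec) & rec == "NO"
    isHT <- !is.na(tt) & grepl("hormone therapy", tolower(tt), fixed = TRUE)
    strata <- list(normal = ids[isNormal],
                   tumor = ids[isTumor],
                   recurrent = ids[isRec],
                   non_recurrent = ids[isNonRec],
                   HT_YES = ids[isRec & isHT],
                   HT_NO = ids[isNonRec & isHT])
    empty <- names(strata)[lengths(strata) == 0L]
    if (length(empty))
        message("empty strata: ", paste(empty, collapse = ", "))
    strata
}

#' Moderated two-sample t-test
#'
#' Pooled-variance two-sample t-statistic with empirical-Bayes-style
#' variance shrinkage: the gene-wise pooled variance s^2 (df
#' d = n1 + n2 - 2) is shrunk toward a prior variance s0^2 with prior
#' degrees of freedom d0,
#' \deqn{\tilde s^2 = (d0 s0^2 + d s^2) / (d0 + d),}
#' and the statistic \eqn{t = (\bar x - \bar y)/\sqrt{\tilde s^2 (1/n1 +
#' 1/n2)}} is referred to a t distribution with d0 + d degrees of freedom.
#' With \code{d0 = 0} this is exactly the ordinary pooled two-sample t-test.
#' For matrix input the default prior variance is the median of the
#' gene-wise pooled variances (a trend-free shrinkage target).
#'
#' When both groups have zero variance and the effective prior variance is
#' zero, the test is degenerate: t = 0 and p = 1 are returned with the
#' result's \code{degenerate} flag set.
#'
#' @param x,y numeric vectors, or matrices with genes in rows and the same
#'   row order (tested row-wise).
#' @param d0 prior degrees of freedom (default 4).
#' @param s02 prior variance; default for matrix input is the median
#'   gene-wise pooled variance, required explicitly for vector input when
#'   \code{d0 > 0}.
#' @return list with elements \code{t}, \code{p}, \code{df} (scalars or
#'   per-gene vectors) and logical \code{degenerate}.
#' @examples
#' moderatedT(c(2, 4), c(0, 2), d0 = 0)   # ordinary pooled t
#' @export
moderatedT <- function(x, y, d0 = 4, s02 = NULL) {
    vec <- is.null(dim(x))
    x <- rbind(x); y <- rbind(y)
    if (vec) { x <- matrix(as.numeric(x), 1L); y <- matrix(as.numeric(y), 1L) }
    if (nrow(x) != nrow(y))
        stop("x and y must have the same number of genes", call. = FALSE)
    n1 <- ncol(x); n2 <- ncol(y)
    if (n1 < 2L || n2 < 2L)
        stop("need at least 2 observations per group", call. = FALSE)
    d <- n1 + n2 - 2
    v1 <- apply(x, 1L, var); v2 <- apply(y, 1L, var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    if (is.null(s02)) {
        if (d0 > 0 && vec)
            stop("provide 's02' (or d0 = 0) for single-gene input",
                 call. = FALSE)
        s02 <- if (d0 > 0) median(s2) else 0
    }
    st2 <- if (is.infinite(d0)) rep_len(s02, length(s2))
           else (d0 * s02 + d * s2) / (d0 + d)
    se <- sqrt(st2 * (1 / n1 + 1 / n2))
    delta <- rowMeans(x) - rowMeans(y)
    degenerate <- st2 == 0
    t <- ifelse(degenerate, 0, delta / se)
    p <- ifelse(degenerate, 1, 2 * pt(-abs(t), df = d0 + d))
    if (vec) list(t = t[[1L]], p = p[[1L]], df = d0 + d,
                  degenerate = degenerate[[1L]])
    else list(t = unname(t), p = unname(p), df = d0 + d,
              degenerate = unname(degenerate))
}

#' Differential-expression screen between two sample groups
#'
#' Screens genes between two sample groups on a bulk cohort: the effect
#' size is the log2 ratio of group mean CPM (pseudocount 1 on the CPM
#' scale), significance comes from the moderated t-test
#' (\code{\link{moderatedT}}) on \code{log2(CPM+1)} values with
#' Benjamini-Hochberg adjustment over all tested genes, and genes are
#' called up / down at \code{|log2FC| > lfcCut} and adjusted p below
#' \code{fdrCut} (defaults 1 and 0.05).
#'
#' @param x SummarizedExperiment (assay \code{counts} or \code{expr}) or a
#'   non-negative genes x samples matrix.
#' @param groupA,groupB disjoint character vectors of sample ids (or
#'   integer column indices); the log2 fold change is A over B.
#' @param lfcCut,fdrCut significance cutoffs.
#' @param d0,s02 moderated-t prior (see \code{\link{moderatedT}}).
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{p_raw}, \code{p_adj}, \code{direction} (up/down/ns).
#' @export
deScreen <- function(x, groupA, groupB, lfcCut = 1, fdrCut = 0.05,
                     d0 = 4, s02 = NULL) {
    m <- if (is(x, "SummarizedExperiment")) {
        an <- SummarizedExperiment::assayNames(x)
        nm <- if ("counts" %in% an) "counts" else if ("expr" %in% an) "expr"
              else an[1L]
        as.matrix(SummarizedExperiment::assay(x, nm))
    } else as.matrix(x)
    .checkFiniteNonNegative(m, "expression matrix")
    if (is.character(groupA)) groupA <- match(groupA, colnames(m))
    if (is.character(groupB)) groupB <- match(groupB, colnames(m))
    if (anyNA(groupA) || anyNA(groupB))
        stop("unknown sample ids in group definitions", call. = FALSE)
    if (length(intersect(groupA, groupB)))
        stop("groups overlap", call. = FALSE)
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("need at least 2 samples per group", call. = FALSE)
    cpm <- sweep(m, 2L, colSums(m), "/") * 1e6
    log2fc <- log2((rowMeans(cpm[, groupA, drop = FALSE]) + 1) /
                   (rowMeans(cpm[, groupB, drop = FALSE]) + 1))
    lm2 <- log2(cpm + 1)
    mt <- moderatedT(lm2[, groupA, drop = FALSE],
                     lm2[, groupB, drop = FALSE], d0 = d0, s02 = s02)
    p_adj <- p.adjust(mt$p, method = "BH")
    direction <- rep("ns", nrow(m))
    direction[log2fc > lfcCut & p_adj < fdrCut] <- "up"
    direction[log2fc < -lfcCut & p_adj < fdrCut] <- "down"
    res <- data.frame(gene = rownames(m), log2fc = unname(log2fc),
                      p_raw = mt$p, p_adj = p_adj, direction = direction,
                      row.names = NULL)
    attr(res, "method") <- sprintf(
        "meanCPM log-ratio + moderated t (d0=%g) + BH", d0)
    res
}
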