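.stars <- function(p) {
    if (is.na(p)) return("")
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
    else "ns"
}

#' Sum-of-z-score module score
#'
#' Scores each cell or sample for a gene set as the sum of its per-gene
#' z-scores over the set's genes present in the matrix. Genes absent from
#' the matrix are skipped and reported; a set with no overlap at all is an
#' error. The score is exactly linear over disjoint gene sets on the same
#' z-matrix.
#'
#' @param z z-score matrix (genes x units), e.g. from
#'   \code{\link{zscoreByGene}}.
#' @param set a \linkS4class{GeneSet} or character vector of gene symbols.
#' @return named numeric vector of scores with attributes
#'   \code{genesUsed} and \code{genesSkipped}.
#' @examples
#' z <- matrix(c(0.5, -0.5, 2), 3, 1,
#'             dimnames = list(c("a", "b", "c"), "cell1"))
#' moduleScore(z, GeneSet("s", c("a", "b", "c")))
#' @export
moduleScore <- function(z, set) {
    genes <- if (is(set, "GeneSet")) geneIds(set) else as.character(set)
    nm <- if (is(set, "GeneSet")) setName(set) else "gene set"
    z <- as.matrix(z)
    used <- intersect(genes, rownames(z))
    if (!length(used))
        stop("no genes of set '", nm, "' (",
             paste(utils::head(genes, 10L), collapse = ", "),
             ") found in matrix", call. = FALSE)
    skipped <- setdiff(genes, used)
    if (length(skipped))
        message(length(skipped), " gene(s) of '", nm,
                "' absent from matrix: ", paste(skipped, collapse = ", "))
    s <- colSums(z[used, , drop = FALSE])
    attr(s, "genesUsed") <- used
    attr(s, "genesSkipped") <- skipped
    s
}

#' Compare module scores between two groups
#'
#' Welch (unequal-variance) two-sample t-test on module scores between two
#' unit groups, with significance stars at 0.05 / 0.01 / 0.001 for
#' reporting. When both groups have zero variance the comparison is
#' degenerate and t = 0, p = 1 is returned flagged.
#'
#' @param scores named numeric vector of scores (see
#'   \code{\link{moduleScore}}).
#' @param groupA,groupB character vectors of unit ids (or numeric values
#'   directly if \code{scores} is unnamed and groups are indices).
#' @param pooled use the pooled-variance (classical Student) test instead
#'   of Welch.
#' @return list with \code{meanA}, \code{meanB}, \code{t}, \code{df},
#'   \code{p}, \code{stars}, \code{degenerate}.
#' @export
compareScores <- function(scores, groupA, groupB, pooled = FALSE) {
    pick <- function(g) {
        if (is.character(g)) {
            i <- match(g, names(scores))
            if (anyNA(i)) stop("unknown unit ids", call. = FALSE)
            scores[i]
        } else scores[g]
    }
    a <- pick(groupA); b <- pick(groupB)
    if (length(a) < 2L || length(b) < 2L)
        stop("need at least 2 units per group", call. = FALSE)
    wt <- .welch(a, b, pooled = pooled)
    c(list(meanA = mean(a), meanB = mean(b)), wt,
      list(stars = .stars(wt$p)))
}

## Welch / pooled two-sample t; closed form (checked against t.test).
.welch <- function(a, b, pooled = FALSE) {
    n1 <- length(a); n2 <- length(b)
    v1 <- var(a); v2 <- var(b)
    if (v1 == 0 && v2 == 0)
        return(list(t = 0, df = n1 + n2 - 2, p = 1, degenerate = TRUE))
    if (pooled) {
        df <- n1 + n2 - 2
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    t <- (mean(a) - mean(b)) / se
    list(t = t, df = df, p = 2 * pt(-abs(t), df = df), degenerate = FALSE)
}

#' Identify subgroup-featured genes
#'
#' Calls a gene "featured" for the subgroup in which its mean normalized
#' expression is strictly highest, provided (i) a one-vs-rest moderated
#' t-test of that subgroup against all remaining cells is significant after
#' Benjamini-Hochberg adjustment over all tested genes, and (ii) the gene
#' is expressed (raw count > 0, i.e. normalized value > 0) in more than
#' \code{minFrac} of the subgroup's cells. Ties for the maximal mean
#' disqualify a gene; each gene is featured for at most one subgroup.
#'
#' @param m normalized \code{log2(CPM+1)} matrix (genes x cells) or a
#'   SummarizedExperiment carrying one.
#' @param ann per-cell annotation with a \code{subgroup} column, ordered as
#'   the columns of \code{m}.
#' @param minFrac minimum expressed fraction within the featured subgroup
#'   (default 0.20, exceeded strictly).
#' @param fdr BH-adjusted significance cutoff (default 0.05).
#' @param d0 moderated-t prior degrees of freedom.
#' @return data.frame with columns \code{gene}, \code{subgroup},
#'   \code{mean_in_subgroup}, \code{max_other_mean},
#'   \code{expressed_fraction}, \code{t}, \code{p_adj}.
#' @export
featuredGenes <- function(m, ann, minFrac = 0.20, fdr = 0.05, d0 = 4) {
    v <- .getLogcpm(m)
    ann <- .getAnnotation(ann)
    if (nrow(ann) != ncol(v))
        stop("annotation rows must match matrix columns", call. = FALSE)
    groups <- sort(unique(ann$subgroup))
    if (length(groups) < 2L)
        stop("need at least 2 subgroups", call. = FALSE)
    sizes <- table(ann$subgroup)
    if (any(sizes < 3L))
        stop("every subgroup needs at least 3 cells", call. = FALSE)
    means <- vapply(groups, function(g)
        rowMeans(v[, ann$subgroup == g, drop = FALSE]), numeric(nrow(v)))
    top <- max.col(means, ties.method = "first")
    maxv <- means[cbind(seq_len(nrow(v)), top)]
    nmax <- rowSums(means == maxv)
    tied <- nmax > 1L
    if (any(tied))
        message(sum(tied), " gene(s) with tied maximal subgroup mean not ",
                "considered")
    ## one-vs-rest moderated t per subgroup, vectorized over genes
    tmat <- pmat <- matrix(NA_real_, nrow(v), length(groups))
    for (k in seq_along(groups)) {
        ink <- ann$subgroup == groups[k]
        mt <- moderatedT(v[, ink, drop = FALSE], v[, !ink, drop = FALSE],
                         d0 = d0)
        tmat[, k] <- mt$t; pmat[, k] <- mt$p
    }
    test <- which(!tied)
    praw <- pmat[cbind(test, top[test])]
    padj <- p.adjust(praw, method = "BH")
    frac <- vapply(seq_along(test), function(i) {
        g <- test[i]
        ink <- ann$subgroup == groups[top[g]]
        mean(v[g, ink] > 0)
    }, numeric(1L))
    other <- vapply(seq_along(test), function(i) {
        g <- test[i]
        max(means[g, -top[g]])
    }, numeric(1L))
    keep <- padj < fdr & frac > minFrac
    data.frame(gene = rownames(v)[test][keep],
               subgroup = groups[top[test]][keep],
               mean_in_subgroup = maxv[test][keep],
               max_other_mean = other[keep],
               expressed_fraction = frac[keep],
               t = tmat[cbind(test, top[test])][keep],
               p_adj = padj[keep],
               row.names = NULL)
}

#' Score a bulk cohort for a gene panel
#'
#' Z-scores each panel gene across the samples of the scaling stratum on
#' the \code{log2(x + 1)} scale of the provided expression values, then
#' sums over the panel (the same sum-of-z machinery as
#' \code{\link{moduleScore}}). The default stratum is all samples of the
#' cohort, appropriate when scores are subsequently compared across its
#' groups.
#'
#' @param x SummarizedExperiment with an \code{expr} assay, or a
#'   non-negative genes x samples matrix.
#' @param panel a \linkS4class{GeneSet} or character vector.
#' @param samples optional sample ids restricting the scaling stratum.
#' @param log2Transform apply \code{log2(x + 1)} before z-scoring
#'   (default TRUE; set FALSE for already-log expression).
#' @return named numeric vector of per-sample scores (attributes as in
#'   \code{\link{moduleScore}}, plus \code{scale}).
#' @export
panelScoreBulk <- function(x, panel, samples = NULL, log2Transform = TRUE) {
    m <- if (is(x, "SummarizedExperiment")) {
        an <- SummarizedExperiment::assayNames(x)
        nm <- if ("expr" %in% an) "expr" else an[1L]
        as.matrix(SummarizedExperiment::assay(x, nm))
    } else as.matrix(x)
    .checkFiniteNonNegative(m, "bulk expression")
    if (!is.null(samples)) {
        i <- match(samples, colnames(m))
        if (anyNA(i)) stop("unknown sample ids", call. = FALSE)
        m <- m[, i, drop = FALSE]
    }
    if (log2Transform) m <- log2(m + 1)
    z <- zscoreByGene(m)
    s <- moduleScore(z, panel)
    attr(s, "scale") <- if (log2Transform) "log2(x+1)" else "as-provided"
    s
}
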