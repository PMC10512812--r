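#' @importFrom stats sd cor
NULL

## Half-up rounding (round() is round-half-even); used for printed percents.
.roundHalfUp <- function(x, digits = 2L) {
    floor(x * 10^digits + 0.5) / 10^digits
}

#' Log2 counts-per-million normalization
#'
#' Normalizes a genes x cells (or samples) count matrix to
#' \code{log2(CPM + 1)}: each column is scaled to one million total counts
#' before the log transform, making values comparable across cells and
#' datasets. The CPM denominator is the total count over all genes present
#' in the matrix as loaded; no gene filtering is applied first. A zero count
#' maps to exactly 0.
#'
#' @param x a counts matrix with dimnames, or a
#'   SummarizedExperiment/SingleCellExperiment with a \code{counts} assay.
#' @return for a matrix, the normalized matrix; for a
#'   SummarizedExperiment, the object with an added \code{logcpm} assay.
#' @examples
#' m <- matrix(c(9, 1), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
#' log2CPM(m)
#' @export
setGeneric("log2CPM", function(x) standardGeneric("log2CPM"))

.log2cpm <- function(m) {
    .checkFiniteNonNegative(m, "count matrix")
    tot <- colSums(m)
    if (any(tot == 0))
        stop("cells with zero total count: ",
             paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
    log2(sweep(m, 2L, tot, "/") * 1e6 + 1)
}

#' @rdname log2CPM
#' @export
setMethod("log2CPM", "matrix", function(x) .log2cpm(x))

#' @rdname log2CPM
#' @export
setMethod("log2CPM", "SummarizedExperiment", function(x) {
    SummarizedExperiment::assay(x, "logcpm") <- .log2cpm(.getCounts(x))
    x
})

## logcpm values from whatever the caller handed us.
.getLogcpm <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if ("logcpm" %in% SummarizedExperiment::assayNames(x))
            return(as.matrix(SummarizedExperiment::assay(x, "logcpm")))
        return(.log2cpm(.getCounts(x)))
    }
    as.matrix(x)
}

#' Per-gene z-score transformation
#'
#' Centers and scales each gene (row) to mean 0 and sample standard
#' deviation 1 (n - 1 denominator), optionally within strata of cells
#' (default stratification in cross-dataset work: per dataset, to absorb
#' batch differences in location/scale). Genes with zero variance within a
#' stratum map to all zeros rather than NaN.
#'
#' @param m numeric matrix (genes x cells), e.g. \code{log2(CPM+1)} values.
#' @param strata optional factor/vector over columns defining scaling
#'   strata; \code{NULL} scales over all columns at once.
#' @return matrix of z-scores, same dimensions and dimnames.
#' @export
zscoreByGene <- function(m, strata = NULL) {
    m <- as.matrix(m)
    if (is.null(strata)) strata <- rep("all", ncol(m))
    if (length(strata) != ncol(m))
        stop("'strata' must have one entry per column", call. = FALSE)
    out <- m
    for (s in unique(strata)) {
        j <- which(strata == s)
        if (length(j) < 2L)
            stop("scaling stratum '", s, "' has fewer than 2 columns",
                 call. = FALSE)
        mu <- rowMeans(m[, j, drop = FALSE])
        sdv <- apply(m[, j, drop = FALSE], 1L, sd)
        z <- (m[, j, drop = FALSE] - mu) / sdv
        z[sdv == 0, ] <- 0
        out[, j] <- z
    }
    out
}

#' Subgroup cell-composition summary
#'
#' Counts cells per subgroup within one (dataset, lineage) block and
#' reports each subgroup's percentage of the block, rounded half-up to two
#' decimals (matching how such compositions are conventionally printed).
#'
#' @param ann per-cell annotation: data.frame (or SummarizedExperiment
#'   colData) with columns \code{dataset_id}, \code{lineage},
#'   \code{subgroup}.
#' @param dataset,lineage values selecting the block; \code{NULL} keeps all.
#' @return data.frame with columns dataset_id, subgroup, n_cells, percent.
#' @examples
#' ann <- data.frame(dataset_id = "D", lineage = "epithelial",
#'                   subgroup = rep(c("basal", "luminal"), c(1, 3)))
#' composition(ann, "D", "epithelial")
#' @export
composition <- function(ann, dataset = NULL, lineage = NULL) {
    ann <- .getAnnotation(ann)
    keep <- rep(TRUE, nrow(ann))
    if (!is.null(dataset)) keep <- keep & ann$dataset_id %in% dataset
    if (!is.null(lineage)) keep <- keep & ann$lineage %in% lineage
    ann <- ann[keep, , drop = FALSE]
    if (!nrow(ann)) {
        warning("no cells selected")
        return(data.frame(dataset_id = character(), subgroup = character(),
                          n_cells = integer(), percent = numeric()))
    }
    tab <- as.data.frame(table(subgroup = ann$subgroup),
                         stringsAsFactors = FALSE)
    names(tab)[2L] <- "n_cells"
    tab <- tab[tab$n_cells > 0, , drop = FALSE]
    data.frame(dataset_id = if (is.null(dataset)) NA_character_ else
                   paste(dataset, collapse = ","),
               subgroup = tab$subgroup,
               n_cells = tab$n_cells,
               percent = .roundHalfUp(100 * tab$n_cells / sum(tab$n_cells)),
               row.names = NULL)
}

#' Mean expression profile per subgroup
#'
#' Arithmetic mean of normalized expression (\code{log2(CPM+1)}) per gene
#' within each cell subgroup, the pseudobulk profiles used for
#' subgroup-to-subgroup similarity.
#'
#' @param m normalized matrix (genes x cells) or a SummarizedExperiment
#'   carrying one.
#' @param ann per-cell annotation with a \code{subgroup} column, ordered as
#'   the columns of \code{m}.
#' @return matrix subgroups x genes.
#' @export
subgroupMeanProfiles <- function(m, ann) {
    v <- .getLogcpm(m)
    ann <- .getAnnotation(ann)
    if (nrow(ann) != ncol(v))
        stop("annotation rows must match matrix columns", call. = FALSE)
    groups <- unique(ann$subgroup)
    empty <- setdiff(groups, unique(ann$subgroup[!is.na(ann$subgroup)]))
    if (length(empty))
        warning("dropping empty subgroup(s): ", paste(empty, collapse = ", "))
    groups <- setdiff(groups, empty)
    prof <- do.call(rbind, lapply(groups, function(g)
        rowMeans(v[, ann$subgroup == g, drop = FALSE])))
    dimnames(prof) <- list(groups, rownames(v))
    prof
}

#' Pearson similarity between subgroup profiles
#'
#' Pairwise Pearson correlation between subgroup mean-expression profiles
#' over their common gene universe. A constant profile has no defined
#' correlation and is reported as \code{NA}, never coerced to 0; the
#' diagonal is fixed at 1.
#'
#' @param profiles matrix subgroups x genes (see
#'   \code{\link{subgroupMeanProfiles}}).
#' @return symmetric matrix of Pearson r with unit diagonal.
#' @export
similarityMatrix <- function(profiles) {
    profiles <- as.matrix(profiles)
    if (nrow(profiles) < 1L) stop("no profiles", call. = FALSE)
    n <- nrow(profiles)
    r <- matrix(NA_real_, n, n,
                dimnames = list(rownames(profiles), rownames(profiles)))
    sds <- apply(profiles, 1L, sd)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) { r[i, j] <- 1; next }
        if (sds[i] == 0 || sds[j] == 0) next  # undefined, stays NA
        r[i, j] <- cor(profiles[i, ], profiles[j, ])
    }
    r
}
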