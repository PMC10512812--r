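#' @importFrom stats rnbinom rpois rnorm rlnorm runif
NULL

#' Simulate a single-cell cohort with planted subgroup markers
#'
#' Draws negative-binomial counts (variance = mean + dispersion x mean^2,
#' dispersion shared across genes) for a set of cell subgroups. Each
#' subgroup owns a disjoint block of marker genes whose mean is elevated
#' \code{2^markerLog2FC}-fold in that subgroup; all other gene/cell means
#' are \code{baselineMean}. Per-cell library-size factors are drawn
#' log-normal (sd \code{libSizeSd}) so that CPM normalization is
#' non-trivial. Optionally a ligand/receptor co-elevation is planted: the
#' ligand gene's mean is multiplied by \code{fold} in the source subgroup
#' and the receptor gene's in the target subgroup. One global RNG stream is
#' seeded once; the draw order (library factors, then counts column-major)
#' is fixed, so identical configurations and seeds give identical output.
#'
#' @param nGenes number of genes.
#' @param cellsPerSubgroup integer vector of subgroup sizes (its length
#'   sets the number of subgroups; a scalar with \code{nSubgroups} also
#'   works).
#' @param nSubgroups number of subgroups when \code{cellsPerSubgroup} is
#'   scalar.
#' @param markersPerSubgroup planted markers per subgroup (disjoint across
#'   subgroups; their total must not exceed \code{nGenes}).
#' @param markerLog2FC log2 fold elevation of a marker in its home
#'   subgroup.
#' @param baselineMean baseline negative-binomial mean per gene and cell.
#' @param nbDispersion dispersion; 0 gives the Poisson limit.
#' @param libSizeSd log-normal sd of per-cell library-size factors.
#' @param lrPlant optional list(ligand, receptor, source, target, fold)
#'   naming genes and subgroups for a planted ligand-receptor co-elevation.
#' @param lineage lineage label written to the annotation.
#' @param seed RNG seed.
#' @return list with \code{sce} (SingleCellExperiment: \code{counts} assay,
#'   colData \code{dataset_id}/\code{lineage}/\code{subgroup}),
#'   \code{truth} (data.frame of planted marker genes and their home
#'   subgroup) and \code{config}.
#' @examples
#' sim <- simulateSC(nGenes = 50, cellsPerSubgroup = c(20, 20), seed = 1)
#' table(SummarizedExperiment::colData(sim$sce)$subgroup)
#' @export
simulateSC <- function(nGenes = 300, cellsPerSubgroup = 200, nSubgroups = 3,
                       markersPerSubgroup = 10, markerLog2FC = 3,
                       baselineMean = 0.5, nbDispersion = 0.5,
                       libSizeSd = 0.3, lrPlant = NULL,
                       lineage = "epithelial", seed = 1L) {
    if (length(cellsPerSubgroup) == 1L)
        cellsPerSubgroup <- rep(cellsPerSubgroup, nSubgroups)
    nSub <- length(cellsPerSubgroup)
    if (markersPerSubgroup * nSub > nGenes)
        stop("more planted markers than genes", call. = FALSE)
    if (baselineMean <= 0 || markerLog2FC < 0 || nbDispersion < 0)
        stop("invalid simulation parameters", call. = FALSE)
    subgroups <- paste0("SG", seq_len(nSub))
    genes <- sprintf("G%04d", seq_len(nGenes))
    nCells <- sum(cellsPerSubgroup)
    cells <- sprintf("C%05d", seq_len(nCells))
    cellSub <- rep(subgroups, cellsPerSubgroup)
    ## planted marker blocks: genes 1..m for SG1, m+1..2m for SG2, ...
    truth <- data.frame(
        gene = genes[seq_len(markersPerSubgroup * nSub)],
        subgroup = rep(subgroups, each = markersPerSubgroup),
        stringsAsFactors = FALSE)
    mu <- matrix(baselineMean, nGenes, nCells, dimnames = list(genes, cells))
    for (k in seq_len(nSub)) {
        gk <- truth$gene[truth$subgroup == subgroups[k]]
        mu[gk, cellSub == subgroups[k]] <- baselineMean * 2^markerLog2FC
    }
    if (!is.null(lrPlant)) {
        need <- c("ligand", "receptor", "source", "target", "fold")
        if (!all(need %in% names(lrPlant)))
            stop("lrPlant needs ", paste(need, collapse = "/"), call. = FALSE)
        if (!all(c(lrPlant$ligand, lrPlant$receptor) %in% genes))
            stop("lrPlant genes not in gene universe", call. = FALSE)
        mu[lrPlant$ligand, cellSub == lrPlant$source] <-
            mu[lrPlant$ligand, cellSub == lrPlant$source] * lrPlant$fold
        mu[lrPlant$receptor, cellSub == lrPlant$target] <-
            mu[lrPlant$receptor, cellSub == lrPlant$target] * lrPlant$fold
    }
    set.seed(seed)
    libf <- rlnorm(nCells, 0, libSizeSd)
    muScaled <- sweep(mu, 2L, libf, "*")
    counts <- if (nbDispersion > 0)
        rnbinom(nGenes * nCells, mu = as.vector(muScaled),
                size = 1 / nbDispersion)
    else rpois(nGenes * nCells, as.vector(muScaled))
    counts <- matrix(counts, nGenes, nCells, dimnames = dimnames(mu))
    sce <- SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(dataset_id = "sim",
                                       lineage = lineage,
                                       subgroup = cellSub,
                                       row.names = cells))
    list(sce = sce, truth = truth,
         config = list(nGenes = nGenes, cellsPerSubgroup = cellsPerSubgroup,
                       markersPerSubgroup = markersPerSubgroup,
                       markerLog2FC = markerLog2FC,
                       baselineMean = baselineMean,
                       nbDispersion = nbDispersion, libSizeSd = libSizeSd,
                       lrPlant = lrPlant, seed = seed))
}

#' Simulate a bulk cohort with a planted panel effect
#'
#' Generates a log-scale expression matrix (per-gene baselines uniform on
#' [3, 8], Gaussian noise sd \code{exprNoiseSd}, clipped at 0) for five
#' phenotype groups: normal, non-recurrent and recurrent tumor, and
#' hormone-treated non-recurrent / recurrent. Panel genes receive an
#' additive shift \code{panelShift} in the two recurrent groups. The
#' default group sizes follow a TCGA-PRAD-like cohort, in particular 14
#' hormone-treated recurrent vs 53 hormone-treated non-recurrent samples.
#' Each recurrent sample's true planted score is the sum over panel genes
#' of its noise-standardized deviation from baseline, and its recurrence
#' time is \code{max(1, T0 + timeBeta x trueScore + noise)}; a negative
#' \code{timeBeta} plants the expected negative score-time association.
#' One RNG stream, fixed draw order: gene baselines, expression noise
#' (column-major), then time noise.
#'
#' @param nPerGroup named integer vector with entries \code{normal},
#'   \code{tumor_norec}, \code{tumor_rec}, \code{HT_norec}, \code{HT_rec}.
#' @param panel \linkS4class{GeneSet} whose genes carry the planted shift.
#' @param panelShift additive log-scale shift in the recurrent groups.
#' @param timeBeta slope (days per true-score unit) linking score to
#'   recurrence time; negative for the planted negative association.
#' @param timeNoiseSd sd (days) of recurrence-time noise.
#' @param exprNoiseSd sd of expression noise on the log scale.
#' @param nGenes total gene universe (panel genes plus fillers).
#' @param baselineT0 recurrence-time intercept in days.
#' @param seed RNG seed.
#' @return list with \code{se} (SummarizedExperiment: assay \code{expr},
#'   colData \code{sample_type}/\code{recurrence}/\code{therapy_type}/
#'   \code{recurrence_time_days}/\code{group}), \code{truth}
#'   (per-sample group and true score) and \code{config}.
#' @examples
#' sim <- simulateBulk(seed = 1)
#' lengths(stratifyCohort(sim$se))
#' @export
simulateBulk <- function(nPerGroup = c(normal = 52, tumor_norec = 340,
                                       tumor_rec = 45, HT_norec = 53,
                                       HT_rec = 14),
                         panel = crpcPanel6(), panelShift = 2,
                         timeBeta = -40, timeNoiseSd = 100,
                         exprNoiseSd = 1, nGenes = 1000,
                         baselineT0 = 1000, seed = 1L) {
    groups <- c("normal", "tumor_norec", "tumor_rec", "HT_norec", "HT_rec")
    if (!all(groups %in% names(nPerGroup)))
        stop("nPerGroup needs entries ", paste(groups, collapse = "/"),
             call. = FALSE)
    nPerGroup <- nPerGroup[groups]
    panelGenes <- if (is(panel, "GeneSet")) geneIds(panel) else
        as.character(panel)
    if (nGenes < length(panelGenes))
        stop("nGenes smaller than the panel", call. = FALSE)
    genes <- c(panelGenes,
               sprintf("B%04d", seq_len(nGenes - length(panelGenes))))
    nS <- sum(nPerGroup)
    samples <- sprintf("S%04d", seq_len(nS))
    grp <- rep(groups, nPerGroup)
    set.seed(seed)
    baseline <- runif(nGenes, 3, 8)
    noise <- matrix(rnorm(nGenes * nS, 0, exprNoiseSd), nGenes, nS)
    shiftCols <- grp %in% c("tumor_rec", "HT_rec")
    shift <- matrix(0, nGenes, nS)
    shift[genes %in% panelGenes, shiftCols] <- panelShift
    expr <- pmax(baseline + shift + noise, 0)
    dimnames(expr) <- list(genes, samples)
    ## true planted score: noise-standardized panel deviation from baseline
    pIdx <- match(panelGenes, genes)
    trueScore <- colSums((shift + noise)[pIdx, , drop = FALSE]) / exprNoiseSd
    isRec <- grp %in% c("tumor_rec", "HT_rec")
    time <- rep(NA_real_, nS)
    time[isRec] <- pmax(1, baselineT0 + timeBeta * trueScore[isRec] +
                            rnorm(sum(isRec), 0, timeNoiseSd))
    cd <- S4Vectors::DataFrame(
        sample_type = ifelse(grp == "normal", "Solid Tissue Normal",
                             "Primary Tumor"),
        recurrence = ifelse(grp == "normal", NA_character_,
                            ifelse(isRec, "YES", "NO")),
        therapy_type = ifelse(grp %in% c("HT_norec", "HT_rec"),
                              "Hormone Therapy", NA_character_),
        recurrence_time_days = time,
        group = grp, row.names = samples)
    se <- SummarizedExperiment(assays = list(expr = expr), colData = cd)
    list(se = se,
         truth = data.frame(sample_id = samples, group = grp,
                            true_score = unname(trueScore),
                            recurrence_time_days = time,
                            stringsAsFactors = FALSE),
         config = list(nPerGroup = as.list(nPerGroup),
                       panel = panelGenes, panelShift = panelShift,
                       timeBeta = timeBeta, timeNoiseSd = timeNoiseSd,
                       exprNoiseSd = exprNoiseSd, nGenes = nGenes,
                       baselineT0 = baselineT0, seed = seed))
}
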