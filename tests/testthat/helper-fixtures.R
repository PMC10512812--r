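suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

## 4-cell ligand-receptor toy: cells c1,c2 in A express the ligand (2, 4),
## cells c3,c4 in B express the receptor (1, 3); one L->R pair.
## Observed intensity = mean(2,4) * mean(1,3) = 6, the unique maximum over
## the 6 distinct {A-cells, B-cells} arrangements.
lrToy <- function() {
    v <- matrix(0, 2, 4, dimnames = list(c("L", "R"), paste0("c", 1:4)))
    v["L", ] <- c(2, 4, 0, 0)
    v["R", ] <- c(0, 0, 1, 3)
    list(v = v,
         ann = data.frame(subgroup = c("A", "A", "B", "B"),
                          row.names = colnames(v)),
         model = LRModel(secreted = "L", membrane = "R",
                         pairs = rbind(c("L", "R"))))
}

## tiny bulk cohort phenotype table exercising all stratification rules
strataToyPheno <- function() {
    data.frame(
        sample_type = c("Solid Tissue Normal", "Primary Tumor",
                        "Primary Tumor", "Primary Tumor", "Primary Tumor",
                        "Primary Tumor"),
        recurrence = c(NA, "YES", "NO", "YES", "NO", NA),
        therapy_type = c(NA, "Hormone Therapy", "Chemotherapy",
                         "Chemotherapy; hormone therapy", "Hormone Therapy",
                         "Hormone Therapy"),
        row.names = paste0("s", 1:6))
}

## brute-force pairwise-counting AUC: (wins + half ties) / (n1 * n0)
bruteForceAuc <- function(scores, labels) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
}

## double-loop Pearson correlation matrix, independent of similarityMatrix
bruteForcePearson <- function(profiles) {
    n <- nrow(profiles)
    r <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        x <- profiles[i, ]; y <- profiles[j, ]
        r[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
            sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    }
    dimnames(r) <- list(rownames(profiles), rownames(profiles))
    r
}

## small dense count matrix with dimnames
toyCounts <- function(nGenes = 5, nCells = 4, seed = 42) {
    set.seed(seed)
    m <- matrix(rpois(nGenes * nCells, 5) + 1, nGenes, nCells,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("c%02d", seq_len(nCells))))
    m
}

## featured-gene recovery for one simulated seed: returns recovered and
## falsely-called counts plus totals
featuredRecoveryOneSeed <- function(seed) {
    sim <- simulateSC(seed = seed)
    v <- log2CPM(as.matrix(assay(sim$sce, "counts")))
    fg <- featuredGenes(v, colData(sim$sce))
    truthKeys <- paste(sim$truth$gene, sim$truth$subgroup)
    callKeys <- paste(fg$gene, fg$subgroup)
    c(recovered = sum(truthKeys %in% callKeys),
      planted = length(truthKeys),
      false = sum(!fg$gene %in% sim$truth$gene),
      nonMarkers = nrow(v) - length(unique(sim$truth$gene)))
}
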