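#' @importFrom utils combn
NULL

#' Directed ligand-receptor candidates from an annotation model
#'
#' Expands the unordered interaction pairs of an \linkS4class{LRModel} into
#' directed (ligand, receptor) candidates: a direction L -> R is emitted
#' whenever L is secreted and R is membrane-bound. A gene annotated as both
#' secreted and membrane can appear on either side, so one unordered pair
#' can yield two directed candidates.
#'
#' @param model an \linkS4class{LRModel}.
#' @return data.frame with columns \code{ligand}, \code{receptor}
#'   (deduplicated directed pairs).
#' @export
lrPairs <- function(model) {
    stopifnot(is(model, "LRModel"))
    p <- model@pairs
    out <- matrix(character(), 0L, 2L)
    if (nrow(p)) {
        a <- p[, 1L]; b <- p[, 2L]
        ab <- a %in% model@secreted & b %in% model@membrane
        ba <- b %in% model@secreted & a %in% model@membrane & a != b
        out <- rbind(cbind(a[ab], b[ab]), cbind(b[ba], a[ba]))
        out <- unique(out)
    }
    data.frame(ligand = out[, 1L], receptor = out[, 2L],
               stringsAsFactors = FALSE)
}

## Total intensity + per-pair contributions for given cell index sets.
.lrCompute <- function(v, idxA, idxB, lig, rec) {
    mA <- rowMeans(v[, idxA, drop = FALSE])
    mB <- rowMeans(v[, idxB, drop = FALSE])
    mA[lig] * mB[rec]
}

.lrSetup <- function(m, ann, model, source, target) {
    v <- .getLogcpm(m)
    ann <- .getAnnotation(ann)
    if (nrow(ann) != ncol(v))
        stop("annotation rows must match matrix columns", call. = FALSE)
    idxA <- which(ann$subgroup == source)
    idxB <- which(ann$subgroup == target)
    if (!length(idxA) || !length(idxB))
        stop("source/target subgroup has no cells", call. = FALSE)
    cand <- lrPairs(model)
    usable <- cand$ligand %in% rownames(v) & cand$receptor %in% rownames(v)
    cand <- cand[usable, , drop = FALSE]
    if (!nrow(cand))
        warning("no usable ligand-receptor pairs; intensity is 0")
    genes <- unique(c(cand$ligand, cand$receptor))
    list(v = v[genes, , drop = FALSE], ann = ann, idxA = idxA, idxB = idxB,
         lig = cand$ligand, rec = cand$receptor)
}

.lrSortContributions <- function(lig, rec, contrib) {
    d <- data.frame(ligand = lig, receptor = rec,
                    contribution = unname(contrib),
                    stringsAsFactors = FALSE)
    d[order(-d$contribution, d$ligand, d$receptor), , drop = FALSE]
}

#' Ligand-receptor communication intensity between two subgroups
#'
#' For every directed candidate pair (ligand secreted, receptor
#' membrane-bound) the contribution is the mean ligand expression over the
#' source subgroup's cells times the mean receptor expression over the
#' target subgroup's cells, on the \code{log2(CPM+1)} scale; the total
#' intensity is the sum over all pairs. Source and target may coincide
#' (autocrine signalling).
#'
#' @param m normalized matrix (genes x cells), a SummarizedExperiment with
#'   a \code{logcpm} assay, or raw counts (normalized on the fly).
#' @param ann per-cell annotation with a \code{subgroup} column.
#' @param model an \linkS4class{LRModel}.
#' @param source,target subgroup labels (ligand-sending, receptor-bearing).
#' @return an \linkS4class{LRIntensity} (no permutation p-value; see
#'   \code{\link{lrPermutationP}}).
#' @export
lrIntensity <- function(m, ann, model, source, target) {
    s <- .lrSetup(m, ann, model, source, target)
    contrib <- if (length(s$lig))
        .lrCompute(s$v, s$idxA, s$idxB, s$lig, s$rec) else numeric()
    pc <- .lrSortContributions(s$lig, s$rec, contrib)
    rownames(pc) <- NULL
    new("LRIntensity", source = source, target = target,
        intensity = sum(contrib), pairContributions = pc,
        pPerm = NA_real_, nPerm = 0L, method = "none", seed = NA_integer_)
}

## All distinct (A-cells, B-cells) assignments as a list of index pairs,
## or NULL when their number exceeds `cap`.
.lrArrangements <- function(n, nA, nB, same, cap) {
    total <- if (same) choose(n, nA) else choose(n, nA) * choose(n - nA, nB)
    if (total > cap) return(NULL)
    out <- vector("list", 0L)
    As <- combn(n, nA, simplify = FALSE)
    if (same) return(lapply(As, function(a) list(a, a)))
    for (a in As) {
        rest <- setdiff(seq_len(n), a)
        for (b in combn(rest, nB, simplify = FALSE))
            out[[length(out) + 1L]] <- list(a, b)
    }
    out
}

#' Permutation p-value for ligand-receptor intensity
#'
#' Tests whether the observed intensity between two subgroups exceeds what
#' label-shuffling produces: subgroup labels are permuted across all
#' annotated cells (subgroup sizes preserved) and the intensity recomputed;
#' the p-value is \code{(1 + #\{permuted >= observed\}) / (1 + nPerm)}
#' (add-one estimator, never exactly 0; ties count against the observed
#' statistic). When the number of distinct label arrangements is at most
#' \code{exhaustiveCap}, all arrangements are enumerated instead and the
#' p-value is the exact proportion of arrangements with intensity at least
#' the observed one (the observed arrangement included).
#'
#' @inheritParams lrIntensity
#' @param nPerm number of sampled permutations (default 1000).
#' @param seed RNG seed for the sampled mode (recorded in the result).
#' @param scope shuffle labels over \code{"all"} annotated cells (default)
#'   or only over the union of the two subgroups (\code{"pair"}).
#' @param exhaustiveCap switch to exhaustive enumeration when the number
#'   of distinct arrangements does not exceed this (default 5000; set to 0
#'   to force sampling).
#' @return an \linkS4class{LRIntensity} with the p-value filled in.
#' @export
lrPermutationP <- function(m, ann, model, source, target, nPerm = 1000,
                           seed = 1L, scope = c("all", "pair"),
                           exhaustiveCap = 5000) {
    scope <- match.arg(scope)
    if (nPerm < 1L) stop("nPerm must be at least 1", call. = FALSE)
    s <- .lrSetup(m, ann, model, source, target)
    obs <- if (length(s$lig))
        .lrCompute(s$v, s$idxA, s$idxB, s$lig, s$rec) else numeric()
    obsTotal <- sum(obs)
    cells <- if (scope == "all") seq_len(ncol(s$v))
             else sort(union(s$idxA, s$idxB))
    v <- s$v[, cells, drop = FALSE]
    posA <- match(s$idxA, cells); posB <- match(s$idxB, cells)
    n <- length(cells); nA <- length(posA); nB <- length(posB)
    same <- source == target
    arr <- .lrArrangements(n, nA, nB, same, exhaustiveCap)
    statOf <- function(a, b)
        if (length(s$lig)) sum(.lrCompute(v, a, b, s$lig, s$rec)) else 0
    if (!is.null(arr)) {
        stats <- vapply(arr, function(ab) statOf(ab[[1L]], ab[[2L]]),
                        numeric(1L))
        p <- sum(stats >= obsTotal - 1e-12) / length(stats)
        method <- "exhaustive"; nUsed <- length(arr); seedUsed <- NA_integer_
    } else {
        set.seed(seed)
        stats <- vapply(seq_len(nPerm), function(i) {
            perm <- sample.int(n)
            a <- perm[posA]
            b <- if (same) a else perm[posB]
            statOf(a, b)
        }, numeric(1L))
        p <- (1 + sum(stats >= obsTotal - 1e-12)) / (1 + nPerm)
        method <- "sampled"; nUsed <- as.integer(nPerm)
        seedUsed <- as.integer(seed)
    }
    pc <- .lrSortContributions(s$lig, s$rec, obs)
    rownames(pc) <- NULL
    new("LRIntensity", source = source, target = target,
        intensity = obsTotal, pairContributions = pc, pPerm = p,
        nPerm = as.integer(nUsed), method = method, seed = seedUsed)
}

#' Rank ligand-receptor pair contributions across subgroup combinations
#'
#' Pools the per-pair contributions of several \linkS4class{LRIntensity}
#' results and returns the top contributors, sorted by contribution
#' descending with deterministic lexicographic tie-breaking on
#' (ligand, receptor, source, target).
#'
#' @param results a list of \linkS4class{LRIntensity} objects (or one).
#' @param topK number of rows to return (default 20; all if fewer).
#' @return data.frame with columns \code{ligand}, \code{receptor},
#'   \code{source}, \code{target}, \code{contribution}.
#' @export
rankPairs <- function(results, topK = 20L) {
    if (is(results, "LRIntensity")) results <- list(results)
    if (!length(results)) stop("no results", call. = FALSE)
    tabs <- lapply(results, function(r) {
        pc <- pairContributions(r)
        if (!nrow(pc)) return(NULL)
        cbind(pc, source = r@source, target = r@target,
              stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    if (is.null(tab))
        return(data.frame(ligand = character(), receptor = character(),
                          source = character(), target = character(),
                          contribution = numeric()))
    tab <- tab[order(-tab$contribution, tab$ligand, tab$receptor,
                     tab$source, tab$target), , drop = FALSE]
    tab <- utils::head(tab, topK)
    rownames(tab) <- NULL
    tab[, c("ligand", "receptor", "source", "target", "contribution")]
}
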