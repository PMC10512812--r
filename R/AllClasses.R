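#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Named ordered gene set
#'
#' A minimal container for a named, ordered list of gene symbols, used for
#' expression panels (e.g. the 6- and 12-gene hormone-treatment-response
#' panels) and for larger signature modules (TCGA / CPGEA up-regulated
#' modules). Gene symbols are plain, case-sensitive strings matched exactly;
#' no alias resolution is attempted.
#'
#' @slot name single string naming the set.
#' @slot genes character vector of unique, non-empty gene symbols (ordered).
#'
#' @examples
#' gs <- GeneSet("demo", c("PEG10", "AR"))
#' geneIds(gs)
#' @export
setClass("GeneSet", representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "gene set must be non-empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "duplicate gene symbols in set")
    if (any(is.na(object@genes)) || any(!nzchar(object@genes)))
        msg <- c(msg, "gene symbols must be non-empty strings")
    if (is.null(msg)) TRUE else msg
})

#' @rdname GeneSet-class
#' @param name single string naming the set.
#' @param genes character vector of gene symbols.
#' @export
GeneSet <- function(name, genes) {
    new("GeneSet", name = as.character(name), genes = as.character(genes))
}

#' @describeIn GeneSet-class gene symbols of the set, in order.
#' @param x,object a \code{GeneSet}.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet-class
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)

#' @describeIn GeneSet-class name of the set.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname GeneSet-class
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname GeneSet-class
#' @export
setMethod("show", "GeneSet", function(object) {
    cat("GeneSet \"", object@name, "\" with ", length(object@genes),
        " genes\n", sep = "")
    cat("  ", paste(utils::head(object@genes, 8L), collapse = ", "),
        if (length(object@genes) > 8L) ", ..." else "", "\n", sep = "")
})

#' Ligand-receptor annotation model
#'
#' Holds the protein-location flags and protein-protein interaction pairs
#' over which ligand-receptor communication intensity is summed. A protein
#' counts as a candidate ligand when its predicted location includes
#' "Secreted" and as a candidate receptor when it includes "Plasma membrane";
#' a gene may carry both flags. Interaction pairs are stored unordered and
#' deduplicated.
#'
#' @slot secreted character vector of secreted-protein gene symbols.
#' @slot membrane character vector of plasma-membrane-protein gene symbols.
#' @slot pairs two-column character matrix of unordered interaction pairs
#'   (each row sorted lexicographically, rows unique).
#' @export
setClass("LRModel", representation(secreted = "character",
                                   membrane = "character",
                                   pairs = "matrix"))

setValidity("LRModel", function(object) {
    msg <- NULL
    if (!is.character(object@pairs) || ncol(object@pairs) != 2L)
        msg <- c(msg, "'pairs' must be a two-column character matrix")
    if (anyDuplicated(object@secreted) || anyDuplicated(object@membrane))
        msg <- c(msg, "location sets must not contain duplicates")
    if (is.null(msg)) TRUE else msg
})

#' @rdname LRModel-class
#' @param secreted,membrane character vectors of gene symbols.
#' @param pairs two-column character matrix or data.frame of interaction
#'   pairs (unordered; deduplicated on construction).
#' @export
LRModel <- function(secreted = character(), membrane = character(),
                    pairs = matrix(character(), ncol = 2L)) {
    pairs <- as.matrix(pairs)
    mode(pairs) <- "character"
    if (nrow(pairs)) {
        pairs <- t(apply(pairs, 1L, sort))
        pairs <- unique(pairs)
    }
    dimnames(pairs) <- NULL
    new("LRModel", secreted = unique(as.character(secreted)),
        membrane = unique(as.character(membrane)), pairs = pairs)
}

#' @rdname LRModel-class
#' @param object an \code{LRModel}.
#' @export
setMethod("show", "LRModel", function(object) {
    cat("LRModel:", length(object@secreted), "secreted,",
        length(object@membrane), "membrane proteins;",
        nrow(object@pairs), "interaction pairs\n")
})

#' Ligand-receptor intensity result
#'
#' Result of summing mean-ligand x mean-receptor products over all directed
#' ligand-receptor candidates between a source (ligand-sending) and target
#' (receptor-bearing) cell subgroup, optionally with a label-permutation
#' p-value.
#'
#' @slot source,target subgroup labels.
#' @slot intensity total intensity (sum of pair contributions).
#' @slot pairContributions data.frame with columns ligand, receptor,
#'   contribution, sorted by decreasing contribution (ties lexicographic).
#' @slot pPerm permutation p-value (NA until computed).
#' @slot nPerm number of permutations (0 until computed; for exhaustive
#'   enumeration, the number of distinct label arrangements).
#' @slot method "none", "sampled" or "exhaustive".
#' @slot seed RNG seed used for sampled permutations (NA otherwise).
#' @export
setClass("LRIntensity", representation(source = "character",
                                       target = "character",
                                       intensity = "numeric",
                                       pairContributions = "data.frame",
                                       pPerm = "numeric",
                                       nPerm = "integer",
                                       method = "character",
                                       seed = "integer"))

setValidity("LRIntensity", function(object) {
    msg <- NULL
    pc <- object@pairContributions
    if (!all(c("ligand", "receptor", "contribution") %in% names(pc)))
        msg <- c(msg, "pairContributions needs ligand/receptor/contribution")
    if (nrow(pc) && any(pc$contribution < 0))
        msg <- c(msg, "contributions must be non-negative")
    if (nrow(pc) &&
        abs(object@intensity - sum(pc$contribution)) >
            1e-8 * max(1, abs(object@intensity)))
        msg <- c(msg, "intensity must equal the sum of pair contributions")
    if (is.null(msg)) TRUE else msg
})

#' @rdname LRIntensity-class
#' @param object an \code{LRIntensity}.
#' @export
setMethod("show", "LRIntensity", function(object) {
    cat("LRIntensity ", object@source, " -> ", object@target,
        ": intensity = ", format(object@intensity, digits = 6), sep = "")
    if (!is.na(object@pPerm))
        cat(", p = ", format(object@pPerm, digits = 4),
            " (", object@method, ", n = ", object@nPerm, ")", sep = "")
    cat("\n", nrow(object@pairContributions), "contributing pairs\n")
})

#' @describeIn LRIntensity-class total intensity.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname LRIntensity-class
#' @param x an \code{LRIntensity}.
#' @export
setMethod("intensity", "LRIntensity", function(x) x@intensity)

#' @describeIn LRIntensity-class per-pair contribution table.
#' @export
setGeneric("pairContributions", function(x) standardGeneric("pairContributions"))

#' @rdname LRIntensity-class
#' @export
setMethod("pairContributions", "LRIntensity", function(x) x@pairContributions)

#' @describeIn LRIntensity-class permutation p-value (NA if not computed).
#' @export
setGeneric("pPerm", function(x) standardGeneric("pPerm"))

#' @rdname LRIntensity-class
#' @export
setMethod("pPerm", "LRIntensity", function(x) x@pPerm)
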