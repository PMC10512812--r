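#' @importFrom Matrix readMM writeMM
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom utils read.delim write.table head
NULL

## Detect comma vs tab from the first line; `sep` overrides.
.detectSep <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    line <- readLines(path, n = 1L)
    if (length(line) == 0L) return("\t")
    if (lengths(regmatches(line, gregexpr("\t", line))) >=
        lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))) "\t"
    else ","
}

.firstColumn <- function(path, sep = NULL) {
    sep <- .detectSep(path, sep)
    x <- read.delim(path, header = FALSE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = "character")
    as.character(x[[1L]])
}

.checkFiniteNonNegative <- function(m, what) {
    if (any(!is.finite(m)))
        stop(what, " contains NA/NaN/Inf values", call. = FALSE)
    if (any(m < 0))
        stop(what, " contains negative values", call. = FALSE)
    invisible(TRUE)
}

#' Read a single-cell count matrix
#'
#' Reads a genes x cells count matrix in Matrix Market sparse format (or
#' dense delimited text) together with one-identifier-per-line gene and
#' cell/barcode files (extra tab-separated columns are ignored; the first
#' column is used). Duplicated gene symbols are made unique by suffixing
#' (\code{ACTB, ACTB.1, ...}) with a warning.
#'
#' @param path_matrix path to the \code{.mtx} (or dense delimited) matrix.
#' @param path_genes,path_cells paths to the gene and cell identifier files.
#' @param sep optional field separator overriding comma/tab auto-detection
#'   for dense matrices and identifier files.
#' @return a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @examples
#' d <- tempfile(); dir.create(d)
#' sce <- simulateSC(nGenes = 20, cellsPerSubgroup = c(5, 5), seed = 1)$sce
#' writeCountMatrix(sce, d)
#' sce2 <- readCountMatrix(file.path(d, "matrix.mtx"),
#'                         file.path(d, "genes.tsv"),
#'                         file.path(d, "barcodes.tsv"))
#' @export
readCountMatrix <- function(path_matrix, path_genes, path_cells, sep = NULL) {
    first <- tryCatch(readLines(path_matrix, n = 1L), error = function(e) "")
    isMM <- length(first) == 1L && grepl("^%%MatrixMarket", first)
    if (isMM || grepl("\\.mtx$", path_matrix)) {
        m <- tryCatch(as.matrix(Matrix::readMM(path_matrix)),
                      error = function(e)
                          stop("failed to read matrix '", path_matrix, "': ",
                               conditionMessage(e), call. = FALSE))
    } else {
        s <- .detectSep(path_matrix, sep)
        m <- as.matrix(read.delim(path_matrix, header = FALSE, sep = s))
    }
    genes <- .firstColumn(path_genes, sep)
    cells <- .firstColumn(path_cells, sep)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
        stop("dimension mismatch between '", path_matrix, "' (",
             nrow(m), " x ", ncol(m), "), '", path_genes, "' (",
             length(genes), " genes) and '", path_cells, "' (",
             length(cells), " cells)", call. = FALSE)
    .checkFiniteNonNegative(m, "count matrix")
    if (any(m != round(m)))
        stop("count matrix contains non-integer values", call. = FALSE)
    if (anyDuplicated(genes)) {
        warning("duplicated gene symbols made unique by suffixing: ",
                paste(unique(genes[duplicated(genes)]), collapse = ", "))
        genes <- make.unique(genes)
    }
    if (anyDuplicated(cells))
        stop("duplicated cell identifiers in '", path_cells, "'",
             call. = FALSE)
    dimnames(m) <- list(genes, cells)
    SingleCellExperiment(assays = list(counts = m))
}

#' Write a single-cell count matrix
#'
#' Writes the \code{counts} assay as \code{matrix.mtx} plus \code{genes.tsv}
#' and \code{barcodes.tsv} (one identifier per line) under \code{dir}, the
#' layout \code{\link{readCountMatrix}} reads back.
#'
#' @param x a SingleCellExperiment / SummarizedExperiment with a
#'   \code{counts} assay, or a genes x cells matrix with dimnames.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeCountMatrix <- function(x, dir) {
    m <- .getCounts(x)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pm <- file.path(dir, "matrix.mtx")
    pg <- file.path(dir, "genes.tsv")
    pc <- file.path(dir, "barcodes.tsv")
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), pm)
    writeLines(rownames(m), pg)
    writeLines(colnames(m), pc)
    invisible(c(matrix = pm, genes = pg, cells = pc))
}

#' Read a bulk expression cohort with phenotypes
#'
#' Reads a genes x samples expression table (header row of sample ids,
#' first column gene symbols) and a phenotype table keyed by sample id with
#' columns \code{sample_type}, \code{recurrence} (YES/NO/blank),
#' \code{therapy_type} and \code{recurrence_time_days}. Samples present in
#' the expression table but missing from the phenotype table are retained
#' with all phenotype fields missing (warning). Empty strings and "NA" are
#' both treated as missing. A recurrence time is kept only for samples with
#' recurrence YES; any other time is dropped with a warning, and a YES
#' sample with no usable time is flagged with a warning.
#'
#' @param path_expression,path_phenotype input file paths (comma/tab
#'   auto-detected; \code{sep} overrides).
#' @param sep optional field separator.
#' @return a \linkS4class{SummarizedExperiment} with assay \code{expr} and
#'   colData columns \code{sample_type}, \code{recurrence},
#'   \code{therapy_type}, \code{recurrence_time_days}.
#' @export
readBulkCohort <- function(path_expression, path_phenotype, sep = NULL) {
    se <- .detectSep(path_expression, sep)
    expr <- read.delim(path_expression, sep = se, check.names = FALSE,
                       row.names = 1L)
    expr <- as.matrix(expr)
    .checkFiniteNonNegative(expr, "bulk expression")
    if (anyDuplicated(colnames(expr)))
        stop("duplicated sample identifiers in expression table",
             call. = FALSE)
    sp <- .detectSep(path_phenotype, sep)
    ph <- read.delim(path_phenotype, sep = sp, check.names = FALSE,
                     stringsAsFactors = FALSE, colClasses = "character")
    names(ph)[1L] <- "sample_id"
    need <- c("sample_type", "recurrence", "therapy_type",
              "recurrence_time_days")
    for (nm in need) if (!nm %in% names(ph)) ph[[nm]] <- NA_character_
    blank2na <- function(x) {
        x[!nzchar(trimws(x)) | toupper(trimws(x)) == "NA"] <- NA_character_
        x
    }
    ph[need] <- lapply(ph[need], blank2na)
    idx <- match(colnames(expr), ph$sample_id)
    if (all(is.na(idx)))
        stop("no overlapping sample ids between expression and phenotype",
             call. = FALSE)
    if (anyNA(idx))
        warning(sum(is.na(idx)), " sample(s) missing from phenotype table; ",
                "retained with unknown phenotype: ",
                paste(head(colnames(expr)[is.na(idx)], 5L), collapse = ", "))
    cd <- ph[idx, need, drop = FALSE]
    rownames(cd) <- colnames(expr)
    time <- suppressWarnings(as.numeric(cd$recurrence_time_days))
    rec <- toupper(cd$recurrence)
    rec[!rec %in% c("YES", "NO")] <- NA_character_
    badYes <- !is.na(rec) & rec == "YES" & is.na(time)
    if (any(badYes))
        warning("recurrence YES without usable recurrence time for: ",
                paste(rownames(cd)[badYes], collapse = ", "))
    dropT <- !is.na(time) & (is.na(rec) | rec != "YES")
    if (any(dropT)) {
        warning("recurrence time dropped for non-recurrent sample(s): ",
                paste(rownames(cd)[dropT], collapse = ", "))
        time[dropT] <- NA_real_
    }
    if (any(!is.na(time) & time < 0))
        stop("negative recurrence times", call. = FALSE)
    SummarizedExperiment(
        assays = list(expr = expr),
        colData = S4Vectors::DataFrame(sample_type = cd$sample_type,
                                       recurrence = rec,
                                       therapy_type = cd$therapy_type,
                                       recurrence_time_days = time,
                                       row.names = rownames(cd)))
}

#' Write a bulk cohort as expression + phenotype tables
#'
#' Writes \code{expr.tsv} (genes x samples, gene column first) and
#' \code{pheno.tsv} (sample_id, sample_type, recurrence, therapy_type,
#' recurrence_time_days) under \code{dir}, the layout
#' \code{\link{readBulkCohort}} reads back.
#'
#' @param x SummarizedExperiment with assay \code{expr} and the phenotype
#'   colData columns.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
writeBulkCohort <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- as.matrix(SummarizedExperiment::assay(x, "expr"))
    pe <- file.path(dir, "expr.tsv")
    pp <- file.path(dir, "pheno.tsv")
    write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                pe, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- c("sample_type", "recurrence", "therapy_type",
              "recurrence_time_days")
    cd <- cd[, intersect(keep, names(cd)), drop = FALSE]
    write.table(data.frame(sample_id = colnames(m), cd, check.names = FALSE),
                pp, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    invisible(c(expression = pe, phenotype = pp))
}

#' Read a ligand-receptor annotation model
#'
#' Reads a protein-location table (columns \code{gene} and
#' \code{predicted_location}, the latter a delimiter-separated token list)
#' and a two-column protein-protein interaction pair table. Secreted
#' proteins are those whose location tokens contain \code{"Secreted"};
#' membrane proteins those containing \code{"Plasma membrane"}; a gene may
#' be both. Pairs are deduplicated as unordered; a pair referencing a gene
#' absent from the location table is kept with a warning.
#'
#' @param path_locations,path_pairs input file paths.
#' @param sep optional field separator (auto-detected otherwise).
#' @param location_sep regular expression splitting location tokens
#'   (default: comma or semicolon, surrounding space tolerated).
#' @return an \linkS4class{LRModel}.
#' @export
readLRModel <- function(path_locations, path_pairs, sep = NULL,
                        location_sep = "[;,]") {
    sl <- .detectSep(path_locations, sep)
    loc <- read.delim(path_locations, sep = sl, stringsAsFactors = FALSE)
    if (ncol(loc) < 2L)
        stop("location table needs gene and predicted_location columns",
             call. = FALSE)
    genes <- as.character(loc[[1L]])
    toks <- strsplit(as.character(loc[[2L]]), location_sep)
    toks <- lapply(toks, trimws)
    secreted <- unique(genes[vapply(toks, function(t) "Secreted" %in% t,
                                    logical(1L))])
    membrane <- unique(genes[vapply(toks, function(t) "Plasma membrane" %in% t,
                                    logical(1L))])
    sp <- .detectSep(path_pairs, sep)
    pr <- read.delim(path_pairs, sep = sp, stringsAsFactors = FALSE)
    if (ncol(pr) < 2L)
        stop("pair table needs two gene columns", call. = FALSE)
    pairs <- cbind(as.character(pr[[1L]]), as.character(pr[[2L]]))
    unknown <- setdiff(unique(c(pairs)), genes)
    if (length(unknown))
        warning("pair gene(s) absent from location table kept: ",
                paste(head(unknown, 10L), collapse = ", "))
    LRModel(secreted = secreted, membrane = membrane, pairs = pairs)
}

#' Read gene sets from GMT or plain text
#'
#' A \code{.gmt} file (set name, description, then gene symbols per
#' tab-separated line) yields a list of \linkS4class{GeneSet}s; any other
#' file is taken as one gene symbol per line and yields a single set named
#' after \code{name} (default: the file name without extension).
#'
#' @param path input file.
#' @param name set name for plain-text input.
#' @return a \code{GeneSet} or a named list of them (GMT).
#' @export
readGeneSet <- function(path, name = NULL) {
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
        lines <- readLines(path)
        lines <- lines[nzchar(trimws(lines))]
        sets <- lapply(strsplit(lines, "\t"), function(f) {
            if (length(f) < 3L)
                stop("malformed GMT line: ", f[1L], call. = FALSE)
            GeneSet(f[1L], f[-(1:2)])
        })
        names(sets) <- vapply(sets, setName, character(1L))
        return(sets)
    }
    genes <- trimws(readLines(path))
    genes <- genes[nzchar(genes)]
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    GeneSet(name, genes)
}

## Extract a counts matrix from SCE/SE or plain matrix input.
.getCounts <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"counts" %in% SummarizedExperiment::assayNames(x))
            stop("no 'counts' assay in object", call. = FALSE)
        m <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    } else {
        m <- as.matrix(x)
    }
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("count matrix must have gene and cell identifiers", call. = FALSE)
    m
}

## Extract per-cell annotation (data.frame) from an SCE or a data.frame.
.getAnnotation <- function(ann) {
    if (is(ann, "SummarizedExperiment"))
        ann <- as.data.frame(SummarizedExperiment::colData(ann))
    ann <- as.data.frame(ann)
    if (is.null(ann$subgroup))
        stop("annotation must contain a 'subgroup' column", call. = FALSE)
    ann
}
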