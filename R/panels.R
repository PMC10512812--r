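#' Built-in hormone-treatment-response gene panels
#'
#' The 6-gene panel combines the CRPC epithelial features
#' (PEG10, CCDC74A, the PPIB-GAPDH-AR regulatory axis) with the epithelial
#' marker EPCAM. The 12-gene panel extends it with tumor-microenvironment
#' features: the CAF markers FAP and TGFB1, the immunosuppressive cytokine
#' IL10, and the T-cell exhaustion checkpoints TIGIT, LAG3 and PDCD1.
#'
#' @return a \linkS4class{GeneSet}.
#' @examples
#' crpcPanel6()
#' setdiff(geneIds(crpcPanel12()), geneIds(crpcPanel6()))
#' @export
crpcPanel6 <- function() {
    GeneSet("panel6", c("PEG10", "CCDC74A", "PPIB", "GAPDH", "AR", "EPCAM"))
}

#' @rdname crpcPanel6
#' @export
crpcPanel12 <- function() {
    GeneSet("panel12", c(geneIds(crpcPanel6()),
                         "FAP", "IL10", "TGFB1", "TIGIT", "LAG3", "PDCD1"))
}
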