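#' @useDynLib halotrait, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom data.table data.table as.data.table setnames fread fwrite :=
#' @importFrom stats sd median setNames
#' @importFrom utils combn head
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("taxon_id", "gene_id", "sample_id", "abundance",
                         "at", "copies", "s", "pathway"))
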