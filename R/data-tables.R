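#' Bundled printed summary tables from the source study
#'
#' Small plain-text copies of the study's printed result tables, used as
#' worked-example inputs: `"table1_top_known"` (top-20 known miRNA raw
#' counts and sequences), `"table3_known_mirna_de"` (differentially
#' expressed known miRNAs: normalized TPM pairs, printed log2 fold change,
#' p-value, direction), `"table4_up_targets"` and `"table5_down_targets"`
#' (target-gene RPKM pairs with printed log2 fold change and FDR).
#' Normalized columns are in TPM (miRNA) or RPKM (genes); fold changes are
#' log2(CMS / maintainer).
#'
#' @param name table name (see above), with or without the `.tsv` suffix.
#' @return data.frame.
#' @export
printed_table <- function(name = c("table3_known_mirna_de",
                                   "table4_up_targets",
                                   "table5_down_targets",
                                   "table1_top_known")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "mircms",
                      mustWork = TRUE)
  read_tsv(path)
}
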