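#' Published QTL intervals for hippocampal proliferation and T-cell subsets
#'
#' The 95% positional confidence intervals (Mb, mouse genome build 37)
#' of the QTLs reported for hippocampal KI67 counts and for the
#' percentage of CD8+ cells among CD3+ blood T lymphocytes in
#' heterogeneous stock mice, with their resample model inclusion
#' probabilities.  Ships with the package as a plain TSV and serves as
#' the worked example for the interval-overlap operations.
#'
#' @return tibble: `phenotype` (`ki67` or `cd8_in_cd3`), `chrom`,
#'   `start`, `end` (Mb), `rmip`.
#' @export
#' @examples
#' q <- hs_published_qtls()
#' qtl_total_length(q)
hs_published_qtls <- function() {
  path <- system.file("extdata", "hs_ki67_cd8_qtls.tsv", package = "hsqtl")
  tibble::as_tibble(utils::read.delim(path,
                                      colClasses = c(chrom = "character")))
}
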