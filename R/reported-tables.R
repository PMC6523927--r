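#' Published summary tables from the faba bean salt-stress sRNA study
#'
#' Bundled copies (plain TSV under `inst/extdata/`) of the summary
#' statistics reported for four leaf sRNA libraries of two faba bean
#' genotypes (salt-sensitive Hassawi-3: HC-4 control / HSA stress;
#' salt-tolerant ILB4347: IC-1 control / IS-4 stress):
#' \describe{
#'   \item{`libraries`}{per-library raw/clean/mapped tag counts with
#'     the printed percentages.}
#'   \item{`categories`}{per-library read counts and percentages by
#'     sRNA category.}
#'   \item{`novel_hc4_hsa`, `novel_ic1_is4`}{the novel-miRNA
#'     differential-expression tables: counts, TPM (zero counts printed
#'     as the 0.001 floor), log2 ratio (stress over control),
#'     regulation call, p-value and FDR.}
#' }
#' These tables serve as verifiable inputs: the package's arithmetic
#' (percentages, log2 ratios of floored TPMs, regulation tallies) can be
#' recomputed from them and compared against the printed columns.
#'
#' @param which One of `"libraries"`, `"categories"`, `"novel_hc4_hsa"`,
#'   `"novel_ic1_is4"`.
#' @return A data.frame.
#' @export
faba_reported_table <- function(which = c("libraries", "categories",
                                          "novel_hc4_hsa",
                                          "novel_ic1_is4")) {
  which <- match.arg(which)
  f <- c(libraries = "faba_library_summary.tsv",
         categories = "faba_srna_categories.tsv",
         novel_hc4_hsa = "faba_novel_mirna_hc4_hsa.tsv",
         novel_ic1_is4 = "faba_novel_mirna_ic1_is4.tsv")[[which]]
  path <- system.file("extdata", f, package = "saltmir", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
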