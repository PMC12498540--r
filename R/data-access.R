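#' Bundled reference methylation dataset
#'
#' The package ships summary-level methylation-index data for human
#' cytoplasmic rRNA measured across an embryonic stem cell (ESC), neural
#' stem cell (NSC) and neuron differentiation trajectory, in wild-type
#' (WT) and FMR1 knockout (KO) backgrounds:
#'
#' \describe{
#'   \item{\code{wtDifferentiationTable()}}{Per-site group-mean MI for WT
#'     ESC/NSC/neuron with one-way ANOVA and Tukey multiple-comparison
#'     p-values (42 sites on 18S, 64 on 28S). p-values reported below
#'     print precision are stored at the censoring bound 1e-04.}
#'   \item{\code{fmr1KoComparisonTable(stage)}}{Sites whose MI differs
#'     significantly between WT and FMR1 KO at one differentiation stage
#'     (\code{"esc"}, \code{"nsc"} or \code{"neuron"}), with per-condition
#'     mean MI and the unpaired two-tailed equal-variance t-test p-value.}
#' }
#'
#' These tables drive the packaged classification examples and let the
#' differential machinery be exercised against known summary statistics
#' without any sequencing input.
#'
#' @param molecule Optional filter, \code{"18S"} or \code{"28S"}.
#' @return A data frame (see Details for columns).
#' @name referenceDataset
NULL

.readExtdata <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "riboMeth",
                                mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname referenceDataset
#' @export
wtDifferentiationTable <- function(molecule = NULL) {
  df <- .readExtdata("wt_differentiation_mi.tsv")
  if (!is.null(molecule)) df <- df[df$molecule_id %in% molecule, ]
  df
}

#' @rdname referenceDataset
#' @param stage Differentiation stage: \code{"esc"}, \code{"nsc"} or
#'   \code{"neuron"}.
#' @export
fmr1KoComparisonTable <- function(stage = c("esc", "nsc", "neuron"),
                                  molecule = NULL) {
  stage <- match.arg(stage)
  df <- .readExtdata(paste0(stage, "_wt_vs_fmr1ko_mi.tsv"))
  if (!is.null(molecule)) df <- df[df$molecule_id %in% molecule, ]
  df
}
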