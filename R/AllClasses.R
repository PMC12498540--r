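#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' rRNA reference sequence set
#'
#' Holds the mature rRNA sequences that alignments and site catalogues are
#' validated against. Sequences are stored as DNA (any \code{U} in the input
#' is converted to \code{T} on construction) and are indexed by molecule
#' label, conventionally \code{"18S"} and \code{"28S"}.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} named by molecule label.
#' @slot accessions Character vector of source record identifiers (for
#'   example transcript accessions), parallel to \code{sequences}.
#'
#' @seealso [readRRNAReference()]
#' @export
setClass("RRNAReferenceSet",
  representation(sequences = "DNAStringSet", accessions = "character"))

setValidity("RRNAReferenceSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n == 0L) msg <- c(msg, "reference set is empty")
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "every sequence needs a molecule label")
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate molecule labels: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "zero-length sequence present")
  if (length(object@accessions) != n)
    msg <- c(msg, "accessions must be parallel to sequences")
  if (length(msg)) msg else TRUE
})

#' Per-position read-end counts for one rRNA molecule in one sample
#'
#' The primary evidence RiboMeth-Seq works from: for every position of the
#' reference, the number of aligned reads whose leftmost base falls there
#' (\code{fivePrime}) and whose rightmost base falls there
#' (\code{threePrime}). After [combineEndCounts()] the \code{combined} slot
#' holds cleavage evidence on the bond coordinate: \code{combined[i]}
#' counts ends attributable to hydrolysis of the phosphodiester bond on the
#' 3' side of nucleotide \code{i}.
#'
#' @slot moleculeId Molecule label, e.g. \code{"18S"}.
#' @slot sampleId Sample identifier.
#' @slot fivePrime,threePrime Integer vectors of length L (reference length).
#' @slot combined Numeric vector of length L (empty until
#'   [combineEndCounts()] is run).
#' @slot fivePrimeStart Count of 5' ends at position 1 (natural transcript
#'   starts), excluded from \code{combined} and reported separately.
#' @slot totalReads Number of alignment records counted.
#' @slot qc List of bookkeeping tallies (skipped records, median coverage).
#'
#' @export
setClass("EndCountProfile",
  representation(moleculeId = "character", sampleId = "character",
                 fivePrime = "integer", threePrime = "integer",
                 combined = "numeric", fivePrimeStart = "integer",
                 totalReads = "integer", qc = "list"),
  prototype(combined = numeric(0), fivePrimeStart = 0L, totalReads = 0L,
            qc = list()))

setValidity("EndCountProfile", function(object) {
  msg <- character()
  L <- length(object@fivePrime)
  if (length(object@threePrime) != L)
    msg <- c(msg, "fivePrime and threePrime must have equal length")
  if (length(object@combined) && length(object@combined) != L)
    msg <- c(msg, "combined must be empty or match the reference length")
  if (any(object@fivePrime < 0L) || any(object@threePrime < 0L) ||
      (length(object@combined) && any(object@combined < 0)))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Parameters of the score C methylation index
#'
#' @slot k Window half-width: the neighbourhood average uses positions
#'   \code{i-k .. i+k} excluding \code{i} itself. Default 6.
#' @slot weightScheme \code{"linear_decay"} (weight \code{(k+1-d)/k} at
#'   distance \code{d}; default) or \code{"uniform"}.
#' @slot minSiteCoverage Minimum summed (unweighted) neighbour count for a
#'   site to be scored; below it the score is \code{NA}. Default 100.
#' @slot clamp Clamp scores into [0, 1] (default \code{TRUE}).
#'
#' @export
setClass("ScoreParams",
  representation(k = "integer", weightScheme = "character",
                 minSiteCoverage = "numeric", clamp = "logical"))

setValidity("ScoreParams", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (!object@weightScheme %in% c("linear_decay", "uniform"))
    msg <- c(msg, "weightScheme must be 'linear_decay' or 'uniform'")
  if (object@minSiteCoverage < 0) msg <- c(msg, "minSiteCoverage must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScoreParams-class Constructor with the package defaults.
#' @param k,weightScheme,minSiteCoverage,clamp See the slot descriptions.
#' @return A \code{ScoreParams} object.
#' @export
ScoreParams <- function(k = 6L, weightScheme = c("linear_decay", "uniform"),
                        minSiteCoverage = 100, clamp = TRUE) {
  new("ScoreParams", k = as.integer(k),
      weightScheme = match.arg(weightScheme),
      minSiteCoverage = as.numeric(minSiteCoverage), clamp = clamp)
}

#' Sites-by-samples matrix of methylation indices
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} subclass whose
#' \code{"MI"} assay holds the methylation index (fraction of the rRNA
#' population methylated at the site; 1 = complete methylation, 0.1 = 10
#' percent). Rows are catalogue sites (\code{rowData}: \code{molecule_id},
#' \code{position}, \code{site_id}); columns are samples (\code{colData}:
#' \code{group}).
#'
#' @export
setClass("MethylationTable", contains = "SummarizedExperiment")

setValidity("MethylationTable", function(object) {
  msg <- character()
  if (!"MI" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'MI' is required")
  else {
    mi <- SummarizedExperiment::assay(object, "MI")
    if (any(mi < 0 | mi > 1, na.rm = TRUE))
      msg <- c(msg, "MI values must lie in [0, 1] or be NA")
  }
  need <- c("molecule_id", "position", "site_id")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData needs molecule_id, position, site_id")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData needs a 'group' column")
  if (length(msg)) msg else TRUE
})

#' qPCR standard curve fitted to a serial dilution series
#'
#' @slot slope Cycles per log10 dilution (negative).
#' @slot intercept Ct at log10 dilution 0 (the top standard).
#' @slot rSquared Coefficient of determination of the fit.
#' @slot efficiency Amplification efficiency, \code{10^(-1/slope) - 1}
#'   (1 = perfect doubling per cycle).
#' @slot ctRange Range of the fitted Ct values, used to flag extrapolation.
#'
#' @seealso [fitStandardCurve()], [copyNumber()]
#' @export
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", efficiency = "numeric",
                 ctRange = "numeric"))

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (object@slope >= 0) msg <- c(msg, "slope must be negative")
  if (object@efficiency <= 0 || object@efficiency > 1.5)
    msg <- c(msg, "efficiency outside (0, 1.5]: implausible chemistry")
  if (object@rSquared < 0 || object@rSquared > 1)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth for the fragment-end simulator
#'
#' Describes one rRNA molecule undergoing controlled alkaline hydrolysis:
#' bond \code{i} (3' of nucleotide \code{i}) is cut with probability
#' proportional to \code{cleavage[i] * (1 - rho * methylation[i])}, so a
#' fully methylated position with \code{rho = 1} is never cut.
#'
#' @slot length Molecule length L in nucleotides.
#' @slot cleavage Positive base cleavage propensity per bond (length L).
#' @slot methylation True methylated fraction per position, in [0, 1].
#' @slot rho Protection efficiency of a methyl group, in [0, 1]; default 1
#'   (methylation fully blocks hydrolysis at its bond).
#' @slot nFragments Number of cleavage events to draw (coverage).
#' @slot seed Integer seed; all simulator randomness flows through it.
#'
#' @seealso [simulateEndCounts()]
#' @export
setClass("SimulationTruth",
  representation(length = "integer", cleavage = "numeric",
                 methylation = "numeric", rho = "numeric",
                 nFragments = "integer", seed = "integer"))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  L <- object@length
  if (L < 2L) msg <- c(msg, "length must be >= 2")
  if (length(object@cleavage) != L || any(object@cleavage <= 0))
    msg <- c(msg, "cleavage must be a positive vector of length L")
  if (length(object@methylation) != L ||
      any(object@methylation < 0 | object@methylation > 1))
    msg <- c(msg, "methylation must lie in [0, 1] over positions 1..L")
  if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
  if (object@nFragments <= 0L) msg <- c(msg, "nFragments must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationTruth-class Constructor. \code{methylation} may be
#'   given sparsely as a named vector of fractions keyed by position.
#' @param length Molecule length (nucleotides).
#' @param methylation Either a full length-L vector of fractions, or a
#'   named vector like \code{c("428" = 0.8)} giving fractions at chosen
#'   positions (zero elsewhere).
#' @param cleavage Base cleavage propensities; default uniform.
#' @param rho Protection efficiency; default 1.
#' @param nFragments Number of cleavage events.
#' @param seed Integer seed.
#' @return A \code{SimulationTruth} object.
#' @export
SimulationTruth <- function(length, methylation = numeric(0),
                            cleavage = rep(1, length), rho = 1,
                            nFragments = 1e5, seed = 1L) {
  L <- as.integer(length)
  m <- rep(0, L)
  if (!is.null(names(methylation)) && length(methylation)) {
    pos <- as.integer(names(methylation))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > L))
      stop("named methylation positions must lie in 1..L")
    m[pos] <- unname(methylation)
  } else if (length(methylation) == L) {
    m <- as.numeric(methylation)
  } else if (length(methylation)) {
    stop("methylation must be length L or a named sparse vector")
  }
  new("SimulationTruth", length = L, cleavage = as.numeric(cleavage),
      methylation = m, rho = as.numeric(rho),
      nFragments = as.integer(nFragments), seed = as.integer(seed))
}

#' Specification of group effects for the MI-matrix simulator
#'
#' @slot means Numeric matrix of true MI group means, sites x groups, with
#'   rownames = site identifiers and colnames = group labels.
#' @slot sigma Between-replicate Gaussian noise standard deviation.
#' @slot nPerGroup Named integer vector of replicates per group.
#' @slot noiseModel \code{"gaussian"} (clamped to [0,1]; default) or
#'   \code{"beta"} for boundary-heavy truths.
#' @slot seed Integer seed.
#'
#' @seealso [simulateMIMatrix()]
#' @export
setClass("GroupEffectSpec",
  representation(means = "matrix", sigma = "numeric",
                 nPerGroup = "integer", noiseModel = "character",
                 seed = "integer"))

setValidity("GroupEffectSpec", function(object) {
  msg <- character()
  if (any(object@means < 0 | object@means > 1))
    msg <- c(msg, "true means must lie in [0, 1]")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (is.null(colnames(object@means)) || is.null(rownames(object@means)))
    msg <- c(msg, "means needs row and column names")
  if (!identical(sort(names(object@nPerGroup)), sort(colnames(object@means))))
    msg <- c(msg, "nPerGroup names must match the mean matrix groups")
  if (any(object@nPerGroup < 1L)) msg <- c(msg, "every group needs >= 1 replicate")
  if (!object@noiseModel %in% c("gaussian", "beta"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'beta'")
  if (length(msg)) msg else TRUE
})

#' @describeIn GroupEffectSpec-class Constructor.
#' @param means Sites x groups matrix of true MI means (named dims).
#' @param sigma Replicate noise SD.
#' @param nPerGroup Named integer vector of replicates per group.
#' @param noiseModel \code{"gaussian"} or \code{"beta"}.
#' @param seed Integer seed.
#' @return A \code{GroupEffectSpec} object.
#' @export
GroupEffectSpec <- function(means, sigma = 0.05, nPerGroup, noiseModel =
                            c("gaussian", "beta"), seed = 1L) {
  storage.mode(means) <- "double"
  n <- as.integer(nPerGroup)
  names(n) <- names(nPerGroup)
  new("GroupEffectSpec", means = means, sigma = as.numeric(sigma),
      nPerGroup = n, noiseModel = match.arg(noiseModel),
      seed = as.integer(seed))
}
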