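#' RTL-P methylation index from four Ct values
#'
#' Reverse transcription at low dNTP concentration pauses at 2'-O-
#' methylated riboses, so the amplicon whose forward primer lies upstream
#' of the site (spanning it) loses template and its Ct rises relative to
#' the downstream (non-spanning) amplicon. With
#' \code{ddCt = (ctUpLow - ctDownLow) - (ctUpHigh - ctDownHigh)}, the
#' methylation score is \code{1 - 2^(-ddCt)}, clamped to [0, 1]:
#' 0 when the dNTP concentration makes no difference (no RT block,
#' unmethylated) and approaching 1 as the block becomes complete.
#' Amplification efficiency is assumed to be 100\%; an efficiency can be
#' supplied to replace the base 2.
#'
#' All arguments are vectorised; any missing Ct yields a missing score.
#'
#' @param ctUpLow,ctDownLow Ct of the spanning (up) and non-spanning
#'   (down) amplicons under low dNTP.
#' @param ctUpHigh,ctDownHigh The same under high dNTP.
#' @param efficiency Amplification efficiency (1 = perfect doubling);
#'   the fold-change base is \code{1 + efficiency}.
#' @return Numeric vector of methylation scores in [0, 1] (\code{NA}
#'   where any Ct is missing).
#' @examples
#' rtlpIndex(24, 21, 23, 21)  # ddCt = 1 -> 0.5
#' @export
rtlpIndex <- function(ctUpLow, ctDownLow, ctUpHigh, ctDownHigh,
                      efficiency = 1) {
  ddct <- (ctUpLow - ctDownLow) - (ctUpHigh - ctDownHigh)
  score <- 1 - (1 + efficiency)^(-ddct)
  pmin(1, pmax(0, score))
}

#' Fit a qPCR standard curve to a serial dilution series
#'
#' Least-squares line \code{Ct = slope * log10(dilution) + intercept}.
#' Perfect two-fold chemistry gives slope \code{-1/log10(2)}, about
#' -3.3219 cycles per 10-fold dilution, i.e. 100\% efficiency.
#'
#' @param log10Dilution Numeric vector of log10 relative dilutions (0 for
#'   the top standard, -1 for 10-fold diluted, ...).
#' @param ct Matching Ct values.
#' @return A [StandardCurve-class].
#' @export
fitStandardCurve <- function(log10Dilution, ct) {
  ok <- !is.na(log10Dilution) & !is.na(ct)
  x <- log10Dilution[ok]; y <- ct[ok]
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct dilutions to fit a standard curve")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("fitted slope is non-negative; Ct must increase ",
                       "as the template is diluted")
  # suppressed: summary.lm warns on numerically perfect fits, which are
  # routine for noiseless synthetic series
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new("StandardCurve", slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2, efficiency = 10^(-1 / slope) - 1,
      ctRange = range(y))
}

#' Arbitrary copy number from a standard curve
#'
#' Inverts the fitted line: \code{copies = topStandardCopies *
#' 10^((ct - intercept) / slope)}. The copy scale is arbitrary -- the top
#' standard is simply assigned a nominal copy number. A Ct outside the
#' fitted range is still converted but flagged as extrapolated.
#'
#' @param ct Numeric vector of Ct values.
#' @param curve A [StandardCurve-class].
#' @param topStandardCopies Nominal copies assigned to the top standard
#'   (default 1e6).
#' @return Numeric vector of copies with a logical
#'   \code{"extrapolated"} attribute marking Ct values outside the fitted
#'   range.
#' @export
copyNumber <- function(ct, curve, topStandardCopies = 1e6) {
  copies <- topStandardCopies * 10^((ct - curve@intercept) / curve@slope)
  extra <- ct < curve@ctRange[1L] | ct > curve@ctRange[2L]
  attr(copies, "extrapolated") <- extra
  copies
}

#' Immunoprecipitation enrichment
#'
#' Pellet/input ratio of a target RNA normalised to the same ratio of a
#' normaliser (typically U6 snRNA):
#' \code{(targetPellet/targetInput) / (normPellet/normInput)}. A target
#' behaving exactly like the normaliser scores 1. Zero or missing
#' denominators yield \code{NA}.
#'
#' @param targetPellet,targetInput,normPellet,normInput Copy numbers (all
#'   must be positive; vectorised).
#' @return Numeric vector of enrichment ratios.
#' @export
ipEnrichment <- function(targetPellet, targetInput, normPellet, normInput) {
  bad <- !is.finite(targetInput) | !is.finite(normInput) |
    !is.finite(normPellet) | !is.finite(targetPellet) |
    targetInput <= 0 | normInput <= 0 | normPellet <= 0
  out <- (targetPellet / targetInput) / (normPellet / normInput)
  out[bad] <- NA_real_
  out
}

#' Normalised expression fold change
#'
#' Copies of a target normalised to a reference RNA (U6), then to a
#' reference condition: equals 1 whenever target and normaliser scale
#' identically across conditions.
#'
#' @param targetCopies,normCopies Copies in the condition of interest.
#' @param refTargetCopies,refNormCopies Copies in the reference
#'   condition.
#' @return Numeric vector of fold changes.
#' @export
normalizedFoldChange <- function(targetCopies, normCopies,
                                 refTargetCopies, refNormCopies) {
  (targetCopies / normCopies) / (refTargetCopies / refNormCopies)
}
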