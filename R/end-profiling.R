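.asBamIfNeeded <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                            indexDestination = TRUE)
    bam
  } else file
}

#' Count read ends per reference position
#'
#' Tallies, for every position of one rRNA reference, the number of mapped
#' reads whose leftmost aligned base falls there (5' ends) and whose
#' rightmost aligned base falls there (3' ends). Only mapped, primary,
#' non-supplementary, plus-strand records are counted; ends are the
#' aligned reference span, so soft-clipped bases never move an end.
#' Reverse-strand and otherwise skipped records are tallied in the
#' profile's QC list.
#'
#' @param file Path to a SAM or BAM file of alignments against the
#'   reference (SAM is converted on the fly).
#' @param refs An [RRNAReferenceSet-class] the reads were aligned to.
#' @param molecule Molecule label to profile, e.g. \code{"18S"}.
#' @param sampleId Sample identifier recorded in the profile.
#' @param refName Sequence name used in the alignment header for this
#'   molecule; defaults to the molecule's accession, falling back to the
#'   label itself.
#' @return An [EndCountProfile-class] with \code{fivePrime} and
#'   \code{threePrime} populated and \code{combined} empty (run
#'   [combineEndCounts()] next). Zero counted reads gives a warning and an
#'   empty profile.
#' @export
countReadEnds <- function(file, refs, molecule, sampleId,
                          refName = NULL) {
  stopifnot(is(refs, "RRNAReferenceSet"))
  lens <- referenceLength(refs)
  if (!molecule %in% names(lens))
    stop("unknown molecule label: ", molecule)
  L <- unname(lens[molecule])
  if (is.null(refName)) {
    acc <- refs@accessions[match(molecule, names(refs@sequences))]
    refName <- acc
  }
  bam <- .asBamIfNeeded(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!refName %in% names(hdr)) {
    if (molecule %in% names(hdr)) refName <- molecule
    else stop("reference '", refName, "' absent from alignment header of ",
              file)
  }
  if (hdr[[refName]] != L)
    stop(sprintf("header length for %s (%d) disagrees with reference (%d)",
                 refName, hdr[[refName]], L))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  aln <- aln[as.character(GenomeInfoDb::seqnames(aln)) == refName]
  minus <- as.character(BiocGenerics::strand(aln)) == "-"
  nMinus <- sum(minus)
  aln <- aln[!minus]
  five <- integer(L); three <- integer(L)
  if (length(aln)) {
    st <- BiocGenerics::start(aln)
    en <- BiocGenerics::end(aln)
    keep <- st >= 1L & en <= L
    nOut <- sum(!keep)
    st <- st[keep]; en <- en[keep]
    t5 <- tabulate(st, nbins = L)
    t3 <- tabulate(en, nbins = L)
    five <- as.integer(t5); three <- as.integer(t3)
  } else nOut <- 0L
  total <- length(aln)
  if (total == 0L)
    warning("no counted reads for ", molecule, " in ", file,
            "; returning an empty profile")
  new("EndCountProfile", moleculeId = molecule, sampleId = sampleId,
      fivePrime = five, threePrime = three, totalReads = as.integer(total),
      qc = list(skipped_minus_strand = nMinus,
                skipped_out_of_range = nOut))
}

#' Combine 5' and 3' end counts onto the cleavage-bond coordinate
#'
#' Hydrolysis of the bond 3' of nucleotide \code{i} leaves a fragment
#' 3'-end at \code{i} and the next fragment's 5'-end at \code{i + 1}. The
#' default therefore re-indexes each 5' count from \code{i + 1} to
#' \code{i} before summation: \code{combined[i] = threePrime[i] +
#' fivePrime[i + 1]}, with \code{combined[L] = threePrime[L]}. 5' ends at
#' position 1 are natural transcript starts, not cleavage evidence; they
#' are excluded from \code{combined} and kept in the
#' \code{fivePrimeStart} slot. Counts are conserved:
#' \code{sum(combined) == sum(threePrime) + sum(fivePrime[-1])}.
#'
#' @param profile An [EndCountProfile-class] with end counts populated.
#' @param shiftDirection \code{"toward_start"} (default, described above)
#'   or \code{"toward_end"}, the mirrored convention indexing each bond by
#'   its downstream nucleotide (\code{combined[i] = threePrime[i - 1] +
#'   fivePrime[i]}; 3' ends at position L are then the excluded terminal
#'   class).
#' @return The profile with \code{combined} and \code{fivePrimeStart}
#'   filled in and the median combined coverage recorded in its QC list.
#' @export
combineEndCounts <- function(profile,
                             shiftDirection = c("toward_start",
                                                "toward_end")) {
  shiftDirection <- match.arg(shiftDirection)
  five <- profile@fivePrime
  three <- profile@threePrime
  L <- length(five)
  if (shiftDirection == "toward_start") {
    combined <- as.numeric(three) + c(five[-1L], 0L)
    profile@fivePrimeStart <- five[1L]
  } else {
    combined <- as.numeric(five) + c(0L, three[-L])
    profile@fivePrimeStart <- five[1L]
  }
  profile@combined <- combined
  profile@qc$median_combined <- stats::median(combined)
  profile@qc$shift_direction <- shiftDirection
  validObject(profile)
  profile
}

#' Coverage bookkeeping for a combined profile
#'
#' Compares the median combined count against a minimum-coverage
#' threshold; low coverage warns rather than errors, since the score
#' itself applies a per-site coverage floor.
#'
#' @param profile A combined [EndCountProfile-class].
#' @param minMedianCoverage Warning threshold (default 100).
#' @return A list of QC values (invisibly): totals, skip tallies, median
#'   combined coverage and the pass/fail flag.
#' @export
profileQC <- function(profile, minMedianCoverage = 100) {
  if (!length(profile@combined))
    stop("run combineEndCounts() before profileQC()")
  med <- stats::median(profile@combined)
  ok <- med >= minMedianCoverage
  if (!ok)
    warning(sprintf("median combined coverage %.1f below %s for %s/%s",
                    med, minMedianCoverage, profile@moleculeId,
                    profile@sampleId))
  invisible(c(profile@qc,
              list(total_reads = profile@totalReads,
                   median_coverage_ok = ok,
                   five_prime_start = profile@fivePrimeStart)))
}

#' Read a per-position end-count table
#'
#' Ingests the plain-text alternative to SAM/BAM input: a TSV with columns
#' \code{position} (1-based), \code{five_prime} and \code{three_prime},
#' one molecule per file.
#'
#' @param path Path to the TSV (\code{#} comments allowed).
#' @param molecule,sampleId Labels recorded in the profile.
#' @param length Reference length; defaults to the maximum listed
#'   position.
#' @param allowSparse If \code{TRUE}, missing positions are filled with
#'   zeros; otherwise a gap is a hard error.
#' @return An [EndCountProfile-class] (not yet combined).
#' @seealso [writeEndCountTable()]
#' @export
readEndCountTable <- function(path, molecule, sampleId, length = NULL,
                              allowSparse = FALSE) {
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("position", "five_prime", "three_prime")
  if (!all(need %in% colnames(df)))
    stop("count table needs columns position, five_prime, three_prime")
  pos <- as.integer(df$position)
  if (any(pos < 1L)) stop("positions must be 1-based and positive")
  if (anyDuplicated(pos)) stop("duplicate positions in count table")
  L <- if (is.null(length)) max(pos) else as.integer(length)
  if (any(pos > L)) stop("position beyond stated length")
  if (!allowSparse && !setequal(pos, seq_len(L)))
    stop("count table is sparse; pass allowSparse = TRUE to zero-fill")
  five <- integer(L); three <- integer(L)
  five[pos] <- as.integer(df$five_prime)
  three[pos] <- as.integer(df$three_prime)
  new("EndCountProfile", moleculeId = molecule, sampleId = sampleId,
      fivePrime = five, threePrime = three,
      totalReads = 0L, qc = list(source = path))
}

#' Write a per-position end-count table
#'
#' @param profile An [EndCountProfile-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeEndCountTable <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# end counts: molecule %s, sample %s",
                       profile@moleculeId, profile@sampleId),
               "# positions are 1-based on the mature rRNA transcript"),
             con)
  utils::write.table(
    data.frame(position = seq_along(profile@fivePrime),
               five_prime = profile@fivePrime,
               three_prime = profile@threePrime),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
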