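#' Load rRNA reference sequences from FASTA
#'
#' Reads mature rRNA reference sequences and maps their FASTA record
#' identifiers to molecule labels through an explicit mapping (no substring
#' guessing). Sequences are uppercased and \code{U} is converted to
#' \code{T}, so RNA and DNA FASTA files behave identically.
#'
#' @param path Path to a FASTA file.
#' @param moleculeMap Named character vector mapping FASTA record ids to
#'   molecule labels, e.g. \code{c(ENST00000606783 = "18S")}. Records not
#'   named in the map are dropped with a message; if \code{NULL}, record
#'   ids are used as labels directly.
#' @return An [RRNAReferenceSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">18S", "ACGUACGUACGU"), fa)
#' readRRNAReference(fa)
#' @export
readRRNAReference <- function(path, moleculeMap = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  bad <- vapply(chars, function(s) grepl("[^ACGTUN]", s), logical(1))
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  chars <- chartr("U", "T", chars)
  if (!is.null(moleculeMap)) {
    keep <- ids %in% names(moleculeMap)
    if (!all(keep))
      message("dropping unmapped FASTA record(s): ",
              paste(ids[!keep], collapse = ", "))
    if (!any(keep)) stop("no FASTA record matches the molecule map")
    chars <- chars[keep]
    acc <- ids[keep]
    labels <- unname(moleculeMap[acc])
  } else {
    acc <- ids
    labels <- ids
  }
  if (anyDuplicated(labels))
    stop("duplicate molecule labels after mapping: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dna <- Biostrings::DNAStringSet(chars)
  names(dna) <- labels
  new("RRNAReferenceSet", sequences = dna, accessions = acc)
}

.validateSites <- function(df, refs = NULL) {
  df$position <- as.integer(df$position)
  if (any(is.na(df$position)) || any(df$position < 1L))
    stop("site positions must be positive 1-based integers; offending rows: ",
         paste(which(is.na(df$position) | df$position < 1L), collapse = ", "))
  key <- paste(df$molecule_id, df$position)
  if (anyDuplicated(key))
    stop("duplicate catalogue sites: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!is.null(refs)) {
    lens <- referenceLength(refs)
    known <- df$molecule_id %in% names(lens)
    if (!all(known))
      stop("catalogue references unknown molecule(s): ",
           paste(unique(df$molecule_id[!known]), collapse = ", "))
    over <- df$position > lens[df$molecule_id]
    if (any(over))
      stop("site position(s) beyond reference length: ",
           paste(key[over], collapse = ", "))
  }
  df[order(df$molecule_id, df$position), , drop = FALSE]
}

.sitesAsGRanges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$molecule_id,
    ranges = IRanges::IRanges(start = df$position, width = 1L))
  gr$site_id <- df$site_id
  gr$guide_snorna <- df$guide_snorna
  gr
}

#' Load a catalogue of known 2'-O-methylation sites
#'
#' Reads a tab-separated catalogue with columns \code{molecule_id} and
#' \code{position} (1-based, on the mature rRNA), plus optional
#' \code{site_id} and \code{guide_snorna}. Positions are validated against
#' the reference lengths when a reference set is supplied; duplicates and
#' out-of-range positions are hard errors naming the offenders.
#'
#' @param path Path to the TSV (lines starting with \code{#} are comments).
#' @param refs Optional [RRNAReferenceSet-class] for length validation.
#' @return A \link[GenomicRanges]{GRanges}, one width-1 range per site,
#'   sorted by molecule and position, with metadata columns
#'   \code{site_id} and \code{guide_snorna}.
#' @seealso [defaultSiteCatalogue()], [writeSiteCatalogue()]
#' @export
readSiteCatalogue <- function(path, refs = NULL) {
  if (!file.exists(path)) stop("site catalogue not found: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("molecule_id", "position")
  if (!all(need %in% colnames(df)))
    stop("catalogue needs columns molecule_id and position")
  if (!"site_id" %in% colnames(df) || all(!nzchar(df$site_id)))
    df$site_id <- paste0(df$molecule_id, "_", df$position)
  if (!"guide_snorna" %in% colnames(df)) df$guide_snorna <- NA_character_
  df$guide_snorna[!nzchar(trimws(ifelse(is.na(df$guide_snorna), "",
                                        df$guide_snorna)))] <- NA_character_
  df <- .validateSites(df, refs)
  .sitesAsGRanges(df)
}

#' The packaged default site catalogue
#'
#' Returns the catalogue of known 2'-O-methylated positions on human
#' cytoplasmic rRNA bundled with the package: 42 positions on 18S and 64
#' on 28S, in 1-based mature-transcript coordinates.
#'
#' @param molecule Optional filter, \code{"18S"} or \code{"28S"}.
#' @return A \link[GenomicRanges]{GRanges} of sites (see
#'   [readSiteCatalogue()]).
#' @examples
#' length(defaultSiteCatalogue("18S"))  # 42
#' @export
defaultSiteCatalogue <- function(molecule = NULL) {
  path <- system.file("extdata", "rrna_site_catalogue.tsv",
                      package = "riboMeth", mustWork = TRUE)
  gr <- readSiteCatalogue(path)
  if (!is.null(molecule))
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% molecule]
  gr
}

#' Write a site catalogue to TSV
#'
#' Inverse of [readSiteCatalogue()]; a write-then-read round trip
#' reproduces the catalogue exactly.
#'
#' @param sites A \link[GenomicRanges]{GRanges} of catalogue sites.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSiteCatalogue <- function(sites, path) {
  df <- data.frame(
    molecule_id = as.character(GenomicRanges::seqnames(sites)),
    position = GenomicRanges::start(sites),
    site_id = sites$site_id,
    guide_snorna = ifelse(is.na(sites$guide_snorna), "", sites$guide_snorna),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# 2'-O-methylation site catalogue",
               "# Coordinates are 1-based on the mature rRNA transcript"),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
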