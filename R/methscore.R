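.neighborWeights <- function(k, scheme) {
  d <- seq_len(k)
  if (scheme == "linear_decay") (k + 1 - d) / k else rep(1, k)
}

#' Weighted neighbourhood average of the cleavage profile
#'
#' The local expectation the score C compares a site against: a weighted
#' mean of the combined counts at positions \code{i - k .. i + k}
#' (excluding \code{i}), with weights \code{(k + 1 - d) / k} decaying
#' linearly in the distance \code{d} (or uniform weights). Window
#' positions outside \code{1..L} are dropped from both the numerator and
#' the weight sum; windows never wrap or reflect at molecule ends.
#'
#' @param profile A combined [EndCountProfile-class].
#' @param position 1-based site position.
#' @param params A [ScoreParams-class] (package defaults if omitted).
#' @return The weighted average (\code{NA} if the window is empty).
#' @export
neighborAverage <- function(profile, position, params = ScoreParams()) {
  combined <- profile@combined
  if (!length(combined)) stop("run combineEndCounts() first")
  L <- length(combined)
  if (position < 1L || position > L)
    stop("position ", position, " outside 1..", L)
  k <- params@k
  w <- .neighborWeights(k, params@weightScheme)
  idxL <- position - seq_len(k)
  idxR <- position + seq_len(k)
  okL <- idxL >= 1L
  okR <- idxR <= L
  num <- sum(w[okL] * combined[idxL[okL]]) +
    sum(w[okR] * combined[idxR[okR]])
  den <- sum(w[okL]) + sum(w[okR])
  if (den == 0) return(NA_real_)
  num / den
}

.rawNeighborSum <- function(combined, position, k) {
  L <- length(combined)
  idx <- c(position - seq_len(k), position + seq_len(k))
  idx <- idx[idx >= 1L & idx <= L]
  sum(combined[idx])
}

#' Score C methylation index at one site
#'
#' The methylation index estimator: \code{MI = 1 - n_i / A_i}, where
#' \code{n_i} is the combined cleavage count at the site and \code{A_i}
#' the weighted neighbourhood average from [neighborAverage()]. A 2'-O-
#' methyl group protects the bond 3' of its nucleotide from alkaline
#' hydrolysis, so end counts at a methylated bond are depleted relative
#' to the neighbourhood in proportion to the methylated fraction; MI = 1
#' means complete protection, MI = 0 no depletion. Scores are clamped to
#' [0, 1] when \code{params@clamp} is \code{TRUE}, and are \code{NA} when
#' the neighbourhood average is zero or the raw (unweighted) neighbour
#' count sum falls below \code{params@minSiteCoverage} (low coverage must
#' not masquerade as absence of methylation).
#'
#' @inheritParams neighborAverage
#' @return The methylation index, or \code{NA}.
#' @export
scoreC <- function(profile, position, params = ScoreParams()) {
  a <- neighborAverage(profile, position, params)
  if (is.na(a) || a == 0) return(NA_real_)
  if (.rawNeighborSum(profile@combined, position, params@k) <
      params@minSiteCoverage)
    return(NA_real_)
  mi <- 1 - profile@combined[position] / a
  if (params@clamp) mi <- min(1, max(0, mi))
  mi
}

#' Score every catalogue site of one sample
#'
#' Computes the methylation index at each annotated site of the profile's
#' molecule. Only catalogued positions are ever scored; the scored vector
#' has exactly one entry (value or \code{NA}) per site.
#'
#' @param profile A combined [EndCountProfile-class].
#' @param sites Site catalogue \link[GenomicRanges]{GRanges} (all ranges
#'   must lie on the profile's molecule, otherwise a hard error).
#' @param params A [ScoreParams-class].
#' @return Named numeric vector of MI values, names = \code{site_id}.
#' @export
scoreSample <- function(profile, sites, params = ScoreParams()) {
  mol <- as.character(GenomicRanges::seqnames(sites))
  if (length(sites) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(mol != profile@moleculeId))
    stop("site catalogue refers to molecule(s) ",
         paste(setdiff(unique(mol), profile@moleculeId), collapse = ", "),
         " but the profile is for ", profile@moleculeId)
  pos <- GenomicRanges::start(sites)
  vapply(pos, function(p) scoreC(profile, p, params), numeric(1)) |>
    stats::setNames(sites$site_id)
}

#' Assemble a sites-by-samples methylation table
#'
#' @param columns Named list of per-sample score vectors from
#'   [scoreSample()] (possibly concatenated over molecules), or a numeric
#'   matrix with rownames = site ids and colnames = sample ids.
#' @param sites Site catalogue \link[GenomicRanges]{GRanges} covering
#'   every row.
#' @param design Data frame with columns \code{sample_id} and
#'   \code{group}, one row per sample column.
#' @return A [MethylationTable-class].
#' @export
buildMethylationTable <- function(columns, sites, design) {
  if (is.list(columns)) {
    ids <- names(columns[[1]])
    mat <- vapply(columns, function(x) x[ids], numeric(length(ids)))
    rownames(mat) <- ids
  } else mat <- as.matrix(columns)
  m <- match(rownames(mat), sites$site_id)
  if (any(is.na(m)))
    stop("rows absent from the site catalogue: ",
         paste(rownames(mat)[is.na(m)], collapse = ", "))
  sites <- sites[m]
  dm <- match(colnames(mat), design$sample_id)
  if (any(is.na(dm)))
    stop("samples absent from the design: ",
         paste(colnames(mat)[is.na(dm)], collapse = ", "))
  rd <- S4Vectors::DataFrame(
    molecule_id = as.character(GenomicRanges::seqnames(sites)),
    position = GenomicRanges::start(sites),
    site_id = sites$site_id)
  cd <- S4Vectors::DataFrame(group = as.character(design$group[dm]),
                             row.names = colnames(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(MI = mat), rowData = rd, colData = cd)
  new("MethylationTable", se)
}

#' Per-group mean and SEM of the methylation index
#'
#' Replicate aggregation is the arithmetic mean of per-replicate MI over
#' non-missing values (the replicate, not the pooled read count, is the
#' unit of observation), with SEM = sd / sqrt(n). A single non-missing
#' replicate keeps its value with \code{NA} SEM; a site missing in every
#' replicate of a group is flagged via \code{all_missing} so downstream
#' contrasts can exclude it.
#'
#' @param mt A [MethylationTable-class].
#' @return A long data frame: \code{site_id}, \code{molecule_id},
#'   \code{position}, \code{group}, \code{mean}, \code{sem}, \code{n},
#'   \code{all_missing}.
#' @export
aggregateReplicates <- function(mt) {
  mi <- methylationIndex(mt)
  groups <- groupLabels(mt)
  if (any(!nzchar(groups))) stop("every sample needs a group label")
  rd <- SummarizedExperiment::rowData(mt)
  out <- lapply(unique(groups), function(g) {
    sub <- mi[, groups == g, drop = FALSE]
    if (ncol(sub) == 0L) stop("group with zero samples: ", g)
    n <- rowSums(!is.na(sub))
    mean <- rowMeans(sub, na.rm = TRUE)
    mean[n == 0L] <- NA_real_
    sem <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    })
    data.frame(site_id = rd$site_id, molecule_id = rd$molecule_id,
               position = rd$position, group = g, mean = mean, sem = sem,
               n = n, all_missing = n == 0L, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Matrix of per-group mean MI
#'
#' @param mt A [MethylationTable-class].
#' @return Numeric matrix, sites x groups (rownames = site ids, column
#'   order = first appearance of each group in the design).
#' @export
groupMeans <- function(mt) {
  agg <- aggregateReplicates(mt)
  groups <- unique(groupLabels(mt))
  ids <- SummarizedExperiment::rowData(mt)$site_id
  mat <- matrix(NA_real_, length(ids), length(groups),
                dimnames = list(ids, groups))
  mat[cbind(match(agg$site_id, ids), match(agg$group, groups))] <- agg$mean
  mat
}

#' Write a methylation table as TSV
#'
#' One row per site with all per-sample MI values followed by per-group
#' mean and SEM columns; the header records the score parameters used.
#'
#' @param mt A [MethylationTable-class].
#' @param path Output path.
#' @param params The [ScoreParams-class] used for scoring (recorded in
#'   the header).
#' @return \code{path}, invisibly.
#' @export
writeMethylationTable <- function(mt, path, params = NULL) {
  mi <- methylationIndex(mt)
  rd <- SummarizedExperiment::rowData(mt)
  agg <- aggregateReplicates(mt)
  wide <- data.frame(molecule_id = rd$molecule_id, position = rd$position,
                     site_id = rd$site_id, mi,
                     check.names = FALSE, row.names = NULL)
  for (g in unique(agg$group)) {
    sub <- agg[agg$group == g, ]
    m <- match(wide$site_id, sub$site_id)
    wide[[paste0("mean_", g)]] <- sub$mean[m]
    wide[[paste0("sem_", g)]] <- sub$sem[m]
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- "# methylation index table (MI in [0,1]; 1 = fully methylated)"
  if (!is.null(params))
    hdr <- c(hdr, sprintf(
      "# score params: k = %d, weights = %s, min_site_coverage = %g, clamp = %s",
      params@k, params@weightScheme, params@minSiteCoverage, params@clamp))
  writeLines(hdr, con)
  utils::write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
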