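#' Unpaired equal-variance t-test for one site
#'
#' Two-tailed pooled-variance (Student) t-test between two groups of
#' replicate MI values. Degenerate inputs are handled explicitly: fewer
#' than two non-missing values in either group yields a missing p with a
#' reason code; zero within-group variance with unequal means is treated
#' as p = 0 with a degeneracy flag, and with equal means as p = 1.
#'
#' @param valuesA,valuesB Numeric vectors of replicate MI values
#'   (\code{NA}s dropped).
#' @return List with \code{p_value}, \code{delta} (mean(B) - mean(A)),
#'   \code{t}, \code{df} and \code{reason} (\code{NA} when the test ran
#'   cleanly).
#' @export
ttestSite <- function(valuesA, valuesB) {
  a <- valuesA[!is.na(valuesA)]
  b <- valuesB[!is.na(valuesB)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(p_value = NA_real_, delta = mean(b) - mean(a),
                t = NA_real_, df = NA_real_,
                reason = "fewer than 2 values in a group"))
  delta <- mean(b) - mean(a)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (delta == 0)
      return(list(p_value = 1, delta = 0, t = 0,
                  df = length(a) + length(b) - 2L,
                  reason = "zero variance, equal means"))
    return(list(p_value = 0, delta = delta, t = Inf * sign(delta),
                df = length(a) + length(b) - 2L,
                reason = "zero variance, unequal means"))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(p_value = unname(tt$p.value), delta = delta,
       t = -unname(tt$statistic), df = unname(tt$parameter),
       reason = NA_character_)
}

#' One-way ANOVA with Tukey's multiple-comparison test for one site
#'
#' Fits a one-way ANOVA across three or more groups of replicate MI
#' values and follows it with Tukey's HSD over all group pairs (the
#' Tukey--Kramer harmonic-mean form when group sizes are unbalanced, as
#' provided by \code{\link[stats]{TukeyHSD}}).
#'
#' @param values Numeric vector of replicate MI values.
#' @param groups Group label per value (coerced to factor).
#' @return List with \code{anova_p}, \code{f}, \code{tukey_p} (named
#'   vector over group pairs, names like \code{"B-A"}) and \code{reason}
#'   (\code{NA} when the test ran; the site is skipped with a reason when
#'   any group has fewer than 2 non-missing values or all values are
#'   identical).
#' @export
anovaTukeySite <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  skipped <- list(anova_p = NA_real_, f = NA_real_, tukey_p = NULL,
                  reason = "fewer than 2 values in a group")
  if (nlevels(groups) < 3L) {
    skipped$reason <- "fewer than 3 groups"
    return(skipped)
  }
  if (any(table(groups) < 2L)) return(skipped)
  if (stats::var(values) == 0) {
    npair <- choose(nlevels(groups), 2L)
    combs <- utils::combn(levels(groups), 2L)
    return(list(anova_p = 1, f = 0,
                tukey_p = stats::setNames(rep(1, npair),
                                          paste(combs[2L, ], combs[1L, ],
                                                sep = "-")),
                reason = NA_character_))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(anova_p = an[["Pr(>F)"]][1L], f = an[["F value"]][1L],
       tukey_p = stats::setNames(tk[, "p adj"], rownames(tk)),
       reason = NA_character_)
}

#' Classify a per-site methylation shift
#'
#' A site is \code{"hyper"} when its shift is significant and the second
#' group's mean MI exceeds the first's, \code{"hypo"} when significant in
#' the other direction, and \code{"unchanged"} otherwise (including a
#' missing p). A significant shift with delta exactly 0 cannot be given a
#' direction and is classified \code{"unchanged"} with a warning.
#'
#' @param pValue Per-site p-value (vectorised).
#' @param delta Mean difference, second group minus first (vectorised).
#' @param alpha Significance level (default 0.05).
#' @return Character vector in \code{c("hyper", "hypo", "unchanged")}.
#' @export
classifyShift <- function(pValue, delta, alpha = 0.05) {
  sig <- !is.na(pValue) & pValue < alpha
  tied <- sig & delta == 0
  if (any(tied))
    warning(sum(tied), " significant site(s) with delta exactly 0 ",
            "classified as unchanged")
  ifelse(sig & delta > 0, "hyper",
         ifelse(sig & delta < 0, "hypo", "unchanged"))
}

#' Pairwise group contrast over all sites
#'
#' Runs [ttestSite()] at every catalogue site for one ordered group pair
#' and classifies each shift with [classifyShift()]. Sites lacking two
#' non-missing replicates in either group carry an \code{NA} p and the
#' reason.
#'
#' @param mt A [MethylationTable-class].
#' @param groupA,groupB Group labels; delta is \code{groupB - groupA}.
#' @param alpha Significance level.
#' @param adjust \code{"none"} (default; per-site unadjusted alpha) or
#'   \code{"BH"} for a Benjamini--Hochberg corrected p column used for
#'   classification instead.
#' @return Data frame with one row per site: means, delta, t, p,
#'   (optionally adjusted p,) classification and reason.
#' @export
compareGroups <- function(mt, groupA, groupB, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- groupLabels(mt)
  for (g in c(groupA, groupB))
    if (!g %in% groups) stop("unknown group: ", g)
  mi <- methylationIndex(mt)
  rd <- SummarizedExperiment::rowData(mt)
  res <- lapply(seq_len(nrow(mi)), function(i) {
    ttestSite(mi[i, groups == groupA], mi[i, groups == groupB])
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  delta <- vapply(res, `[[`, numeric(1), "delta")
  out <- data.frame(
    site_id = rd$site_id, molecule_id = rd$molecule_id,
    position = rd$position,
    mean_a = rowMeans(mi[, groups == groupA, drop = FALSE], na.rm = TRUE),
    mean_b = rowMeans(mi[, groups == groupB, drop = FALSE], na.rm = TRUE),
    delta = delta, t = vapply(res, `[[`, numeric(1), "t"),
    p_value = p,
    reason = vapply(res, `[[`, character(1), "reason"),
    row.names = NULL)
  pClass <- p
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(p, method = "BH")
    pClass <- out$p_adjusted
  }
  out$classification <- classifyShift(pClass, delta, alpha)
  attr(out, "contrast") <- paste(groupA, "vs", groupB)
  attr(out, "alpha") <- alpha
  out
}

#' Three-or-more-group trajectory ANOVA over all sites
#'
#' Runs [anovaTukeySite()] at every site across an ordered set of groups,
#' mirroring the per-site ANOVA + Tukey layout used for differentiation
#' trajectories.
#'
#' @param mt A [MethylationTable-class].
#' @param groups Ordered character vector of at least three group labels.
#' @return Data frame with per-group means, \code{anova_p} and one Tukey
#'   p column per group pair.
#' @export
trajectoryAnova <- function(mt, groups = unique(groupLabels(mt))) {
  if (length(groups) < 3L) stop("need at least 3 groups")
  lab <- groupLabels(mt)
  for (g in groups) if (!g %in% lab) stop("unknown group: ", g)
  mi <- methylationIndex(mt)
  rd <- SummarizedExperiment::rowData(mt)
  keep <- lab %in% groups
  mi <- mi[, keep, drop = FALSE]
  lab <- lab[keep]
  pairs <- utils::combn(groups, 2L)
  pairNames <- paste(pairs[1L, ], pairs[2L, ], sep = "_vs_")
  rows <- lapply(seq_len(nrow(mi)), function(i) {
    r <- anovaTukeySite(mi[i, ], lab)
    tp <- rep(NA_real_, ncol(pairs))
    if (!is.null(r$tukey_p)) {
      for (j in seq_len(ncol(pairs))) {
        nm1 <- paste(pairs[2L, j], pairs[1L, j], sep = "-")
        nm2 <- paste(pairs[1L, j], pairs[2L, j], sep = "-")
        tp[j] <- if (nm1 %in% names(r$tukey_p)) r$tukey_p[[nm1]]
                 else if (nm2 %in% names(r$tukey_p)) r$tukey_p[[nm2]]
                 else NA_real_
      }
    }
    c(anova_p = r$anova_p, stats::setNames(tp, paste0("tukey_", pairNames)))
  })
  stat <- do.call(rbind, rows)
  means <- vapply(groups, function(g)
    rowMeans(mi[, lab == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(mi)))
  colnames(means) <- paste0("mean_", groups)
  data.frame(site_id = rd$site_id, molecule_id = rd$molecule_id,
             position = rd$position, means, stat, row.names = NULL)
}

#' Select hypomethylated sites
#'
#' A site is hypomethylated in a group when its group-mean MI is at or
#' below the threshold (inclusive; default 0.9).
#'
#' @param x A [MethylationTable-class], or a data frame with columns
#'   \code{site_id}, \code{group} and \code{mean} (as produced by
#'   [aggregateReplicates()]).
#' @param group Group label to select within.
#' @param threshold Inclusive MI cutoff (default 0.9).
#' @return Character vector of selected \code{site_id}s.
#' @export
selectHypomethylated <- function(x, group, threshold = 0.9) {
  agg <- if (is(x, "MethylationTable")) aggregateReplicates(x) else x
  if (!group %in% agg$group) stop("unknown group: ", group)
  sub <- agg[agg$group == group & !is.na(agg$mean), ]
  sub$site_id[sub$mean <= threshold]
}

#' Count significant sites per molecule and shift class
#'
#' @param comparisons A contrast data frame from [compareGroups()] (or any
#'   data frame with \code{molecule_id}, \code{p_value} and
#'   \code{classification}).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per molecule: \code{n_significant},
#'   \code{n_hyper}, \code{n_hypo}.
#' @export
countSignificant <- function(comparisons, alpha = 0.05) {
  if (nrow(comparisons) == 0L)
    return(data.frame(molecule_id = character(0),
                      n_significant = integer(0), n_hyper = integer(0),
                      n_hypo = integer(0)))
  sig <- !is.na(comparisons$p_value) & comparisons$p_value < alpha
  mol <- comparisons$molecule_id
  out <- lapply(unique(mol), function(m) {
    s <- sig & mol == m
    data.frame(molecule_id = m, n_significant = sum(s),
               n_hyper = sum(s & comparisons$classification == "hyper"),
               n_hypo = sum(s & comparisons$classification == "hypo"))
  })
  do.call(rbind, out)
}

#' Heatmap matrix with variable/saturated row grouping
#'
#' Splits catalogue sites into "variable" rows, whose group means span
#' more than \code{variabilityDelta}, and "saturated" rows (everything
#' else), and exports the per-sample MI matrix in that row order for
#' plotting.
#'
#' @param mt A [MethylationTable-class] with at least two samples.
#' @param variabilityDelta Span threshold on group means (default 0.05).
#' @return List with \code{matrix} (sites x samples MI), \code{grouping}
#'   (factor \code{variable}/\code{saturated} per row) and
#'   \code{group_means}.
#' @seealso [plotMethylationHeatmap()]
#' @export
heatmapMatrix <- function(mt, variabilityDelta = 0.05) {
  if (ncol(mt) < 2L) stop("need at least 2 sample columns")
  gm <- groupMeans(mt)
  span <- apply(gm, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(0)
    max(v) - min(v)
  })
  grouping <- factor(ifelse(span > variabilityDelta, "variable",
                            "saturated"),
                     levels = c("variable", "saturated"))
  ord <- order(grouping)
  mi <- methylationIndex(mt)
  rownames(mi) <- SummarizedExperiment::rowData(mt)$site_id
  list(matrix = mi[ord, , drop = FALSE], grouping = grouping[ord],
       group_means = gm[ord, , drop = FALSE])
}

#' Render a methylation heatmap to file
#'
#' Thin adapter over \pkg{pheatmap} applied to the matrix from
#' [heatmapMatrix()]; the plotting backend is deliberately replaceable
#' since the exported matrix is the primary product.
#'
#' @param hm A list from [heatmapMatrix()].
#' @param file Output image path (PNG).
#' @param ... Passed to \code{pheatmap::pheatmap}.
#' @return \code{file}, invisibly.
#' @export
plotMethylationHeatmap <- function(hm, file, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("the pheatmap package is required for plotting")
  ann <- data.frame(class = hm$grouping,
                    row.names = rownames(hm$matrix))
  grDevices::png(file, width = 1200, height = 1600, res = 150)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(hm$matrix, cluster_rows = FALSE,
                     annotation_row = ann, ...)
  invisible(file)
}
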