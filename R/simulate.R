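#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed}, so simulator calls never leak
#' RNG state into the caller.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate alkaline-hydrolysis fragment end counts
#'
#' Emulates the controlled-hydrolysis step of RiboMeth-Seq. Each internal
#' bond \code{i} (3' of nucleotide \code{i}, for \code{i} in
#' \code{1..L-1}) is cut with probability proportional to
#' \code{cleavage[i] * (1 - rho * methylation[i])}; methylation depletes
#' read ends at its bond in proportion to the methylated fraction.
#'
#' In the default \code{"ends"} mode, \code{nFragments} cleavage events
#' are drawn multinomially and each event is emitted as a matched 3' end
#' at \code{i} and 5' end at \code{i + 1}, so [combineEndCounts()]
#' reconstructs the cleavage profile exactly (each event contributes two
#' matched end counts) and expected combined counts are analytic. The
#' \code{"fragments"} mode instead samples cut pairs \code{(i, j)} with a
#' fragment-length window (emulating gel size selection of the library),
#' emitting the 5' end at \code{i + 1} and the 3' end at \code{j}; it
#' stresses edge behaviour at the cost of analytic expectations.
#'
#' @param truth A [SimulationTruth-class].
#' @param mode \code{"ends"} (default) or \code{"fragments"}.
#' @param fragmentLength Length-2 integer window for \code{"fragments"}
#'   mode (default \code{c(30, 50)}, the size-selected band).
#' @return An [EndCountProfile-class] (not yet combined) with
#'   \code{moleculeId "sim"} unless overridden via \code{molecule}.
#' @param molecule,sampleId Labels for the emitted profile.
#' @export
simulateEndCounts <- function(truth, mode = c("ends", "fragments"),
                              fragmentLength = c(30L, 50L),
                              molecule = "sim", sampleId = "sim") {
  mode <- match.arg(mode)
  stopifnot(is(truth, "SimulationTruth"))
  L <- truth@length
  w <- truth@cleavage * (1 - truth@rho * truth@methylation)
  w <- w[seq_len(L - 1L)]  # bond L is the transcript 3' end, not cleavable
  if (all(w <= 0)) stop("all adjusted cleavage propensities are zero")
  p <- w / sum(w)
  five <- integer(L); three <- integer(L)
  .withSeed(truth@seed, {
    if (mode == "ends") {
      x <- as.integer(stats::rmultinom(1L, truth@nFragments, p))
      three[seq_len(L - 1L)] <- x
      five[seq_len(L - 1L) + 1L] <- x
    } else {
      minL <- fragmentLength[1L]; maxL <- fragmentLength[2L]
      i <- sample.int(L - 1L, truth@nFragments, replace = TRUE, prob = p)
      for (cut in i) {
        lo <- cut + minL; hi <- min(cut + maxL, L - 1L)
        if (lo > hi) next
        idx <- lo:hi
        pw <- w[idx]
        if (all(pw <= 0)) next
        j <- idx[sample.int(length(idx), 1L, prob = pw)]
        five[cut + 1L] <- five[cut + 1L] + 1L
        three[j] <- three[j] + 1L
      }
    }
  })
  new("EndCountProfile", moleculeId = molecule, sampleId = sampleId,
      fivePrime = five, threePrime = three,
      totalReads = truth@nFragments,
      qc = list(simulated = TRUE, mode = mode, seed = truth@seed))
}

.parseSiteIds <- function(ids) {
  m <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  data.frame(site_id = ids,
             molecule_id = ifelse(ok, vapply(m, function(x)
               if (length(x) == 3L) x[2L] else "sim", character(1)), "sim"),
             position = ifelse(ok, as.integer(vapply(m, function(x)
               if (length(x) == 3L) x[3L] else NA_character_,
               character(1))), seq_along(ids)),
             stringsAsFactors = FALSE)
}

#' Simulate a replicate MI matrix with group effects
#'
#' Draws replicate methylation indices around per-site per-group true
#' means, with Gaussian noise clamped to [0, 1] (or beta noise with
#' matched mean for boundary-heavy truths), and returns them as a
#' [MethylationTable-class] whose metadata carries the generating truth
#' for recovery tests.
#'
#' @param spec A [GroupEffectSpec-class].
#' @return A [MethylationTable-class]; \code{metadata(x)$truth} is the
#'   true mean matrix and \code{metadata(x)$spec} the generating spec.
#' @export
simulateMIMatrix <- function(spec) {
  stopifnot(is(spec, "GroupEffectSpec"))
  groups <- colnames(spec@means)
  reps <- spec@nPerGroup[groups]
  sampleIds <- unlist(lapply(groups, function(g)
    paste0(g, "_r", seq_len(reps[[g]]))))
  groupOf <- rep(groups, times = reps[groups])
  nSite <- nrow(spec@means)
  mat <- matrix(NA_real_, nSite, length(sampleIds),
                dimnames = list(rownames(spec@means), sampleIds))
  .withSeed(spec@seed, {
    for (j in seq_along(sampleIds)) {
      mu <- spec@means[, groupOf[j]]
      if (spec@sigma == 0) {
        mat[, j] <- mu
      } else if (spec@noiseModel == "gaussian") {
        mat[, j] <- pmin(1, pmax(0, stats::rnorm(nSite, mu, spec@sigma)))
      } else {
        # beta with mean mu and variance min(sigma^2, mu(1-mu)*0.9)
        v <- pmin(spec@sigma^2, mu * (1 - mu) * 0.9)
        v[v <= 0] <- 1e-8
        conc <- mu * (1 - mu) / v - 1
        conc[conc <= 0] <- 1e-3
        mat[, j] <- stats::rbeta(nSite, mu * conc, (1 - mu) * conc)
      }
    }
  })
  info <- .parseSiteIds(rownames(spec@means))
  sites <- GenomicRanges::GRanges(
    info$molecule_id, IRanges::IRanges(info$position, width = 1L))
  sites$site_id <- info$site_id
  sites$guide_snorna <- NA_character_
  design <- data.frame(sample_id = sampleIds, group = groupOf)
  mt <- buildMethylationTable(mat, sites, design)
  S4Vectors::metadata(mt)$truth <- spec@means
  S4Vectors::metadata(mt)$spec <- spec
  mt
}

#' Simulate RTL-P Ct quadruplets from true methylated fractions
#'
#' Inverts the [rtlpIndex()] model: the spanning amplicon's low-dNTP Ct
#' is displaced by \code{-log2(1 - m)} cycles relative to its high-dNTP
#' Ct, the non-spanning amplicon is unaffected, and Gaussian cycle noise
#' is added to all four Ct values. With zero noise, [rtlpIndex()]
#' recovers \code{m} exactly.
#'
#' @param m True methylated fractions (values must be < 1 for finite Ct).
#' @param sigmaCt Per-Ct Gaussian noise SD in cycles (default 0).
#' @param seed Integer seed.
#' @param ctDown,ctUp Baseline Ct of the non-spanning and spanning
#'   amplicons under high dNTP.
#' @return Data frame with \code{site_id}, the four Ct columns and
#'   \code{true_m}.
#' @export
simulateRTLPCt <- function(m, sigmaCt = 0, seed = 1L,
                           ctDown = 20, ctUp = 22) {
  if (any(m >= 1)) stop("true fractions must be < 1 (complete methylation",
                        " gives an unbounded RT block)")
  ddct <- -log2(1 - m)
  n <- length(m)
  ids <- if (is.null(names(m))) paste0("site", seq_len(n)) else names(m)
  .withSeed(seed, {
    noise <- matrix(stats::rnorm(4L * n, 0, sigmaCt), n, 4L)
    data.frame(site_id = ids,
               ct_up_low = ctUp + ddct + noise[, 1L],
               ct_down_low = ctDown + noise[, 2L],
               ct_up_high = ctUp + noise[, 3L],
               ct_down_high = ctDown + noise[, 4L],
               true_m = m, row.names = NULL)
  })
}

#' Simulate a qPCR serial dilution series
#'
#' Generates Ct values on a line with the slope implied by the given
#' amplification efficiency (\code{-1/log10(1 + efficiency)} cycles per
#' 10-fold dilution), plus Gaussian cycle noise.
#'
#' @param log10Dilution Dilution grid (default \code{0, -1, -2, -3}).
#' @param interceptCt Ct of the top standard.
#' @param efficiency Amplification efficiency (default 1 = 100\%).
#' @param sigmaCt Gaussian noise SD in cycles.
#' @param seed Integer seed.
#' @return Data frame with \code{log10_dilution} and \code{ct}, with the
#'   generating slope in attribute \code{"slope"}.
#' @export
simulateDilutionSeries <- function(log10Dilution = 0:-3, interceptCt = 20,
                                   efficiency = 1, sigmaCt = 0, seed = 1L) {
  slope <- -1 / log10(1 + efficiency)
  .withSeed(seed, {
    ct <- interceptCt + slope * log10Dilution +
      stats::rnorm(length(log10Dilution), 0, sigmaCt)
    out <- data.frame(log10_dilution = log10Dilution, ct = ct)
    attr(out, "slope") <- slope
    out
  })
}

.randomSequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

.writeSAM <- function(path, refName, refLen, refSeq, five, three,
                      fragmentRange = c(30L, 50L)) {
  # reconstruct one read per matched (5', 3') event pair; events were
  # emitted pairwise so pairing by order within position is exact enough
  # for fixture purposes when produced by the fragments-mode simulator
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen)), con)
  starts <- rep(seq_along(five), five)
  ends <- rep(seq_along(three), three)
  n <- min(length(starts), length(ends))
  if (n) {
    starts <- sort(starts)[seq_len(n)]
    ends <- sort(ends)[seq_len(n)]
    ends <- pmax(ends, starts)  # guard degenerate pairs at molecule edges
    len <- ends - starts + 1L
    seqs <- substring(refSeq, starts, ends)
    writeLines(sprintf("read%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       seq_len(n), refName, starts, len, seqs), con)
  }
  invisible(path)
}

#' Write a complete miniature fixture dataset
#'
#' Emits everything the pipeline consumes, generated from known truth:
#' rRNA reference FASTA, site catalogue TSV, SAM alignments and
#' per-position count tables for every sample, a design table, RTL-P and
#' dilution-series Ct tables, and a YAML truth manifest. Byte-identical
#' for a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param moleculeLengths Named lengths of the miniature molecules.
#' @param groups Group labels.
#' @param nReplicates Replicates per group.
#' @param nFragments Cleavage events per molecule per sample.
#' @return Invisibly, a list describing the written files and the truth.
#' @export
writeFixtures <- function(dir, seed = 1L,
                          moleculeLengths = c(`18S` = 250L, `28S` = 400L),
                          groups = c("ESC_WT", "NSC_WT", "Neuron_WT"),
                          nReplicates = 3L, nFragments = 20000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  refSeqs <- .withSeed(seed, lapply(moleculeLengths, .randomSequence))
  fa <- file.path(dir, "references.fa")
  writeLines(unlist(lapply(names(refSeqs), function(m)
    c(paste0(">", m), refSeqs[[m]]))), fa)

  # truth: three sites per molecule with group-dependent methylation
  siteTruth <- list()
  for (m in names(moleculeLengths)) {
    L <- moleculeLengths[[m]]
    pos <- as.integer(round(c(0.25, 0.5, 0.75) * L))
    mi <- rbind(c(0.30, 0.70, 0.95),   # rises along the trajectory
                c(0.90, 0.90, 0.90),   # constant partial
                c(0.99, 0.99, 0.99))   # saturated
    colnames(mi) <- groups
    rownames(mi) <- paste0(m, "_", pos)
    siteTruth[[m]] <- list(positions = pos, mi = mi)
  }
  catPath <- file.path(dir, "site_catalogue.tsv")
  catDf <- do.call(rbind, lapply(names(siteTruth), function(m)
    data.frame(molecule_id = m, position = siteTruth[[m]]$positions,
               site_id = rownames(siteTruth[[m]]$mi), guide_snorna = "")))
  con <- file(catPath, "w")
  writeLines("# miniature synthetic site catalogue (1-based positions)", con)
  utils::write.table(catDf, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  design <- data.frame(
    sample_id = unlist(lapply(groups, function(g)
      paste0(g, "_r", seq_len(nReplicates)))),
    group = rep(groups, each = nReplicates))
  utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  samDir <- file.path(dir, "sam"); countDir <- file.path(dir, "counts")
  dir.create(samDir, showWarnings = FALSE)
  dir.create(countDir, showWarnings = FALSE)
  sampleSeed <- 0L
  for (s in seq_len(nrow(design))) {
    for (m in names(moleculeLengths)) {
      sampleSeed <- sampleSeed + 1L
      L <- moleculeLengths[[m]]
      meth <- rep(0, L)
      meth[siteTruth[[m]]$positions] <-
        siteTruth[[m]]$mi[, design$group[s]]
      truth <- SimulationTruth(L, methylation = meth,
                               nFragments = nFragments,
                               seed = seed * 1000L + sampleSeed)
      prof <- simulateEndCounts(truth, mode = "fragments",
                                molecule = m,
                                sampleId = design$sample_id[s])
      .writeSAM(file.path(samDir,
                          paste0(design$sample_id[s], "_", m, ".sam")),
                m, L, refSeqs[[m]], prof@fivePrime, prof@threePrime)
      writeEndCountTable(prof, file.path(
        countDir, paste0(design$sample_id[s], "_", m, ".tsv")))
    }
  }

  rtlpTruth <- c(site_a = 0.3, site_b = 0.7, site_c = 0.9)
  rtlp <- simulateRTLPCt(rtlpTruth, sigmaCt = 0.2, seed = seed + 7L)
  utils::write.table(rtlp, file.path(dir, "qpcr_rtlp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dil <- simulateDilutionSeries(sigmaCt = 0.1, seed = seed + 11L)
  utils::write.table(dil, file.path(dir, "qpcr_dilution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = as.integer(seed),
    n_fragments = as.integer(nFragments),
    molecules = lapply(siteTruth, function(st) list(
      positions = as.integer(st$positions),
      true_mi = apply(st$mi, 1L, as.list))),
    rtlp_true_m = as.list(rtlpTruth),
    dilution_slope = unname(attr(dil, "slope")))
  yaml::write_yaml(manifest, file.path(dir, "truth.yaml"))

  invisible(list(dir = dir, design = design, truth = siteTruth,
                 catalogue = catPath, references = fa,
                 rtlp_truth = rtlpTruth))
}
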