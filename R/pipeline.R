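#' Read a sample design table
#'
#' @param path TSV with columns \code{sample_id} and \code{group}.
#' @return Data frame; every sample maps to exactly one non-empty group.
#' @export
readGroupDesign <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("design needs columns sample_id and group")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  if (any(!nzchar(df$group))) stop("empty group label in design")
  df
}

.configDefaults <- list(
  alpha = 0.05, hypo_threshold = 0.9, variability_delta = 0.05,
  seed = 1L, input = list(type = "counts"),
  score = list(k = 6, weight_scheme = "linear_decay",
               min_site_coverage = 100, clamp = TRUE))

#' Read and validate a pipeline run configuration
#'
#' Reads the YAML configuration driving [runPipeline()] and validates it,
#' reporting every problem at once rather than stopping at the first.
#'
#' @param path Path to a YAML file (see the packaged example under
#'   \code{system.file("extdata", "example_config.yaml", package =
#'   "riboMeth")}).
#' @return A validated config list with defaults filled in; the
#'   canonical-YAML md5 is stored in attribute \code{"config_hash"}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(.configDefaults, cfg)
  errs <- character()
  need_file <- function(p, what) {
    if (is.null(p)) errs <<- c(errs, paste0("missing config key: ", what))
    else if (!file.exists(p))
      errs <<- c(errs, sprintf("%s does not exist: %s", what, p))
  }
  need_file(cfg$reference$fasta, "reference.fasta")
  need_file(cfg$catalogue, "catalogue")
  need_file(cfg$design, "design")
  if (is.null(cfg$out_dir)) errs <- c(errs, "missing config key: out_dir")
  if (!cfg$input$type %in% c("counts", "sam"))
    errs <- c(errs, "input.type must be 'counts' or 'sam'")
  groups <- NULL
  if (!is.null(cfg$design) && file.exists(cfg$design))
    groups <- unique(readGroupDesign(cfg$design)$group)
  known <- function(g, where) {
    if (!is.null(groups) && !g %in% groups)
      errs <<- c(errs, sprintf("%s references unknown group '%s'", where, g))
  }
  for (ct in cfg$contrasts) for (g in ct) known(g, "contrast")
  for (g in cfg$trajectory) known(g, "trajectory")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  attr(cfg, "config_hash") <- .hashObject(cfg)
  cfg
}

.hashObject <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}

.provenance <- function(cfg, ...) {
  extra <- c(...)
  c(sprintf("# riboMeth %s", as.character(utils::packageVersion("riboMeth"))),
    sprintf("# config_hash: %s", attr(cfg, "config_hash")),
    sprintf("# seed: %s", cfg$seed),
    sprintf("# catalogue_md5: %s", unname(tools::md5sum(cfg$catalogue))),
    if (length(extra)) paste0("# ", extra))
}

.log <- function(cfg, level, fmt, ...) {
  line <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  logfile <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) cat(line, "\n", file = logfile,
                                   append = TRUE, sep = "")
  message(line)
  invisible(line)
}

.scoreParamsFromConfig <- function(cfg) {
  s <- cfg$score
  ScoreParams(k = s$k, weightScheme = s$weight_scheme,
              minSiteCoverage = s$min_site_coverage, clamp = s$clamp)
}

#' Generate the fixture dataset described by a configuration
#'
#' Wraps [writeFixtures()] with the configured seed and logs a truth
#' summary.
#'
#' @param cfg Config list from [readRunConfig()], or a directory plus
#'   seed via \code{out}/\code{seed} arguments for standalone use.
#' @param out Output directory (default \code{file.path(cfg$out_dir,
#'   "fixtures")}).
#' @return The [writeFixtures()] result, invisibly.
#' @export
runSimulate <- function(cfg, out = file.path(cfg$out_dir, "fixtures")) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- writeFixtures(out, seed = cfg$seed)
  .log(cfg, "INFO", "simulated fixtures in %s (seed %s, %d samples)",
       out, cfg$seed, nrow(res$design))
  invisible(res)
}

#' Score every sample of a configured run
#'
#' Loads each sample's end counts (SAM or count-table input), combines
#' them onto the cleavage coordinate and scores the catalogue, producing
#' one [MethylationTable-class] per molecule and writing each as TSV with
#' a provenance header. A sample present in the design but missing on
#' disk is a hard error naming it.
#'
#' @param cfg Config list from [readRunConfig()].
#' @return Named list of [MethylationTable-class], one per molecule.
#' @export
runScore <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- readRRNAReference(cfg$reference$fasta,
                            moleculeMap = unlist(cfg$reference$map))
  sites <- readSiteCatalogue(cfg$catalogue, refs)
  design <- readGroupDesign(cfg$design)
  params <- .scoreParamsFromConfig(cfg)
  lens <- referenceLength(refs)
  tables <- list()
  for (mol in names(lens)) {
    molSites <- sites[as.character(GenomicRanges::seqnames(sites)) == mol]
    if (!length(molSites)) next
    cols <- list()
    for (s in design$sample_id) {
      ext <- if (cfg$input$type == "counts") ".tsv" else ".sam"
      f <- file.path(cfg$input$dir, paste0(s, "_", mol, ext))
      if (!file.exists(f))
        stop("input for sample '", s, "' (", mol, ") missing on disk: ", f)
      prof <- if (cfg$input$type == "counts")
        readEndCountTable(f, mol, s, length = lens[[mol]])
      else countReadEnds(f, refs, mol, s)
      prof <- combineEndCounts(prof)
      cols[[s]] <- scoreSample(prof, molSites, params)
    }
    mt <- buildMethylationTable(cols, molSites, design)
    out <- file.path(cfg$out_dir, paste0("mi_", mol, ".tsv"))
    con <- file(out, "w")
    writeLines(.provenance(cfg, paste0("molecule: ", mol)), con)
    close(con)
    tmp <- tempfile()
    writeMethylationTable(mt, tmp, params)
    file.append(out, tmp)
    unlink(tmp)
    .log(cfg, "INFO", "scored %s: %d sites x %d samples -> %s", mol,
         nrow(mt), ncol(mt), out)
    tables[[mol]] <- mt
  }
  tables
}

#' Differential analysis of a configured run
#'
#' Runs every configured pairwise contrast and the multi-group
#' trajectory ANOVA on each molecule's methylation table, writing
#' per-contrast statistics, hyper/hypo membership lists,
#' significant-site counts and the heatmap matrix.
#'
#' @param cfg Config list from [readRunConfig()].
#' @param tables Named list of [MethylationTable-class] from
#'   [runScore()].
#' @return Invisibly, a list with \code{contrasts}, \code{counts},
#'   \code{hypo} and \code{heatmap} components per molecule.
#' @export
runDiff <- function(cfg, tables) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (mol in names(tables)) {
    mt <- tables[[mol]]
    groups <- unique(groupLabels(mt))
    if (length(groups) < 2L) stop("need at least 2 groups, got: ",
                                  paste(groups, collapse = ", "))
    res <- list()
    for (ct in cfg$contrasts) {
      cmp <- compareGroups(mt, ct[[1]], ct[[2]], alpha = cfg$alpha)
      label <- paste0(ct[[1]], "_vs_", ct[[2]])
      f <- file.path(cfg$out_dir,
                     paste0("contrast_", mol, "_", label, ".tsv"))
      con <- file(f, "w")
      writeLines(.provenance(cfg, paste0("contrast: ", label)), con)
      suppressWarnings(utils::write.table(cmp, con, sep = "\t",
                                          quote = FALSE,
                                          row.names = FALSE))
      close(con)
      memb <- split(cmp$site_id, cmp$classification)
      res[[label]] <- list(comparison = cmp,
                           counts = countSignificant(cmp, cfg$alpha),
                           hyper = memb$hyper, hypo = memb$hypo)
      .log(cfg, "INFO", "%s %s: %d significant sites", mol, label,
           sum(res[[label]]$counts$n_significant))
    }
    if (length(cfg$trajectory) >= 3L) {
      tr <- trajectoryAnova(mt, unlist(cfg$trajectory))
      f <- file.path(cfg$out_dir, paste0("trajectory_", mol, ".tsv"))
      con <- file(f, "w")
      writeLines(.provenance(cfg, "trajectory ANOVA + Tukey MCT"), con)
      utils::write.table(tr, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      res$trajectory <- tr
    }
    hypo <- selectHypomethylated(mt, groupLabels(mt)[1L],
                                 cfg$hypo_threshold)
    hm <- heatmapMatrix(mt, cfg$variability_delta)
    f <- file.path(cfg$out_dir, paste0("heatmap_", mol, ".tsv"))
    con <- file(f, "w")
    writeLines(.provenance(cfg, "heatmap matrix; rows grouped variable/saturated"),
               con)
    utils::write.table(
      data.frame(site_id = rownames(hm$matrix), class = hm$grouping,
                 hm$matrix, check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    out[[mol]] <- c(res, list(hypo = hypo, heatmap = hm))
  }
  invisible(out)
}

#' qPCR analyses of a configured run
#'
#' Scores an RTL-P Ct table and fits a dilution-series standard curve
#' when the corresponding files are configured, writing one result TSV
#' per assay. Rows with missing Ct values score \code{NA} and the run
#' continues.
#'
#' @param cfg Config list from [readRunConfig()].
#' @return Invisibly, a list with \code{rtlp} (scored data frame) and
#'   \code{curve} (a [StandardCurve-class]) where configured.
#' @export
runQpcr <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (!is.null(cfg$qpcr$rtlp)) {
    ct <- utils::read.delim(cfg$qpcr$rtlp, comment.char = "#")
    ct$mi_rtlp <- rtlpIndex(ct$ct_up_low, ct$ct_down_low,
                            ct$ct_up_high, ct$ct_down_high)
    f <- file.path(cfg$out_dir, "rtlp_scores.tsv")
    con <- file(f, "w")
    writeLines(.provenance(cfg, "RTL-P score = 1 - 2^(-ddCt), clamped to [0,1]"),
               con)
    utils::write.table(ct, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    .log(cfg, "INFO", "RTL-P: scored %d rows -> %s", nrow(ct), f)
    out$rtlp <- ct
  }
  if (!is.null(cfg$qpcr$dilution)) {
    dil <- utils::read.delim(cfg$qpcr$dilution, comment.char = "#")
    curve <- fitStandardCurve(dil$log10_dilution, dil$ct)
    top <- cfg$qpcr$top_standard_copies
    if (is.null(top)) top <- 1e6
    dil$copies <- copyNumber(dil$ct, curve, top)
    f <- file.path(cfg$out_dir, "standard_curve.tsv")
    con <- file(f, "w")
    writeLines(c(.provenance(cfg),
                 sprintf("# slope: %.6f  intercept: %.6f  r2: %.6f  efficiency: %.4f",
                         curve@slope, curve@intercept, curve@rSquared,
                         curve@efficiency)), con)
    utils::write.table(dil, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    .log(cfg, "INFO", "standard curve: slope %.4f, eff %.1f%% -> %s",
         curve@slope, 100 * curve@efficiency, f)
    out$curve <- curve
  }
  invisible(out)
}

#' Run the full pipeline from a configuration file
#'
#' score -> diff -> qpcr, with all outputs written under the configured
#' output directory, each carrying a provenance header (package version,
#' config hash, seed, catalogue checksum). Two runs with equal hashes
#' produce equal outputs; inputs are never mutated.
#'
#' @param configPath Path to the YAML configuration.
#' @return Invisibly, a list with the scored tables and differential
#'   results.
#' @export
runPipeline <- function(configPath) {
  cfg <- readRunConfig(configPath)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  .log(cfg, "INFO", "run start (config %s)", attr(cfg, "config_hash"))
  tables <- runScore(cfg)
  diffs <- runDiff(cfg, tables)
  qp <- runQpcr(cfg)
  .log(cfg, "INFO", "run complete")
  invisible(list(tables = tables, diff = diffs, qpcr = qp))
}
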