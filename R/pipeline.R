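#' @details
#' The pipeline reconstructs a strand-concordant differential-methylation
#' analysis of two-colour tiling arrays: [normalizeArrays()] (LOESS within,
#' scale/quantile between), [fitContrasts()] (group-means linear model with
#' empirical-Bayes moderated t), [callDML()] (sense/antisense concordance
#' rule), [annotateCalls()] (CpG context, gene bodies, CTCF, miRNA),
#' [representationReport()] (two-proportion under-representation test) and
#' the reporting layer ([summarizeCounts()], [percentBreakdown()],
#' [vennOverlap()], [directionDiscordant()]). [simulateMethylArray()]
#' generates a 36-array synthetic dataset with planted truth for calibration.
#' @keywords internal
"_PACKAGE"

#' Run the full analysis on a MethylArraySet
#'
#' Normalise, fit, call, annotate and summarise in one step, optionally
#' writing all artefacts (calls TSV/BEDs, per-contrast stats, count tables,
#' representation JSON, summary JSON) under `outdir`.
#'
#' @param arrays a [MethylArraySet-class].
#' @param features a [GenomeFeatures-class].
#' @param config a [callConfig()].
#' @param span,degree,between normalisation settings (see
#'   [normalizeArrays()]).
#' @param minPresentFrac detection fraction for [filterPairedLoci()].
#' @param outdir optional output directory.
#' @return List with `normalized`, `fits`, `pairs`, `calls`, `annotated`,
#'   `counts` (per-contrast up/down/total), `percent`
#'   ([percentBreakdown()]), `featureCounts`, `featureSummary`, `ctcf`
#'   (the under-representation report, `NULL` when no calls), `venn`
#'   (SOV-vs-IVP locus overlap), `discordant`.
#' @examples
#' sim <- simulateMethylArray(simConfig(nLoci = 200, seed = 9))
#' res <- runPipeline(sim$arrays, sim$features)
#' res$counts
#' @export
runPipeline <- function(arrays, features, config = callConfig(),
                        span = 0.3, degree = 1L,
                        between = c("scale", "quantile"),
                        minPresentFrac = 1, outdir = NULL) {
  between <- match.arg(between)
  norm <- normalizeArrays(arrays, span = span, degree = degree,
                          between = between)
  fits <- fitContrasts(norm)
  pairs <- filterPairedLoci(probePairs(norm), is.finite(mValues(norm)),
                            minPresentFrac = minPresentFrac)
  calls <- callDML(fits, pairs, config)
  annotated <- annotateCalls(calls, features)
  counts <- summarizeCounts(calls)
  featureCounts <- featureCountTable(annotated,
                                     contrasts = defaultContrasts())
  # universe for representation testing: all analyzable fragments
  uniGr <- GRanges(pairs$chrom, IRanges(pairs$start0 + 1L, pairs$end))
  kUniverse <- sum(overlapAny(uniGr, ctcfSites(features)))
  ctcf <- if (nrow(calls) > 0 && sum(annotated$inCtcf) > 0 && kUniverse > 0)
    representationReport(sum(annotated$inCtcf), nrow(calls),
                         kUniverse, nrow(pairs)) else NULL
  res <- list(
    normalized = norm, fits = fits, pairs = pairs, calls = calls,
    annotated = annotated, counts = counts,
    percent = if (nrow(calls)) percentBreakdown(counts) else NULL,
    featureCounts = featureCounts,
    featureSummary = if (nrow(calls)) summarizeFeatureCounts(featureCounts)
                     else NULL,
    ctcf = ctcf,
    venn = if (nrow(calls))
      vennOverlap(calls, list(SOV = grep("^SOV", defaultContrasts(),
                                         value = TRUE),
                              IVP = grep("^IVP", defaultContrasts(),
                                         value = TRUE))) else NULL,
    discordant = directionDiscordant(calls)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeCalls(calls, outdir)
    writeContrastStats(fits, outdir)
    write.table(cbind(annotated), file.path(outdir, "annotated_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(counts, file.path(outdir, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(featureCounts, file.path(outdir, "feature_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$venn))
      write.table(res$venn, file.path(outdir, "venn.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write.table(res$discordant, file.path(outdir, "discordant.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeJsonReport(metadata(norm)$normalization,
                    file.path(outdir, "normalization.json"))
    if (!is.null(ctcf))
      writeJsonReport(ctcf, file.path(outdir, "ctcf_representation.json"))
    summaryReport <- list(
      thresholds = list(p = config@pThreshold, log2FC = config@fcThreshold,
                        adjusted = config@useAdjustedP,
                        minPresentFrac = minPresentFrac),
      grandTotals = as.list(attr(counts, "grandTotals")),
      percent = res$percent, featureSummary = res$featureSummary
    )
    writeJsonReport(summaryReport, file.path(outdir, "summary.json"))
  }
  res
}
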