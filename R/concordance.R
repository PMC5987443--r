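# High-stringency locus calling: a locus is differentially methylated in a
# contrast only when its sense and antisense probes BOTH pass the
# significance and fold-change thresholds with the same sign.

#' Locus-level probe pairs of a MethylArraySet
#'
#' Pairs probes by shared locus id: one sense (`+`) and one antisense (`-`)
#' probe per locus. Loci missing either strand are returned with `NA` for the
#' absent probe and are removed by [filterPairedLoci()].
#'
#' @param x a [MethylArraySet-class], or a probe-annotation data.frame as
#'   returned by [probeInfo()].
#' @return data.frame with `locusId`, `chrom`, `start0`, `end`,
#'   `senseProbe`, `antisenseProbe`.
#' @export
probePairs <- function(x) {
  info <- if (is(x, "MethylArraySet")) probeInfo(x) else x
  sense <- info[info$strand == "+", ]
  anti <- info[info$strand == "-", ]
  loci <- unique(info[, c("locusId", "chrom", "start0", "end")])
  loci <- loci[!duplicated(loci$locusId), ]
  data.frame(
    locusId = loci$locusId, chrom = loci$chrom,
    start0 = loci$start0, end = loci$end,
    senseProbe = sense$probeId[match(loci$locusId, sense$locusId)],
    antisenseProbe = anti$probeId[match(loci$locusId, anti$locusId)],
    stringsAsFactors = FALSE
  )
}

#' Restrict to loci whose probes hybridised on enough arrays
#'
#' A probe counts as detected on an array when its measurement is finite and
#' non-missing. A pair is analyzable when both its probes are detected in at
#' least `minPresentFrac` of arrays (default 1: everywhere).
#'
#' @param pairs data.frame from [probePairs()].
#' @param detection logical probe-by-array matrix (rownames = probe ids),
#'   e.g. `is.finite(mValues(x))`.
#' @param minPresentFrac required detected fraction of arrays, in `[0, 1]`.
#' @return The analyzable subset of `pairs`, with an attribute `nRetained`.
#' @export
filterPairedLoci <- function(pairs, detection, minPresentFrac = 1) {
  stopifnot(minPresentFrac >= 0, minPresentFrac <= 1)
  frac <- rowMeans(detection)
  probeOk <- function(id) {
    i <- match(id, rownames(detection))
    !is.na(i) & frac[ifelse(is.na(i), 1L, i)] >= minPresentFrac
  }
  keep <- !is.na(pairs$senseProbe) & !is.na(pairs$antisenseProbe) &
    probeOk(pairs$senseProbe) & probeOk(pairs$antisenseProbe)
  out <- pairs[keep, , drop = FALSE]
  attr(out, "nRetained") <- nrow(out)
  out
}

# the four threshold predicates plus sign agreement, vectorised;
# all comparisons inclusive (p <= threshold, |logFC| >= threshold)
concordantPass <- function(senseP, senseFC, antiP, antiFC, config) {
  senseP <= config@pThreshold & antiP <= config@pThreshold &
    abs(senseFC) >= config@fcThreshold & abs(antiFC) >= config@fcThreshold &
    sign(senseFC) == sign(antiFC) & senseFC != 0
}

#' Concordance call for a single locus in one contrast
#'
#' @param sense,antisense one-row stat records (need `logFC`, `p`, `pAdj`).
#' @param config a [callConfig()].
#' @return `"up"`, `"down"`, or `NA` (no call).
#' @examples
#' callLocus(data.frame(logFC = 1.8, p = 0.01, pAdj = 0.2),
#'           data.frame(logFC = 1.6, p = 0.04, pAdj = 0.3), callConfig())
#' @export
callLocus <- function(sense, antisense, config = callConfig()) {
  pS <- if (config@useAdjustedP) sense$pAdj else sense$p
  pA <- if (config@useAdjustedP) antisense$pAdj else antisense$p
  if (isTRUE(concordantPass(pS, sense$logFC, pA, antisense$logFC, config)))
    if (sense$logFC > 0) "up" else "down"
  else NA_character_
}

#' Call differentially methylated loci across all contrasts
#'
#' Applies the sense/antisense concordance rule to every analyzable pair in
#' every contrast: both probes must reach `p <= pThreshold` and
#' `|logFC| >= fcThreshold` with agreeing sign. Direction is relative to the
#' AI reference (`up` = gain of methylation).
#'
#' @param fits per-contrast stats from [fitContrasts()].
#' @param pairs analyzable pairs from [filterPairedLoci()].
#' @param config a [callConfig()].
#' @param contrasts contrast ids to call; must all be present in `fits`.
#' @return data.frame of calls: `locusId`, `chrom`, `start0`, `end`,
#'   `contrast`, `treatment`, `region`, `direction`, `senseLogFC`, `senseP`,
#'   `antisenseLogFC`, `antisenseP`.
#' @examples
#' sim <- simulateMethylArray(simConfig(nLoci = 150, seed = 11))
#' norm <- normalizeArrays(sim$arrays)
#' fits <- fitContrasts(norm)
#' pairs <- filterPairedLoci(probePairs(norm), is.finite(mValues(norm)))
#' calls <- callDML(fits, pairs)
#' table(calls$contrast, calls$direction)
#' @export
callDML <- function(fits, pairs, config = callConfig(),
                    contrasts = names(fits)) {
  missing <- setdiff(contrasts, names(fits))
  if (length(missing))
    stop("contrast(s) missing from fits: ", paste(missing, collapse = ", "))
  res <- lapply(contrasts, function(ct) {
    st <- fits[[ct]]
    si <- match(pairs$senseProbe, st$probeId)
    ai <- match(pairs$antisenseProbe, st$probeId)
    ok <- !is.na(si) & !is.na(ai)
    si <- si[ok]; ai <- ai[ok]
    pr <- pairs[ok, , drop = FALSE]
    pS <- if (config@useAdjustedP) st$pAdj[si] else st$p[si]
    pA <- if (config@useAdjustedP) st$pAdj[ai] else st$p[ai]
    hit <- concordantPass(pS, st$logFC[si], pA, st$logFC[ai], config)
    hit[is.na(hit)] <- FALSE
    parts <- strsplit(ct, "_", fixed = TRUE)[[1L]]
    nHit <- sum(hit)
    data.frame(
      locusId = pr$locusId[hit], chrom = pr$chrom[hit],
      start0 = pr$start0[hit], end = pr$end[hit],
      contrast = rep(ct, nHit), treatment = rep(parts[1L], nHit),
      region = rep(parts[2L], nHit),
      direction = ifelse(st$logFC[si][hit] > 0, "up", "down"),
      senseLogFC = st$logFC[si][hit], senseP = pS[hit],
      antisenseLogFC = st$logFC[ai][hit], antisenseP = pA[hit],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write calls as TSV plus one BED of called loci per contrast
#'
#' @param calls data.frame from [callDML()].
#' @param dir output directory.
#' @return Written file names, invisibly.
#' @export
writeCalls <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(calls, file.path(dir, "calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- "calls.tsv"
  for (ct in unique(calls$contrast)) {
    sub <- calls[calls$contrast == ct, ]
    gr <- GRanges(sub$chrom, IRanges(sub$start0 + 1L, sub$end))
    mcols(gr)$name <- sub$locusId
    bed <- sprintf("calls_%s.bed", ct)
    writeBed(gr, file.path(dir, bed))
    files <- c(files, bed)
  }
  invisible(files)
}
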