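# Genomic-context annotation of calls and feature representation testing.

#' Annotate calls with genomic context
#'
#' Labels each call with its CpG context ([classifyCpgContext()]) and with
#' gene-body, CTCF-site and miRNA overlap ([overlapAny()]). Annotation is a
#' pure function of the call coordinates and the feature set: the same call
#' always receives the same labels.
#'
#' @param calls data.frame from [callDML()] (needs `chrom`, `start0`, `end`).
#' @param features a [GenomeFeatures-class].
#' @param shoreBp,shelfBp CpG-context flank widths (see
#'   [classifyCpgContext()]).
#' @return `calls` with added columns `cpgContext`, `inGeneBody`, `inCtcf`,
#'   `inMirna`.
#' @export
annotateCalls <- function(calls, features, shoreBp = 2000L, shelfBp = 2000L) {
  stopifnot(is(features, "GenomeFeatures"))
  gr <- GRanges(calls$chrom, IRanges(calls$start0 + 1L, calls$end))
  calls$cpgContext <- classifyCpgContext(gr, islands(features),
                                         shoreBp = shoreBp, shelfBp = shelfBp)
  calls$inGeneBody <- overlapAny(gr, geneBodies(features))
  calls$inCtcf <- overlapAny(gr, ctcfSites(features))
  calls$inMirna <- overlapAny(gr, mirnaLoci(features))
  calls
}

#' Per-contrast feature count table
#'
#' Tallies, for each treatment-by-region contrast, the total calls, calls in
#' CpG islands, calls in gene bodies, and the up/down split of the gene-body
#' calls.
#'
#' @param annotated data.frame from [annotateCalls()].
#' @param contrasts contrast ids fixing the column order (default: those
#'   present).
#' @return data.frame with one row per contrast: `contrast`, `region`,
#'   `treatment`, `total`, `cpgIsland`, `geneBody`, `geneBodyUp`,
#'   `geneBodyDown`.
#' @export
featureCountTable <- function(annotated,
                              contrasts = unique(annotated$contrast)) {
  rows <- lapply(contrasts, function(ct) {
    sub <- annotated[annotated$contrast == ct, , drop = FALSE]
    parts <- strsplit(ct, "_", fixed = TRUE)[[1L]]
    gb <- sub$inGeneBody
    data.frame(
      contrast = ct, treatment = parts[1L], region = parts[2L],
      total = nrow(sub),
      cpgIsland = sum(sub$cpgContext == "island"),
      geneBody = sum(gb),
      geneBodyUp = sum(gb & sub$direction == "up"),
      geneBodyDown = sum(gb & sub$direction == "down"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a feature count table into summary percentages
#'
#' @param counts data.frame shaped like [featureCountTable()] output.
#' @return List with `grandTotal`, `islandTotal`, `islandPct` (islands as %
#'   of all calls), `geneBodyTotal`, `geneBodyPct`, and
#'   `geneBodyRegionSharePct` (each region's share of the gene-body calls),
#'   percentages half-up rounded to one decimal.
#' @export
summarizeFeatureCounts <- function(counts) {
  grand <- sum(counts$total)
  if (grand == 0) stop("no calls to summarise")
  gb <- sum(counts$geneBody)
  byRegion <- tapply(counts$geneBody, counts$region, sum)
  list(
    grandTotal = grand,
    islandTotal = sum(counts$cpgIsland),
    islandPct = roundHalfUp(100 * sum(counts$cpgIsland) / grand),
    geneBodyTotal = gb,
    geneBodyPct = roundHalfUp(100 * gb / grand),
    geneBodyRegionSharePct =
      if (gb > 0) vapply(byRegion, function(k) roundHalfUp(100 * k / gb),
                         numeric(1)) else byRegion * NA_real_
  )
}

#' Pooled two-proportion z-test
#'
#' Tests `k1/n1` against `k2/n2` with the pooled-proportion z statistic,
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p = (k1+k2)/(n1+n2)`, by
#' default without continuity correction; `z^2` equals the 2x2 chi-square
#' statistic. This is the "proportional test" used for feature
#' under-representation (e.g. called loci in CTCF sites versus all analyzable
#' fragments).
#'
#' @param k1,n1 successes and trials in the first sample (the subset of
#'   interest, e.g. called loci).
#' @param k2,n2 successes and trials in the second sample (the universe).
#' @param alternative `"two_sided"` (default), `"less"` (first proportion
#'   smaller: depletion), or `"greater"`.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return List with `z`, `p`, `p1`, `p2`, `alternative`.
#' @examples
#' twoProportionTest(7, 3140, 746, 48530, alternative = "less")
#' @export
twoProportionTest <- function(k1, n1, k2, n2,
                              alternative = c("two_sided", "less", "greater"),
                              correct = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  diff <- p1 - p2
  if (correct)
    diff <- sign(diff) * max(0, abs(diff) - 0.5 * (1 / n1 + 1 / n2))
  z <- if (se > 0) diff / se else 0
  p <- switch(alternative,
              two_sided = 2 * pnorm(-abs(z)),
              less = pnorm(z),
              greater = pnorm(-z))
  list(z = z, p = min(p, 1), p1 = p1, p2 = p2, alternative = alternative)
}

#' Fold of over-/under-representation between two proportions
#'
#' Expresses both proportions as percentages, optionally rounds them to one
#' decimal first (the convention under which published fold figures are
#' quoted), and reports the ratio of the larger to the smaller together with
#' which sample is depleted.
#'
#' @param k1,n1,k2,n2 as in [twoProportionTest()].
#' @param rounding `"none"` or `"one_decimal_percent"`.
#' @return List with `fold`, `direction` (`"under"` if the subset `k1/n1` is
#'   depleted relative to the universe, else `"over"`), `pct1`, `pct2`.
#' @examples
#' representationFold(7, 3140, 746, 48530, "one_decimal_percent")$fold  # 7.5
#' @export
representationFold <- function(k1, n1, k2, n2,
                               rounding = c("none", "one_decimal_percent")) {
  rounding <- match.arg(rounding)
  pct1 <- 100 * k1 / n1
  pct2 <- 100 * k2 / n2
  if (rounding == "one_decimal_percent") {
    pct1 <- roundHalfUp(pct1)
    pct2 <- roundHalfUp(pct2)
  }
  if (pct1 == 0 || pct2 == 0)
    stop("a proportion rounds to zero; fold undefined")
  list(fold = max(pct1, pct2) / min(pct1, pct2),
       direction = if (pct1 < pct2) "under" else "over",
       pct1 = pct1, pct2 = pct2)
}

#' CTCF-style representation report
#'
#' Bundles [twoProportionTest()] (one-sided for depletion of the subset) with
#' [representationFold()] under both rounding modes.
#'
#' @param k1,n1 feature-overlapping and total counts in the called set.
#' @param k2,n2 feature-overlapping and total counts in the analyzable
#'   universe.
#' @return List with `counts`, `foldRounded`, `foldUnrounded`, `direction`,
#'   `z`, `p`, `alternative`.
#' @export
representationReport <- function(k1, n1, k2, n2) {
  tst <- twoProportionTest(k1, n1, k2, n2, alternative = "less")
  fr <- representationFold(k1, n1, k2, n2, "one_decimal_percent")
  fu <- representationFold(k1, n1, k2, n2, "none")
  list(counts = list(k1 = k1, n1 = n1, k2 = k2, n2 = n2),
       foldRounded = fr$fold, foldUnrounded = fu$fold,
       direction = fr$direction,
       z = tst$z, p = tst$p, alternative = tst$alternative)
}
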