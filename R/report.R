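# Treatment/region/direction accounting, set overlaps, and the packaged
# reference count tables.

# half-up rounding at one decimal; R's round() is round-half-even, which
# would mis-reproduce printed one-decimal percentages on .x5 boundaries
roundHalfUp <- function(x, digits = 1L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Per-contrast up/down/total call counts
#'
#' @param calls data.frame from [callDML()] (needs `contrast`, `direction`),
#'   or an already-counted table with `region`, `treatment`, `up`, `down`.
#' @param contrasts contrast ids fixing the row order; contrasts without
#'   calls appear with zero counts.
#' @return data.frame with `region`, `treatment`, `up`, `down`, `total`, one
#'   row per contrast, plus an attribute `grandTotals` (named up/down/total).
#' @export
summarizeCounts <- function(calls, contrasts = defaultContrasts()) {
  rows <- lapply(contrasts, function(ct) {
    parts <- strsplit(ct, "_", fixed = TRUE)[[1L]]
    sub <- calls[calls$contrast == ct, , drop = FALSE]
    up <- sum(sub$direction == "up")
    down <- sum(sub$direction == "down")
    data.frame(region = parts[2L], treatment = parts[1L],
               up = up, down = down, total = up + down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grandTotals") <- c(up = sum(out$up), down = sum(out$down),
                                total = sum(out$total))
  out
}

#' Percentage breakdown of a count table
#'
#' Computes the summary shares of a per-contrast up/down/total count table:
#' treatment, region and direction shares of the grand total, and
#' within-treatment region/direction breakdowns over each treatment's own
#' total. All percentages are half-up rounded to one decimal; each share
#' family sums to 100 up to rounding.
#'
#' @param counts data.frame with `region`, `treatment`, `up`, `down`,
#'   `total` (as from [summarizeCounts()] or [dmlReferenceCounts()]).
#' @return List of named numeric vectors: `treatmentPct`, `regionPct`,
#'   `directionPct`, `withinTreatmentUpPct`, `withinTreatmentRegionPct` (a
#'   treatment-by-region matrix), plus `grandTotal`.
#' @examples
#' percentBreakdown(dmlReferenceCounts())$treatmentPct
#' @export
percentBreakdown <- function(counts) {
  grand <- sum(counts$total)
  if (grand == 0) stop("zero grand total; percentages undefined")
  pct <- function(k, n) roundHalfUp(100 * k / n)
  trt <- tapply(counts$total, counts$treatment, sum)
  reg <- tapply(counts$total, counts$region, sum)
  upByTrt <- tapply(counts$up, counts$treatment, sum)
  withinRegion <- t(vapply(names(trt), function(tr) {
    sub <- counts[counts$treatment == tr, ]
    v <- tapply(sub$total, sub$region, sum)
    vapply(v, function(k) pct(k, trt[[tr]]), numeric(1))
  }, setNames(numeric(length(unique(counts$region))),
              sort(unique(counts$region)))))
  list(
    grandTotal = grand,
    treatmentPct = vapply(trt, function(k) pct(k, grand), numeric(1)),
    regionPct = vapply(reg, function(k) pct(k, grand), numeric(1)),
    directionPct = c(up = pct(sum(counts$up), grand),
                     down = pct(sum(counts$down), grand)),
    withinTreatmentUpPct = mapply(function(k, n) pct(k, n), upByTrt, trt),
    withinTreatmentRegionPct = withinRegion
  )
}

#' Overlap (Venn) counts of call sets
#'
#' Groups calls into named locus-ID sets (each set the union of the loci
#' called in its contrasts, deduplicated by locus id when `dedupe = TRUE`, as
#' when duplicate probes found in multiple groups are removed before drawing
#' a Venn diagram) and counts every intersection region of those sets.
#'
#' @param calls data.frame from [callDML()].
#' @param grouping named list of character vectors of contrast ids, e.g.
#'   `list(SOV = c("SOV_TE", "SOV_TP"), IVP = c("IVP_TE", "IVP_TP"))`.
#' @param dedupe count each locus once per set (default `TRUE`).
#' @param contrasts the contrast ids considered part of the analysis;
#'   grouping entries outside this set raise an error. Defaults to the six
#'   standard contrasts plus any present in `calls` (a contrast with zero
#'   calls is still a known contrast).
#' @return data.frame with one row per non-empty membership pattern: one
#'   logical column per set, plus `count`; region counts sum to the size of
#'   the union.
#' @export
vennOverlap <- function(calls, grouping, dedupe = TRUE,
                        contrasts = union(defaultContrasts(),
                                          unique(calls$contrast))) {
  stopifnot(length(grouping) >= 1L, !is.null(names(grouping)))
  unknown <- setdiff(unlist(grouping), contrasts)
  if (length(unknown))
    stop("unknown contrast(s) in grouping: ", paste(unknown, collapse = ", "))
  sets <- lapply(grouping, function(cts) {
    ids <- calls$locusId[calls$contrast %in% cts]
    if (dedupe) unique(ids) else ids
  })
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(grouping)))
  names(patterns) <- names(grouping)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  patterns$count <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == as.logical(p))))
  })
  rownames(patterns) <- NULL
  patterns
}

#' Loci with opposite call directions across contrasts
#'
#' Returns the loci called in two or more contrasts with both directions
#' present (e.g. more methylated in TE but less methylated in TP), each with
#' its per-contrast directions.
#'
#' @param calls data.frame from [callDML()].
#' @return data.frame with `locusId`, `nContrasts`, `contrasts`
#'   (comma-separated `contrast:direction` labels).
#' @export
directionDiscordant <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(locusId = character(), nContrasts = integer(),
                      contrasts = character(), stringsAsFactors = FALSE))
  byLocus <- split(calls, calls$locusId)
  keep <- vapply(byLocus, function(d) {
    nrow(d) >= 2L && length(unique(d$direction)) == 2L
  }, logical(1))
  rows <- lapply(byLocus[keep], function(d) {
    data.frame(locusId = d$locusId[1L], nContrasts = nrow(d),
               contrasts = paste(sprintf("%s:%s", d$contrast, d$direction),
                                 collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(locusId = character(), nContrasts = integer(),
                      contrasts = character(), stringsAsFactors = FALSE)
  out
}

#' Packaged reference count table of differentially methylated loci
#'
#' The published per-contrast up/down/total counts from the 36-array bovine
#' conceptus experiment this package's pipeline reconstructs (3,140 loci
#' total: 2,127 up, 1,013 down across SOV and IVP versus AI within ED, TE and
#' TP). Distributed as a plain-text fixture for the reporting layer.
#'
#' @return data.frame with `region`, `treatment`, `up`, `down`, `total`.
#' @examples
#' sum(dmlReferenceCounts()$total)  # 3140
#' @export
dmlReferenceCounts <- function() {
  read.table(system.file("extdata", "conceptus_dml_counts.tsv",
                         package = "methconcord"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Packaged reference feature count table
#'
#' The published per-contrast counts of called loci overlapping CpG islands
#' and gene bodies (with the up/down split of the gene-body calls) from the
#' same experiment as [dmlReferenceCounts()].
#'
#' @return data.frame shaped like [featureCountTable()] output.
#' @examples
#' sum(featureReferenceCounts()$geneBody)  # 968
#' @export
featureReferenceCounts <- function() {
  read.table(system.file("extdata", "conceptus_feature_counts.tsv",
                         package = "methconcord"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
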