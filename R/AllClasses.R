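#' @import methods
#' @importFrom GenomicRanges GRanges granges sort strand start end width
#'   findOverlaps countOverlaps seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowRanges colData rowData
#' @importFrom stats approx lowess loess mad median pnorm pt p.adjust predict
#'   quantile rnorm runif sd setNames var
#' @importFrom utils read.table write.table head
NULL

#' Genomic feature tracks for methylation-array annotation
#'
#' Bundles the four interval tracks the annotation layer queries: CpG islands,
#' gene bodies (all coding and non-coding sequence within the transcribed
#' region), computationally predicted CTCF recognition sites, and miRNA loci.
#' Each track is stored as a sorted \link[GenomicRanges]{GRanges}; sorting is
#' enforced at construction so indexed overlap queries agree with a linear
#' scan.
#'
#' @slot islands CpG-island intervals.
#' @slot geneBodies transcribed-region intervals.
#' @slot ctcfSites predicted CTCF recognition-site intervals.
#' @slot mirnaLoci miRNA locus intervals.
#'
#' @seealso [GenomeFeatures()], [classifyCpgContext()], [annotateCalls()]
#' @export
setClass("GenomeFeatures",
  representation(
    islands = "GRanges",
    geneBodies = "GRanges",
    ctcfSites = "GRanges",
    mirnaLoci = "GRanges"
  )
)

setValidity("GenomeFeatures", function(object) {
  isSorted <- function(gr) {
    length(gr) < 2L || !is.unsorted(order(as.factor(GenomicRanges::seqnames(gr)),
                                          GenomicRanges::start(gr)))
  }
  for (nm in c("islands", "geneBodies", "ctcfSites", "mirnaLoci")) {
    if (!isSorted(slot(object, nm)))
      return(sprintf("track '%s' is not sorted by (chrom, start)", nm))
  }
  TRUE
})

#' Construct a GenomeFeatures object
#'
#' Tracks may be given in any order; they are sorted by (chromosome, start) on
#' construction. Strand is ignored for all feature queries (an array fragment
#' covers both strands), so input strands are erased.
#'
#' @param islands,geneBodies,ctcfSites,mirnaLoci `GRanges` of feature
#'   intervals; empty by default.
#' @return A [GenomeFeatures-class] object.
#' @examples
#' gf <- GenomeFeatures(islands = GenomicRanges::GRanges("chr1:1000-2000"))
#' islands(gf)
#' @export
GenomeFeatures <- function(islands = GRanges(), geneBodies = GRanges(),
                           ctcfSites = GRanges(), mirnaLoci = GRanges()) {
  prep <- function(gr) {
    gr <- granges(gr)  # drop mcols; coordinates are all that matter here
    GenomicRanges::strand(gr) <- "*"
    sort(gr, ignore.strand = TRUE)
  }
  new("GenomeFeatures",
      islands = prep(islands), geneBodies = prep(geneBodies),
      ctcfSites = prep(ctcfSites), mirnaLoci = prep(mirnaLoci))
}

#' @describeIn GenomeFeatures-class CpG-island track accessor
#' @param x a `GenomeFeatures` object.
#' @export
islands <- function(x) x@islands

#' @describeIn GenomeFeatures-class gene-body track accessor
#' @export
geneBodies <- function(x) x@geneBodies

#' @describeIn GenomeFeatures-class CTCF-site track accessor
#' @export
ctcfSites <- function(x) x@ctcfSites

#' @describeIn GenomeFeatures-class miRNA-locus track accessor
#' @export
mirnaLoci <- function(x) x@mirnaLoci

setMethod("show", "GenomeFeatures", function(object) {
  cat("GenomeFeatures\n")
  cat(sprintf("  islands:    %d intervals\n", length(object@islands)))
  cat(sprintf("  geneBodies: %d intervals\n", length(object@geneBodies)))
  cat(sprintf("  ctcfSites:  %d intervals\n", length(object@ctcfSites)))
  cat(sprintf("  mirnaLoci:  %d intervals\n", length(object@mirnaLoci)))
})

#' Two-colour methylation-array intensity container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding per-probe
#' M-values (log2 channel ratio) and A-values (mean log2 intensity) across
#' arrays. `rowRanges` carries the probe coordinates with strand (sense `+`,
#' antisense `-`) and metadata columns `probeId` and `locusId`; each locus
#' (restriction fragment) maps to at most one probe per strand. `colData` holds
#' the sample sheet: `treatment`, `region`, `replicate`.
#'
#' @seealso [MethylArraySet()], [simulateMethylArray()], [normalizeArrays()]
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @export
setClass("MethylArraySet", contains = "RangedSummarizedExperiment")

setValidity("MethylArraySet", function(object) {
  if (!all(c("M", "A") %in% assayNames(object)))
    return("assays must include 'M' and 'A'")
  if (!identical(dim(assay(object, "M")), dim(assay(object, "A"))))
    return("'M' and 'A' must have identical dimensions")
  rd <- rowData(object)
  if (!all(c("probeId", "locusId") %in% colnames(rd)))
    return("rowData must carry 'probeId' and 'locusId'")
  if (anyDuplicated(rd$probeId))
    return("probe ids must be unique")
  key <- paste(rd$locusId, as.character(GenomicRanges::strand(rowRanges(object))))
  if (anyDuplicated(key))
    return("each locus may carry at most one probe per strand")
  cd <- colData(object)
  if (!all(c("treatment", "region", "replicate") %in% colnames(cd)))
    return("colData must carry 'treatment', 'region', 'replicate'")
  TRUE
})

#' Construct a MethylArraySet
#'
#' @param M numeric probe-by-array matrix of M-values (log2 ratio of the two
#'   channels).
#' @param A numeric probe-by-array matrix of A-values (mean log2 intensity),
#'   same shape as `M`.
#' @param probes `GRanges` of probe coordinates, one per row of `M`, with
#'   strand set and metadata columns `probeId` and `locusId`.
#' @param samples `DataFrame` or data.frame with one row per array and columns
#'   `treatment`, `region`, `replicate`.
#' @return A [MethylArraySet-class].
#' @export
MethylArraySet <- function(M, A, probes, samples) {
  samples <- DataFrame(samples)
  if (is.null(rownames(samples)))
    rownames(samples) <- colnames(M)
  se <- SummarizedExperiment(
    assays = list(M = M, A = A),
    rowRanges = probes,
    colData = samples
  )
  new("MethylArraySet", se)
}

#' @describeIn MethylArraySet-class M-value matrix accessor
#' @param x a `MethylArraySet`.
#' @export
mValues <- function(x) assay(x, "M")

#' @describeIn MethylArraySet-class A-value matrix accessor
#' @export
aValues <- function(x) assay(x, "A")

#' @describeIn MethylArraySet-class probe annotation as a data.frame
#'   (probeId, locusId, chrom, start0, end, strand; coordinates 0-based
#'   half-open as in BED)
#' @export
probeInfo <- function(x) {
  rr <- rowRanges(x)
  data.frame(
    probeId = rr$probeId,
    locusId = rr$locusId,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start0 = GenomicRanges::start(rr) - 1L,
    end = GenomicRanges::end(rr),
    strand = as.character(GenomicRanges::strand(rr)),
    stringsAsFactors = FALSE
  )
}

#' @describeIn MethylArraySet-class sample sheet accessor
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

setMethod("show", "MethylArraySet", function(object) {
  callNextMethod()
  cd <- colData(object)
  cat(sprintf("design: %d arrays = %s treatments x %s regions\n",
              ncol(object),
              length(unique(cd$treatment)), length(unique(cd$region))))
})

#' Simulation configuration for the synthetic two-colour array generator
#'
#' Captures the design the generator emulates: three treatments (`AI`, `SOV`,
#' `IVP`) by three conceptus regions (`ED`, `TE`, `TP`) with a fixed number of
#' replicate conceptuses each (36 arrays at the default 4 replicates), paired
#' sense/antisense probes over non-overlapping restriction fragments, an
#' intensity-dependent dye-bias trend, per-array offsets, and planted
#' methylation differences with recorded truth.
#'
#' @slot nLoci number of probe-paired loci.
#' @slot chromLength simulated chromosome length (bp).
#' @slot nIslands,nGenes,nCtcf,nMirna feature-track sizes.
#' @slot replicates biological replicates per treatment-by-region group.
#' @slot effectSize planted absolute log2 methylation difference.
#' @slot fracDml fraction of loci truly differential per contrast.
#' @slot fracDiscordant fraction of loci whose sense and antisense probes
#'   receive opposite-sign effects.
#' @slot noiseSd per-probe, per-array Gaussian noise (log2 units).
#' @slot arrayEffectSd SD of the per-array additive offset (log2 units).
#' @slot dyeBiasCoeffs polynomial coefficients (intercept, linear, quadratic,
#'   ...) of the M-on-centred-A dye-bias trend.
#' @slot baselineSd SD of per-locus baseline M (log2 units).
#' @slot fracMissing fraction of probe-array measurements set to NA, emulating
#'   failed hybridisations.
#' @slot seed RNG seed; identical configurations reproduce byte-identical
#'   output.
#' @seealso [simConfig()], [simulateMethylArray()]
#' @export
setClass("SimConfig",
  representation(
    nLoci = "integer", chromLength = "integer",
    nIslands = "integer", nGenes = "integer", nCtcf = "integer",
    nMirna = "integer", replicates = "integer",
    effectSize = "numeric", fracDml = "numeric", fracDiscordant = "numeric",
    noiseSd = "numeric", arrayEffectSd = "numeric", dyeBiasCoeffs = "numeric",
    baselineSd = "numeric", fracMissing = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nLoci < 0L) return("nLoci must be >= 0")
  if (object@chromLength <= 0L) return("chromLength must be positive")
  if (any(c(object@nIslands, object@nGenes, object@nCtcf, object@nMirna) < 0L))
    return("feature counts must be >= 0")
  if (object@replicates < 2L) return("replicates must be >= 2")
  if (object@noiseSd <= 0) return("noiseSd must be > 0")
  if (object@fracDml < 0 || object@fracDiscordant < 0 ||
      object@fracDml + object@fracDiscordant > 1)
    return("need 0 <= fracDml + fracDiscordant <= 1")
  if (object@fracMissing < 0 || object@fracMissing >= 1)
    return("fracMissing must be in [0, 1)")
  TRUE
})

#' Create a simulation configuration
#'
#' Defaults match the study conditions the generator emulates: a 36-array
#' design (3 treatments x 3 regions x 4 replicates), planted effects of 2.0
#' log2 units at 5% of loci per contrast, probe noise SD 0.4 log2 units, a
#' mild quadratic dye-bias trend, and per-array offsets of SD 0.2.
#'
#' @param nLoci number of probe-paired loci (default 10000).
#' @param chromLength simulated chromosome length in bp (default 1e7).
#' @param nIslands,nGenes,nCtcf,nMirna feature-track sizes.
#' @param replicates replicates per treatment-by-region group (default 4).
#' @param effectSize planted |log2 FC| (default 2.0).
#' @param fracDml fraction of loci differential per contrast (default 0.05).
#' @param fracDiscordant fraction of loci with opposite-sign probe effects
#'   (default 0.01); these exercise the concordance filter's rejection path.
#' @param noiseSd probe noise SD, log2 units (default 0.4).
#' @param arrayEffectSd per-array offset SD (default 0.2).
#' @param dyeBiasCoeffs polynomial coefficients in centred A (default
#'   `c(0, 0.2, 0.05)`: mild linear + quadratic trend).
#' @param baselineSd per-locus baseline SD (default 0.5).
#' @param fracMissing fraction of measurements set NA (default 0).
#' @param seed integer RNG seed (default 1).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nLoci = 200, seed = 7)
#' @export
simConfig <- function(nLoci = 10000L, chromLength = 10000000L,
                      nIslands = 300L, nGenes = 200L, nCtcf = 200L,
                      nMirna = 20L, replicates = 4L,
                      effectSize = 2.0, fracDml = 0.05, fracDiscordant = 0.01,
                      noiseSd = 0.4, arrayEffectSd = 0.2,
                      dyeBiasCoeffs = c(0, 0.2, 0.05),
                      baselineSd = 0.5, fracMissing = 0, seed = 1L) {
  new("SimConfig",
      nLoci = as.integer(nLoci), chromLength = as.integer(chromLength),
      nIslands = as.integer(nIslands), nGenes = as.integer(nGenes),
      nCtcf = as.integer(nCtcf), nMirna = as.integer(nMirna),
      replicates = as.integer(replicates),
      effectSize = effectSize, fracDml = fracDml,
      fracDiscordant = fracDiscordant, noiseSd = noiseSd,
      arrayEffectSd = arrayEffectSd, dyeBiasCoeffs = dyeBiasCoeffs,
      baselineSd = baselineSd, fracMissing = fracMissing,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      object@nLoci, "loci,",
      3L * 3L * object@replicates, "arrays (3 trt x 3 region x",
      object@replicates, "reps),",
      "effect", object@effectSize, "log2, noise SD", object@noiseSd,
      ", seed", object@seed, "\n")
})

#' Locus-calling thresholds
#'
#' @param pThreshold significance threshold, inclusive (default 0.05).
#' @param fcThreshold absolute log2 fold-change threshold, inclusive
#'   (default 1.5).
#' @param useAdjustedP if `TRUE`, compare `pThreshold` against BH-adjusted
#'   p-values instead of raw ones (default `FALSE`).
#' @return A `CallConfig` object.
#' @examples
#' callConfig(pThreshold = 0.01)
#' @export
callConfig <- function(pThreshold = 0.05, fcThreshold = 1.5,
                       useAdjustedP = FALSE) {
  new("CallConfig", pThreshold = pThreshold, fcThreshold = fcThreshold,
      useAdjustedP = useAdjustedP)
}

#' @rdname callConfig
#' @export
setClass("CallConfig",
  representation(pThreshold = "numeric", fcThreshold = "numeric",
                 useAdjustedP = "logical")
)

setValidity("CallConfig", function(object) {
  if (object@pThreshold <= 0 || object@pThreshold >= 1)
    return("pThreshold must lie in (0, 1)")
  if (object@fcThreshold <= 0) return("fcThreshold must be > 0")
  TRUE
})

setMethod("show", "CallConfig", function(object) {
  cat(sprintf("CallConfig: p <= %g (%s), |log2 FC| >= %g\n",
              object@pThreshold,
              if (object@useAdjustedP) "BH-adjusted" else "raw",
              object@fcThreshold))
})
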