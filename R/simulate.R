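# Synthetic two-colour methylation-array generator.
#
# Emulates the 36-array design (3 treatments x 3 regions x 4 replicate
# conceptuses), the array's paired sense/antisense probes over non-overlapping
# restriction fragments, intensity-dependent dye bias, per-array offsets, and
# planted group-specific methylation differences with recorded ground truth.

TREATMENTS <- c("AI", "SOV", "IVP")
REGIONS <- c("ED", "TE", "TP")

# run expr under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# place n non-overlapping intervals of width in [minW, maxW] by jittering one
# interval inside each of n equal bins; errors when the bins cannot hold them
placeIntervals <- function(n, chromLength, minW, maxW, chrom = "chrSim") {
  if (n == 0L)
    return(GRanges())
  bin <- chromLength %/% n
  if (bin < maxW + 1L)
    stop(sprintf(
      "cannot place %d intervals of width <= %d on %d bp: chromosome capacity exceeded",
      n, maxW, chromLength))
  w <- sample(minW:maxW, n, replace = TRUE)
  off <- floor(runif(n) * (bin - w))  # 0-based offset within bin
  st <- (seq_len(n) - 1L) * bin + off + 1L
  GRanges(chrom, IRanges(as.integer(st), width = w))
}

#' Simulate a genome with feature tracks and probe-paired loci
#'
#' Places non-overlapping restriction-fragment loci on one simulated
#' chromosome, gives each locus a sense and an antisense probe over the same
#' fragment, and draws CpG-island, gene-body, CTCF-site and miRNA tracks.
#' Fully reproducible from `config`'s seed.
#'
#' @param config a [simConfig()] object.
#' @return A list with elements `loci` (`GRanges`, one per fragment, metadata
#'   `locusId`), `probes` (`GRanges`, two per locus, metadata `probeId`,
#'   `locusId`), and `features` (a [GenomeFeatures-class]).
#' @examples
#' sf <- simulateFeatures(simConfig(nLoci = 50, seed = 3))
#' length(sf$probes)  # 2 probes per locus
#' @export
simulateFeatures <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    loci <- placeIntervals(config@nLoci, config@chromLength, 80L, 200L)
    if (length(loci))
      mcols(loci)$locusId <- sprintf("L%06d", seq_along(loci))
    features <- GenomeFeatures(
      islands = placeIntervals(config@nIslands, config@chromLength, 400L, 2000L),
      geneBodies = placeIntervals(config@nGenes, config@chromLength, 4000L, 20000L),
      ctcfSites = placeIntervals(config@nCtcf, config@chromLength, 15L, 20L),
      mirnaLoci = placeIntervals(config@nMirna, config@chromLength, 60L, 100L)
    )
    probes <- GRanges()
    if (length(loci)) {
      sense <- granges(loci)
      GenomicRanges::strand(sense) <- "+"
      anti <- granges(loci)
      GenomicRanges::strand(anti) <- "-"
      probes <- c(sense, anti)
      mcols(probes)$probeId <- c(sprintf("%s_s", loci$locusId),
                                 sprintf("%s_as", loci$locusId))
      mcols(probes)$locusId <- rep(loci$locusId, 2L)
      probes <- probes[order(mcols(probes)$locusId,
                             as.character(GenomicRanges::strand(probes)))]
    }
    list(loci = loci, probes = probes, features = features)
  })
}

#' Contrast identifiers of the default six comparisons
#'
#' Each non-reference treatment (`SOV`, `IVP`) is compared against `AI` within
#' each region (`ED`, `TE`, `TP`), giving ids `"SOV_ED"`, ..., `"IVP_TP"`.
#'
#' @return Character vector of six contrast ids.
#' @export
defaultContrasts <- function() {
  as.vector(outer(TREATMENTS[-1L], REGIONS, paste, sep = "_"))
}

#' Simulate two-colour intensities with planted differential methylation
#'
#' For probe p of locus l on array j the M-value is
#' `mu_l + delta * planted(l, group(j)) + arrayEffect_j + dyeBias(A_pj) + eps`,
#' with `eps ~ N(0, noiseSd^2)`. Planted effects are drawn independently per
#' contrast: a `fracDml` fraction of loci gets `+/- effectSize` on both
#' strands (direction recorded as `up`/`down`), and a `fracDiscordant`
#' fraction gets `+effectSize` on the sense probe and `-effectSize` on the
#' antisense probe (recorded `discordant`; the concordance filter must never
#' call these). The dye bias is a polynomial in per-array-centred A.
#'
#' @param config a [simConfig()] object.
#' @param sim output of [simulateFeatures()] run with the same config.
#' @return A list with `arrays` (a [MethylArraySet-class]) and `truth`
#'   (data.frame `locusId`, `contrast`, `status` covering every locus and all
#'   six contrasts; `status` in `null`, `up`, `down`, `discordant`).
#' @export
simulateIntensities <- function(config, sim) {
  stopifnot(is(config, "SimConfig"))
  probes <- sim$probes
  nProbe <- length(probes)
  nLoci <- length(sim$loci)
  contrasts <- defaultContrasts()

  samples <- expand.grid(replicate = seq_len(config@replicates),
                         region = REGIONS, treatment = TREATMENTS,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$arrayId <- sprintf("%s_%s_r%d", samples$treatment, samples$region,
                             samples$replicate)
  samples$conceptus <- sprintf("%s_c%d", samples$treatment, samples$replicate)
  nArr <- nrow(samples)

  withSeed(config@seed + 1L, {
    # planted truth, drawn independently per contrast
    truth <- expand.grid(locusId = sim$loci$locusId, contrast = contrasts,
                         stringsAsFactors = FALSE)
    truth$status <- "null"
    for (ct in contrasts) {
      nDml <- round(config@fracDml * nLoci)
      nDisc <- round(config@fracDiscordant * nLoci)
      if (nDml + nDisc == 0L) next
      pick <- sample(nLoci, nDml + nDisc)
      st <- c(sample(c("up", "down"), nDml, replace = TRUE),
              rep("discordant", nDisc))
      truth$status[truth$contrast == ct][pick] <- st
    }

    # per-probe signed effect matrix against each contrast's treatment group
    locIdx <- match(probes$locusId, sim$loci$locusId)
    senseRow <- as.character(GenomicRanges::strand(probes)) == "+"
    effect <- matrix(0, nProbe, nArr)
    for (ct in contrasts) {
      parts <- strsplit(ct, "_", fixed = TRUE)[[1L]]
      inGroup <- samples$treatment == parts[1L] & samples$region == parts[2L]
      st <- truth$status[truth$contrast == ct][locIdx]
      sgn <- numeric(nProbe)
      sgn[st == "up"] <- 1
      sgn[st == "down"] <- -1
      sgn[st == "discordant"] <- ifelse(senseRow[st == "discordant"], 1, -1)
      effect[, inGroup] <- effect[, inGroup] + config@effectSize * sgn
    }

    mu <- rnorm(nLoci, 0, config@baselineSd)[locIdx]
    arrayEff <- rnorm(nArr, 0, config@arrayEffectSd)
    A0 <- runif(nProbe, 6, 14)
    A <- A0 + matrix(rnorm(nProbe * nArr, 0, 0.1), nProbe, nArr)
    Ac <- sweep(A, 2L, colMeans(A))
    bias <- matrix(0, nProbe, nArr)
    for (k in seq_along(config@dyeBiasCoeffs))
      bias <- bias + config@dyeBiasCoeffs[k] * Ac^(k - 1L)
    M <- mu + effect +
      matrix(arrayEff, nProbe, nArr, byrow = TRUE) + bias +
      matrix(rnorm(nProbe * nArr, 0, config@noiseSd), nProbe, nArr)
    if (config@fracMissing > 0) {
      drop <- which(matrix(runif(nProbe * nArr), nProbe, nArr) < config@fracMissing)
      M[drop] <- NA_real_
    }
    dimnames(M) <- dimnames(A) <- list(probes$probeId, samples$arrayId)
    mas <- MethylArraySet(M, A, probes,
                          samples[, c("treatment", "region", "replicate",
                                      "conceptus", "arrayId")])
    list(arrays = mas, truth = truth)
  })
}

#' One-call synthetic dataset
#'
#' Runs [simulateFeatures()] and [simulateIntensities()] under one
#' configuration.
#'
#' @param config a [simConfig()] object.
#' @return A list with `loci`, `probes`, `features`, `arrays`, `truth`.
#' @examples
#' sim <- simulateMethylArray(simConfig(nLoci = 100, seed = 2))
#' sim$arrays
#' @export
simulateMethylArray <- function(config = simConfig()) {
  sf <- simulateFeatures(config)
  si <- simulateIntensities(config, sf)
  c(sf, si)
}

#' Write a simulated dataset to disk
#'
#' Emits, under `dir`: a probe annotation TSV (probe id, BED-convention
#' coordinates, strand, locus id), one intensity TSV per array (probe id, M,
#' A), a sample sheet TSV, one BED per feature track, the planted-truth TSV,
#' and a `manifest.json` listing all files. Raw Cy5/Cy3 channel intensities
#' are derived from M and A (`log2 Cy5 = A + M/2`, `log2 Cy3 = A - M/2`) and
#' included in the per-array tables for format realism.
#'
#' @param sim output of [simulateMethylArray()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }
  files <- character()
  files <- c(files, tsv(probeInfo(sim$arrays), "probes.tsv"))
  M <- mValues(sim$arrays); A <- aValues(sim$arrays)
  for (j in colnames(M)) {
    df <- data.frame(probeId = rownames(M), M = M[, j], A = A[, j],
                     logCy5 = A[, j] + M[, j] / 2,
                     logCy3 = A[, j] - M[, j] / 2)
    files <- c(files, tsv(df, sprintf("intensity_%s.tsv", j)))
  }
  files <- c(files, tsv(sampleInfo(sim$arrays), "samples.tsv"))
  for (nm in c("islands", "geneBodies", "ctcfSites", "mirnaLoci")) {
    bed <- sprintf("%s.bed", nm)
    writeBed(slot(sim$features, nm), file.path(dir, bed))
    files <- c(files, bed)
  }
  files <- c(files, tsv(sim$truth, "truth.tsv"))
  manifest <- list(files = sort(files),
                   nLoci = length(sim$loci),
                   nProbes = nrow(M), nArrays = ncol(M))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
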