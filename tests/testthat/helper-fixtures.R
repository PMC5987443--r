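# Shared fixtures and brute-force oracles. Oracles work on plain coordinate
# vectors so they stay independent of the GenomicRanges-backed code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# random 1-based closed intervals as a data.frame
randIntervals <- function(n, chroms = c("chr1", "chr2"), chromLen = 100000L,
                          maxW = 100L) {
  st <- sample(chromLen - maxW, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = st, end = st + sample(maxW, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

asGR <- function(df) GRanges(df$chrom, IRanges(df$start, df$end))

# all-pairs overlap scan (1-based closed coordinates)
bruteOverlapAny <- function(loci, track, minOverlap = 1L) {
  vapply(seq_len(nrow(loci)), function(i) {
    any(track$chrom == loci$chrom[i] &
          pmin(track$end, loci$end[i]) - pmax(track$start, loci$start[i]) + 1L >=
          minOverlap)
  }, logical(1))
}

# distance-based CpG-context oracle (1-based closed coordinates)
bruteContext <- function(loci, islands, shoreBp = 2000L, shelfBp = 2000L) {
  vapply(seq_len(nrow(loci)), function(i) {
    same <- islands[islands$chrom == loci$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) return("open_sea")
    # gap between locus and island (0 when they touch/overlap)
    d <- pmax(0L, pmax(same$start - loci$end[i], loci$start[i] - same$end))
    ov <- same$start <= loci$end[i] & same$end >= loci$start[i]
    if (any(ov)) "island"
    else if (any(d >= 1L & d <= shoreBp)) "shore"
    else if (any(d > shoreBp & d <= shoreBp + shelfBp)) "shelf"
    else "open_sea"
  }, character(1))
}

# per-locus conjunction oracle for the concordance rule
bruteCall <- function(senseP, senseFC, antiP, antiFC,
                      pThr = 0.05, fcThr = 1.5) {
  n <- length(senseP)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (senseP[i] <= pThr && antiP[i] <= pThr &&
        abs(senseFC[i]) >= fcThr && abs(antiFC[i]) >= fcThr &&
        sign(senseFC[i]) == sign(antiFC[i]))
      out[i] <- if (senseFC[i] > 0) "up" else "down"
  }
  out
}

# a small simulated dataset + pipeline result reused across test files
fixtureSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateMethylArray(simConfig(nLoci = 300, seed = 9))
      res <- runPipeline(sim$arrays, sim$features)
      cache <<- list(sim = sim, res = res)
    }
    cache
  }
})

# random per-contrast stats tables + pairs for caller oracle tests
randomStatsFixture <- function(nLoci, contrasts = defaultContrasts()) {
  pairs <- data.frame(
    locusId = sprintf("L%05d", seq_len(nLoci)),
    chrom = "chr1",
    start0 = (seq_len(nLoci) - 1L) * 200L,
    end = (seq_len(nLoci) - 1L) * 200L + 100L,
    stringsAsFactors = FALSE
  )
  pairs$senseProbe <- paste0(pairs$locusId, "_s")
  pairs$antisenseProbe <- paste0(pairs$locusId, "_as")
  fits <- lapply(contrasts, function(ct) {
    mk <- function(ids) {
      p <- runif(nLoci)^2      # skew toward small p so some loci pass
      data.frame(probeId = ids, locusId = pairs$locusId, strand = "+",
                 logFC = rnorm(nLoci, 0, 1.5), p = p, pAdj = bhAdjust(p),
                 stringsAsFactors = FALSE)
    }
    s <- mk(pairs$senseProbe)
    a <- mk(pairs$antisenseProbe)
    a$strand <- "-"
    rbind(s, a)
  })
  names(fits) <- contrasts
  list(pairs = pairs, fits = fits)
}
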