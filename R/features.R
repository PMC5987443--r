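# Interval I/O and feature queries.
#
# Coordinate convention: files are BED (0-based, half-open); in memory
# everything is GRanges (1-based, closed). readBed/writeBed do the shift, so
# the two round-trip coordinates bit-exactly.

#' Read a BED3/BED6 file into a GRanges
#'
#' Accepts `track`, `browser` and `#` comment lines. Strand is taken from
#' column 6 when present, otherwise unstranded (`*`). Input order is
#' preserved. Zero-width or inverted intervals and non-integer coordinates are
#' rejected with an error naming the offending line.
#'
#' @param path path to a BED file, or a connection.
#' @return A `GRanges`, one range per data line, in file order, with a
#'   metadata column `name` when BED column 4 is present.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t100", "chr2\t10\t20\tx\t0\t-"), bed)
#' readBed(bed)
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields", lineNo[bad[1L]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  startc <- vapply(fields, `[[`, "", 2L)
  endc <- vapply(fields, `[[`, "", 3L)
  start0 <- suppressWarnings(as.integer(startc))
  end <- suppressWarnings(as.integer(endc))
  bad <- which(is.na(start0) | is.na(end) |
               startc != as.character(start0) | endc != as.character(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates", lineNo[bad[1L]]))
  bad <- which(start0 < 0L | start0 >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: need 0 <= start < end", lineNo[bad[1L]]))
  if (any(!nzchar(chrom)))
    stop("BED parse error: empty chromosome name")
  strand <- ifelse(nf >= 6L,
                   vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", ""),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1L, end), strand = strand)
  if (any(nf >= 4L))
    mcols(gr)$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else ".", "")
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED6 when any range is stranded or named, BED3 otherwise.
#' Coordinates are converted back to 0-based half-open, so
#' `readBed(writeBed(x))` round-trips exactly.
#'
#' @param gr a `GRanges`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  name <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else
    rep(".", length(gr))
  if (all(strand == "*") && is.null(mcols(gr)$name)) {
    out <- paste(chrom, start0, end, sep = "\t")
  } else {
    strand[strand == "*"] <- "."
    out <- paste(chrom, start0, end, name, 0L, strand, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Classify loci by CpG context
#'
#' Assigns each locus one of `island`, `shore`, `shelf`, `open_sea` relative to
#' a CpG-island track: `island` on any (>= 1 bp) overlap with an island;
#' otherwise `shore` on overlap with the `shoreBp` flanks of any island;
#' otherwise `shelf` on overlap with the next `shelfBp` beyond a shore;
#' otherwise `open_sea`. Precedence island > shore > shelf. Strand is ignored.
#' The defaults (2 kb shores, 2 kb shelves) are the methylation-array
#' convention.
#'
#' @param loci `GRanges` of query loci.
#' @param islandTrack `GRanges` of CpG islands (an empty track classifies
#'   everything `open_sea`).
#' @param shoreBp,shelfBp flank widths in bp, both > 0.
#' @return Factor of length `length(loci)` with levels
#'   `island`, `shore`, `shelf`, `open_sea`.
#' @examples
#' isl <- GenomicRanges::GRanges("chr1:901-1500")
#' loci <- GenomicRanges::GRanges(c("chr1:1001-1100", "chr1:2001-2100",
#'                                  "chr1:5101-5200"))
#' classifyCpgContext(loci, isl)
#' @export
classifyCpgContext <- function(loci, islandTrack, shoreBp = 2000L,
                               shelfBp = 2000L) {
  stopifnot(shoreBp > 0L, shelfBp > 0L)
  lv <- c("island", "shore", "shelf", "open_sea")
  out <- factor(rep("open_sea", length(loci)), levels = lv)
  if (length(islandTrack) == 0L || length(loci) == 0L)
    return(out)
  expand <- function(gr, by) {
    # widen both ends; clip at 1 since GRanges is 1-based
    st <- pmax(1L, GenomicRanges::start(gr) - as.integer(by))
    GRanges(GenomicRanges::seqnames(gr),
            IRanges(st, GenomicRanges::end(gr) + as.integer(by)))
  }
  inIsland <- IRanges::overlapsAny(loci, islandTrack, ignore.strand = TRUE)
  inShore <- IRanges::overlapsAny(loci, expand(islandTrack, shoreBp),
                                  ignore.strand = TRUE)
  inShelf <- IRanges::overlapsAny(loci, expand(islandTrack, shoreBp + shelfBp),
                                  ignore.strand = TRUE)
  out[inShelf] <- "shelf"
  out[inShore] <- "shore"
  out[inIsland] <- "island"
  out
}

#' Test loci for overlap with a feature track
#'
#' `TRUE` for each locus sharing at least `minOverlap` bp with some track
#' interval, strand-blind.
#'
#' @param loci `GRanges` of query loci.
#' @param track `GRanges` feature track.
#' @param minOverlap minimum shared bp (default 1).
#' @return Logical vector along `loci`.
#' @examples
#' overlapAny(GenomicRanges::GRanges("chr1:1-10"),
#'            GenomicRanges::GRanges("chr1:10-20"))
#' @export
overlapAny <- function(loci, track, minOverlap = 1L) {
  if (length(track) == 0L)
    return(rep(FALSE, length(loci)))
  countOverlaps(loci, track, minoverlap = as.integer(minOverlap),
                ignore.strand = TRUE) > 0L
}
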