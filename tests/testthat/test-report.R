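test_that("summarizeCounts matches a group-by loop and handles empties", {
  withr::local_seed(71)
  calls <- data.frame(
    locusId = sprintf("L%03d", 1:200),
    contrast = sample(defaultContrasts(), 200, replace = TRUE),
    direction = sample(c("up", "down"), 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  counts <- summarizeCounts(calls)
  for (i in seq_len(nrow(counts))) {
    ct <- paste(counts$treatment[i], counts$region[i], sep = "_")
    sub <- calls[calls$contrast == ct, ]
    expect_equal(counts$up[i], sum(sub$direction == "up"))
    expect_equal(counts$down[i], sum(sub$direction == "down"))
    expect_equal(counts$total[i], nrow(sub))
  }
  gt <- attr(counts, "grandTotals")
  expect_equal(unname(gt["total"]), 200L)
  empty <- summarizeCounts(calls[0L, ])
  expect_true(all(empty$total == 0L))
})

test_that("percentBreakdown reproduces the published summary percentages", {
  pct <- percentBreakdown(dmlReferenceCounts())
  expect_equal(pct$grandTotal, 3140L)
  expect_equal(unname(pct$treatmentPct["SOV"]), 77.3)
  expect_equal(unname(pct$treatmentPct["IVP"]), 22.7)
  expect_equal(unname(pct$directionPct["up"]), 67.7)
  expect_equal(unname(pct$directionPct["down"]), 32.3)
  expect_equal(unname(pct$regionPct[c("ED", "TE", "TP")]), c(1.2, 55.4, 43.3))
  expect_equal(unname(pct$withinTreatmentUpPct["SOV"]), 70.6)
  expect_equal(unname(pct$withinTreatmentUpPct["IVP"]), 57.9)
  expect_equal(unname(pct$withinTreatmentRegionPct["IVP", "ED"]), 4.9)
  # share families sum to 100 up to one-decimal rounding
  expect_lt(abs(sum(pct$treatmentPct) - 100), 0.1 + 1e-9)
  expect_lt(abs(sum(pct$regionPct) - 100), 0.15 + 1e-9)
  expect_lt(abs(sum(pct$directionPct) - 100), 0.1 + 1e-9)
})

test_that("percentBreakdown handles degenerate tables", {
  one <- data.frame(region = c("TE", "TP"), treatment = c("SOV", "SOV"),
                    up = c(1L, 0L), down = c(0L, 0L), total = c(1L, 0L))
  pct <- percentBreakdown(one)
  expect_equal(unname(pct$treatmentPct["SOV"]), 100)
  expect_equal(unname(pct$regionPct[c("TE", "TP")]), c(100, 0))
  zero <- transform(one, up = 0L, total = 0L)
  expect_error(percentBreakdown(zero), "zero grand total")
})

test_that("vennOverlap counts every intersection region correctly", {
  calls <- data.frame(
    locusId = c("a", "b", "c", "b", "c", "d"),
    contrast = rep(c("SOV_TE", "IVP_TE"), each = 3L),
    direction = "up", stringsAsFactors = FALSE
  )
  v <- vennOverlap(calls, list(SOV = "SOV_TE", IVP = "IVP_TE"))
  expect_equal(v$count[v$SOV & v$IVP], 2L)
  expect_equal(v$count[v$SOV & !v$IVP], 1L)
  expect_equal(v$count[!v$SOV & v$IVP], 1L)
  expect_equal(sum(v$count), 4L)  # size of the union
  # disjoint sets
  d <- data.frame(locusId = c("x", "y", "z", "u", "v"),
                  contrast = c(rep("SOV_TP", 3), rep("IVP_TP", 2)),
                  direction = "up", stringsAsFactors = FALSE)
  vd <- vennOverlap(d, list(A = "SOV_TP", B = "IVP_TP"))
  expect_equal(vd$count[vd$A & vd$B], 0L)
  expect_equal(sort(vd$count[xor(vd$A, vd$B)]), c(2L, 3L))
  expect_error(vennOverlap(calls, list(A = "nope")), "unknown contrast")
})

test_that("4-way vennOverlap equals a power-set membership oracle", {
  withr::local_seed(72)
  cts <- defaultContrasts()[c(3, 4, 5, 6)]  # the TE/TP contrasts
  calls <- data.frame(
    locusId = sample(sprintf("L%03d", 1:100), 260, replace = TRUE),
    contrast = sample(cts, 260, replace = TRUE),
    direction = "up", stringsAsFactors = FALSE
  )
  calls <- calls[!duplicated(calls[, c("locusId", "contrast")]), ]
  grouping <- as.list(setNames(cts, cts))
  v <- vennOverlap(calls, grouping)
  sets <- lapply(cts, function(ct) unique(calls$locusId[calls$contrast == ct]))
  names(sets) <- cts
  universe <- unique(calls$locusId)
  for (i in seq_len(nrow(v))) {
    pat <- as.logical(v[i, cts])
    oracle <- sum(vapply(universe, function(id)
      all(vapply(seq_along(cts),
                 function(k) (id %in% sets[[k]]) == pat[k], logical(1))),
      logical(1)))
    expect_equal(v$count[i], oracle)
  }
  expect_equal(nrow(v), 15L)  # all non-empty membership patterns
  expect_equal(sum(v$count), length(universe))
})

test_that("vennOverlap dedupe collapses multiplicity to locus identity", {
  calls <- data.frame(locusId = c("a", "a", "b"),
                      contrast = c("SOV_TE", "SOV_TP", "SOV_TE"),
                      direction = "up", stringsAsFactors = FALSE)
  both <- list(SOV = c("SOV_TE", "SOV_TP"))
  expect_equal(vennOverlap(calls, both, dedupe = TRUE)$count, 2L)
})

test_that("directionDiscordant returns exactly the mixed-direction loci", {
  calls <- data.frame(
    locusId = c("a", "a", "b", "b", "c", "d", "d", "d"),
    contrast = c("SOV_TE", "SOV_TP", "SOV_TE", "IVP_TE",
                 "SOV_TE", "SOV_TE", "SOV_TP", "IVP_TP"),
    direction = c("up", "down", "up", "up", "down", "up", "up", "down"),
    stringsAsFactors = FALSE
  )
  disc <- directionDiscordant(calls)
  expect_setequal(disc$locusId, c("a", "d"))
  expect_equal(disc$nContrasts[disc$locusId == "d"], 3L)
  expect_equal(nrow(directionDiscordant(calls[0L, ])), 0L)
  # oracle: per-locus scan on a random table
  withr::local_seed(73)
  rnd <- data.frame(
    locusId = sample(sprintf("L%02d", 1:30), 120, replace = TRUE),
    contrast = sample(defaultContrasts(), 120, replace = TRUE),
    direction = sample(c("up", "down"), 120, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rnd <- rnd[!duplicated(rnd[, c("locusId", "contrast")]), ]
  got <- directionDiscordant(rnd)$locusId
  oracle <- names(Filter(function(d) nrow(d) >= 2 &&
                           length(unique(d$direction)) == 2,
                         split(rnd, rnd$locusId)))
  expect_setequal(got, oracle)
  # returned loci are always a subset of multi-contrast loci
  multi <- names(which(table(rnd$locusId) >= 2))
  expect_true(all(got %in% multi))
})
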