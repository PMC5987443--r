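test_that("buildDesign gives one indicator per group with one 1 per row", {
  samp <- expand.grid(treatment = c("AI", "SOV", "IVP"),
                      region = c("ED", "TE", "TP"), rep = 1:4,
                      stringsAsFactors = FALSE)
  des <- buildDesign(samp)
  expect_equal(dim(des$design), c(36L, 9L))
  expect_true(all(rowSums(des$design) == 1L))
  expect_equal(qr(des$design)$rank, 9L)
})

test_that("fitGroupMeans matches a per-group loop oracle", {
  withr::local_seed(41)
  group <- rep(c("g1", "g2", "g3"), times = c(3, 4, 5))
  M <- matrix(rnorm(20 * 12), 20, 12)
  fit <- fitGroupMeans(M, group)
  expect_equal(fit$df, 12L - 3L)
  for (g in unique(group)) {
    oracleMeans <- rowMeans(M[, group == g, drop = FALSE])
    expect_equal(unname(fit$means[, g]), oracleMeans, tolerance = 1e-12)
  }
  oracleS2 <- apply(M, 1L, function(x) {
    rss <- sum(unlist(lapply(unique(group), function(g)
      (x[group == g] - mean(x[group == g]))^2)))
    rss / (length(x) - 3L)
  })
  expect_equal(unname(fit$s2), oracleS2, tolerance = 1e-12)
  # the full design forces df = 36 - 9 = 27
  g36 <- paste(rep(c("AI", "SOV", "IVP"), each = 12),
               rep(rep(c("ED", "TE", "TP"), each = 4), 3), sep = "_")
  expect_equal(fitGroupMeans(matrix(rnorm(5 * 36), 5, 36), g36)$df, 27L)
  # degenerate probe: identical values everywhere
  Mc <- rbind(rep(2, 12), M)
  fitc <- fitGroupMeans(Mc, group)
  expect_equal(fitc$s2[[1L]], 0)
  expect_true(all(fitc$means[1L, ] == 2))
  expect_error(fitGroupMeans(M[, 1:4], c("a", "a", "a", "b")), "b")
})

test_that("EB hyperparameter estimation recovers a known prior", {
  withr::local_seed(42)
  d0 <- 4; s02 <- 1; df <- 27L
  sigma2 <- s02 * d0 / rchisq(10000, d0)
  s2 <- sigma2 * rchisq(10000, df) / df
  est <- estimateEBHyperparams(s2, df)
  expect_lt(abs(est$d0 - d0) / d0, 0.2)
  expect_lt(abs(est$s02 - s02) / s02, 0.1)
  # agrees with the established reference fit
  ref <- limma::fitFDist(s2, df1 = df)
  expect_equal(est$d0, ref$df2, tolerance = 1e-6)
  expect_equal(est$s02, ref$scale, tolerance = 1e-6)
})

test_that("EB estimation declares d0 = Inf for dispersion-free variances", {
  expect_equal(estimateEBHyperparams(rep(1.7, 50), 10L)$d0, Inf)
  # two distinct repeated values give a finite positive d0
  est <- estimateEBHyperparams(rep(c(0.5, 2), 50), 10L)
  expect_true(is.finite(est$d0) && est$d0 > 0)
  expect_error(estimateEBHyperparams(numeric(0), 10L), ">= 10")
})

test_that("moderated t matches limits, a formula oracle, and limma", {
  withr::local_seed(43)
  group <- rep(c("A", "B"), each = 4)
  # heteroskedastic probes so the variance prior has finite df
  sigma <- sqrt(1 * 6 / rchisq(200, 6))
  M <- matrix(rnorm(200 * 8, sd = rep(sigma, 8)), 200, 8,
              dimnames = list(sprintf("p%03d", 1:200), NULL))
  fit <- fitGroupMeans(M, group)
  # d0 = 0: ordinary pooled-variance two-sample t
  ord <- moderatedStatistics(fit, "A", "B", d0 = 0, s02 = 1)
  oracle <- apply(M, 1L, function(x)
    t.test(x[group == "A"], x[group == "B"], var.equal = TRUE)$statistic)
  expect_equal(unname(ord$t), unname(oracle), tolerance = 1e-10)
  # d0 = Inf: every probe tested against s02 with a normal reference
  shr <- moderatedStatistics(fit, "A", "B", d0 = Inf, s02 = 0.8)
  expect_equal(shr$t, ord$logFC / sqrt(0.8 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(shr$p, 2 * pnorm(-abs(shr$t)), tolerance = 1e-12)
  # general case against an independent formula evaluation
  eb <- estimateEBHyperparams(fit$s2, fit$df)
  expect_true(is.finite(eb$d0))
  mod <- moderatedStatistics(fit, "A", "B", eb$d0, eb$s02)
  s2t <- (eb$d0 * eb$s02 + fit$df * fit$s2) / (eb$d0 + fit$df)
  tOracle <- (rowMeans(M[, 1:4]) - rowMeans(M[, 5:8])) / sqrt(s2t * 0.5)
  expect_equal(unname(mod$t), unname(tOracle), tolerance = 1e-10)
  # antisymmetry under contrast swap
  rev <- moderatedStatistics(fit, "B", "A", eb$d0, eb$s02)
  expect_equal(rev$logFC, -mod$logFC)
  expect_equal(rev$t, -mod$t)
  expect_equal(rev$p, mod$p)
  # cross-check the whole route against limma
  design <- cbind(A = as.numeric(group == "A"), B = as.numeric(group == "B"))
  lf <- limma::lmFit(M, design)
  lf <- limma::contrasts.fit(lf, c(1, -1))
  lf <- limma::eBayes(lf)
  expect_equal(unname(mod$t), unname(lf$t[, 1L]), tolerance = 1e-6)
  expect_equal(unname(mod$p), unname(lf$p.value[, 1L]), tolerance = 1e-6)
  # homoskedastic probes: no excess dispersion, complete shrinkage, and the
  # whole route still agrees with limma
  Mh <- matrix(rnorm(200 * 8), 200, 8)
  fith <- fitGroupMeans(Mh, group)
  ebh <- estimateEBHyperparams(fith$s2, fith$df)
  expect_equal(ebh$d0, Inf)
  modh <- moderatedStatistics(fith, "A", "B", ebh$d0, ebh$s02)
  lfh <- limma::eBayes(limma::contrasts.fit(limma::lmFit(Mh, design),
                                            c(1, -1)))
  expect_equal(unname(modh$t), unname(lfh$t[, 1L]), tolerance = 1e-6)
  # p agrees only approximately: with d0 = Inf this package uses the normal
  # reference while limma caps df.total at the pooled residual df (1200)
  expect_equal(unname(modh$p), unname(lfh$p.value[, 1L]), tolerance = 5e-3)
})

test_that("moderated |t| interpolates monotonically in d0", {
  withr::local_seed(44)
  group <- rep(c("A", "B"), each = 3)
  M <- matrix(rnorm(50 * 6), 50, 6)
  fit <- fitGroupMeans(M, group)
  s02 <- mean(fit$s2)
  ts <- sapply(c(0, 1, 4, 16, 64, 1e6), function(d0)
    abs(moderatedStatistics(fit, "A", "B", d0, s02)$t))
  # per probe, |t| moves monotonically from the ordinary t toward the fully
  # shrunk statistic as d0 grows
  mono <- apply(ts, 1L, function(x) all(diff(x) >= -1e-12) || all(diff(x) <= 1e-12))
  expect_true(all(mono))
})

test_that("null data yields calibrated p-values", {
  withr::local_seed(45)
  df <- 27L
  g36 <- paste(rep(c("AI", "SOV", "IVP"), each = 12),
               rep(rep(c("ED", "TE", "TP"), each = 4), 3), sep = "_")
  sigma2 <- 1 * 4 / rchisq(10000, 4)
  M <- matrix(rnorm(10000 * 36, sd = sqrt(sigma2)), 10000, 36)
  fit <- fitGroupMeans(M, g36)
  eb <- estimateEBHyperparams(fit$s2, fit$df)
  mod <- moderatedStatistics(fit, "SOV_TE", "AI_TE", eb$d0, eb$s02)
  frac <- mean(mod$p <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("bhAdjust reproduces hand-computed step-up values", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- c(0.03, 0.002, 0.8, 0.004)
  # hand step-up: sorted (0.002,0.004,0.03,0.8) -> (0.008,0.008,0.04,0.8)
  expect_equal(bhAdjust(p), c(0.04, 0.008, 0.8, 0.008))
})

test_that("fitContrasts ties the pieces together on simulated data", {
  fx <- fixtureSim()
  fits <- fitContrasts(normalizeArrays(fx$sim$arrays))
  expect_named(fits, defaultContrasts())
  expect_true(attr(fits, "d0") > 0)
  expect_equal(attr(fits, "df"), 27L)
  st <- fits[["SOV_TE"]]
  expect_true(all(st$p >= 0 & st$p <= 1))
  expect_true(all(st$pAdj >= st$p - 1e-12))
  expect_error(fitContrasts(normalizeArrays(fx$sim$arrays), "SOVTE"),
               "treatment_region")
})
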