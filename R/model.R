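# Group-means linear model and empirical-Bayes moderated t-statistics.
#
# The design is one indicator column per treatment-by-region group (9 groups
# over 36 arrays at 4 replicates), so the fit reduces to per-group means and a
# pooled residual variance with df = nArrays - nGroups (27 for the full
# design). Per-probe variances are shrunk toward a scaled inverse-chi-square
# prior whose hyperparameters (d0, s0^2) are estimated by the method of
# moments on log variances.

#' Build the group indicator design
#'
#' @param samples data.frame with `treatment` and `region` columns, one row
#'   per array.
#' @return List with `design` (array-by-group 0/1 matrix, full column rank,
#'   one 1 per row) and `group` (character vector of per-array
#'   `treatment_region` labels).
#' @export
buildDesign <- function(samples) {
  group <- paste(samples$treatment, samples$region, sep = "_")
  lev <- unique(group)
  design <- sapply(lev, function(g) as.integer(group == g))
  rownames(design) <- rownames(samples)
  list(design = design, group = group)
}

#' Per-probe group means and residual variance
#'
#' @param M probe-by-array matrix.
#' @param group per-array group labels (length `ncol(M)`); every group must
#'   have at least two arrays.
#' @return List with `means` (probe-by-group matrix), `s2` (per-probe
#'   residual variance), `df` (residual degrees of freedom,
#'   `nArrays - nGroups`), `n` (named per-group array counts).
#' @examples
#' M <- matrix(rnorm(40), 10, 4)
#' fitGroupMeans(M, c("a", "a", "b", "b"))$df  # 2
#' @export
fitGroupMeans <- function(M, group) {
  stopifnot(is.matrix(M), length(group) == ncol(M))
  n <- table(group)
  if (any(n < 2L))
    stop("every group needs >= 2 arrays; offending group(s): ",
         paste(names(n)[n < 2L], collapse = ", "))
  lev <- unique(group)
  ind <- sapply(lev, function(g) as.numeric(group == g))
  counts <- colSums(ind)
  means <- (M %*% ind) %*% diag(1 / counts, length(lev))
  colnames(means) <- lev
  resid <- M - means[, match(group, lev), drop = FALSE]
  df <- ncol(M) - length(lev)
  s2 <- rowSums(resid^2) / df
  list(means = means, s2 = s2, df = df,
       n = setNames(as.integer(counts), lev))
}

# Newton inversion of trigamma on (0, Inf); x > 0
trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Fits a scaled inverse-chi-square prior (d0 degrees of freedom, scale s0^2)
#' to the ensemble of per-probe residual variances by the method of moments on
#' log s^2: with `z = log(s2)` and `e = z - digamma(df/2) + log(df/2)`, d0
#' solves `trigamma(d0/2) = var(e) - trigamma(df/2)` and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the observed
#' dispersion of log variances does not exceed what sampling alone implies,
#' the equation has no positive solution and `d0 = Inf` with `s0^2` the mean
#' shrinkage target `mean(s2)`.
#'
#' @param s2 per-probe residual variances (>= 10 positive values required).
#' @param df residual degrees of freedom of each `s2`.
#' @return List with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   variance).
#' @examples
#' s2 <- 1 * rchisq(1000, 8) / 8  # pure sampling spread -> large d0
#' estimateEBHyperparams(s2, 8)
#' @export
estimateEBHyperparams <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L)
    stop("need >= 10 positive variances to estimate the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as the single
#' point where the multiple-testing method is chosen.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Moderated statistics for one two-group contrast
#'
#' `logFC = mean(groupA) - mean(groupB)`; the posterior variance is
#' `s2Tilde = (d0 * s02 + df * s2) / (d0 + df)` and
#' `t = logFC / sqrt(s2Tilde * (1/nA + 1/nB))`, referred to a t distribution
#' on `d0 + df` degrees of freedom (standard normal when `d0 = Inf`). With
#' `d0 = 0` this is the ordinary pooled-variance two-sample t. A probe with
#' `s2Tilde = 0` but nonzero logFC gets `p = 0` and `degenerate = TRUE`.
#'
#' @param fit output of [fitGroupMeans()].
#' @param groupA,groupB group labels; the contrast is A minus B.
#' @param d0,s02 prior hyperparameters from [estimateEBHyperparams()].
#' @return data.frame with `logFC`, `s2`, `t`, `p`, `pAdj` (BH within the
#'   contrast), and `degenerate`.
#' @export
moderatedStatistics <- function(fit, groupA, groupB, d0, s02) {
  if (!all(c(groupA, groupB) %in% colnames(fit$means)))
    stop(sprintf("contrast groups %s, %s not both present in the fit",
                 groupA, groupB))
  logFC <- fit$means[, groupA] - fit$means[, groupB]
  if (is.infinite(d0)) {
    s2t <- rep(s02, length(logFC))
    dfTotal <- Inf
  } else {
    s2t <- (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
    dfTotal <- d0 + fit$df
  }
  se <- sqrt(s2t * (1 / fit$n[[groupA]] + 1 / fit$n[[groupB]]))
  degenerate <- se == 0 & logFC != 0
  if (any(degenerate, na.rm = TRUE))
    warning(sum(degenerate, na.rm = TRUE),
            " probe(s) with zero posterior variance but nonzero logFC; p set to 0")
  t <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, sign(logFC) * Inf))
  p <- if (is.infinite(dfTotal)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), dfTotal)
  p[degenerate] <- 0
  data.frame(logFC = logFC, s2 = fit$s2, t = t, p = p, pAdj = bhAdjust(p),
             degenerate = degenerate, row.names = rownames(fit$means))
}

#' Fit all treatment-vs-AI contrasts of a MethylArraySet
#'
#' Fits the group-means model on the (normalised) M-values, estimates the
#' variance prior once across all probes, and computes moderated statistics
#' for each requested contrast (`"SOV_ED"` means SOV vs AI within ED, etc.).
#' Probes with any missing M-value are dropped from the fit (the concordance
#' filter accounts for them separately).
#'
#' @param x a [MethylArraySet-class], normally after [normalizeArrays()].
#' @param contrasts character vector of `treatment_region` contrast ids
#'   (default [defaultContrasts()]).
#' @return List with one data.frame per contrast (probe stats plus `probeId`,
#'   `locusId`, `strand`), and attributes `d0`, `s02`, `df`.
#' @examples
#' sim <- simulateMethylArray(simConfig(nLoci = 80, seed = 4))
#' fits <- fitContrasts(normalizeArrays(sim$arrays))
#' head(fits[["SOV_TE"]])
#' @export
fitContrasts <- function(x, contrasts = defaultContrasts()) {
  stopifnot(is(x, "MethylArraySet"))
  M <- mValues(x)
  info <- probeInfo(x)
  complete <- rowSums(!is.finite(M)) == 0L
  M <- M[complete, , drop = FALSE]
  info <- info[complete, , drop = FALSE]
  des <- buildDesign(sampleInfo(x))
  fit <- fitGroupMeans(M, des$group)
  eb <- estimateEBHyperparams(fit$s2, fit$df)
  out <- lapply(contrasts, function(ct) {
    parts <- strsplit(ct, "_", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("contrast id must be 'treatment_region': ", ct)
    stats <- moderatedStatistics(fit, paste(parts[1L], parts[2L], sep = "_"),
                                 paste("AI", parts[2L], sep = "_"),
                                 eb$d0, eb$s02)
    cbind(info[, c("probeId", "locusId", "strand")], stats,
          row.names = NULL)
  })
  names(out) <- contrasts
  attr(out, "d0") <- eb$d0
  attr(out, "s02") <- eb$s02
  attr(out, "df") <- fit$df
  out
}

#' Write per-contrast probe statistics as TSV
#'
#' @param fits output of [fitContrasts()].
#' @param dir output directory.
#' @return Written file names, invisibly.
#' @export
writeContrastStats <- function(fits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(fits), function(ct) {
    f <- file.path(dir, sprintf("stats_%s.tsv", ct))
    write.table(fits[[ct]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    basename(f)
  }, "")
  invisible(files)
}
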