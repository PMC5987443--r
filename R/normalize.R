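# Intra-array LOESS trend removal and inter-array distribution alignment.

#' LOESS intra-array normalisation of one array's M-values
#'
#' Removes the intensity-dependent dye-bias trend by returning
#' `M - f(A)`, where `f` is a local regression of M on A. Degree 1 uses
#' `stats::lowess` (robust, fast on full-array inputs); degree 2 uses
#' `stats::loess`. Adding a constant to `M` leaves the corrected values
#' unchanged.
#'
#' @param M numeric M-values for one array (length >= 10, finite).
#' @param A matching A-values.
#' @param span LOESS span in (0, 1] (default 0.3).
#' @param degree local-polynomial degree, 1 or 2 (default 1).
#' @return Corrected M, same length as the input.
#' @examples
#' A <- runif(200, 6, 14)
#' M <- 0.3 * (A - 10) + rnorm(200, 0, 0.1)
#' summary(loessWithin(M, A))
#' @export
loessWithin <- function(M, A, span = 0.3, degree = 1L) {
  stopifnot(length(M) == length(A), span > 0, span <= 1, degree %in% 1:2)
  ok <- is.finite(M) & is.finite(A)
  if (sum(ok) < 10L)
    stop("loessWithin needs at least 10 finite (M, A) pairs; got ", sum(ok))
  fitted <- rep(NA_real_, length(M))
  if (degree == 1L) {
    o <- order(A[ok])
    lw <- lowess(A[ok][o], M[ok][o], f = span)
    f <- rep(NA_real_, sum(ok))
    f[o] <- lw$y
    fitted[ok] <- f
  } else {
    fit <- loess(m ~ a, data = data.frame(m = M[ok], a = A[ok]),
                 span = span, degree = degree, family = "symmetric",
                 surface = "direct")
    fitted[ok] <- predict(fit, newdata = data.frame(a = A[ok]))
  }
  M - fitted
}

#' Inter-array normalisation of an M-value matrix
#'
#' `method = "scale"` rescales each array's deviations about its median by
#' the ratio of the geometric mean of all arrays' MADs to the array's own
#' MAD, equalising MADs while leaving per-array medians untouched.
#' `method = "quantile"` forces every array onto the common distribution of
#' rank means: after normalisation the sorted values of all arrays agree
#' exactly, ties receiving the mean of their spanned quantiles
#' (interpolated at averaged ranks).
#'
#' @param M numeric probe-by-array matrix with at least two columns.
#' @param method `"scale"` (default) or `"quantile"`.
#' @return Normalised matrix of the same shape and dimnames.
#' @examples
#' M <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' scaleBetween(M, "quantile")
#' @export
scaleBetween <- function(M, method = c("scale", "quantile")) {
  method <- match.arg(method)
  if (!is.matrix(M) || ncol(M) < 2L)
    stop("scaleBetween needs a matrix with >= 2 arrays")
  out <- M
  if (method == "scale") {
    mads <- apply(M, 2L, mad, na.rm = TRUE)
    zero <- which(mads == 0 | !is.finite(mads))
    if (length(zero)) {
      nm <- colnames(M)[zero[1L]]
      stop(sprintf("array %s has zero MAD; scale normalisation undefined",
                   if (is.null(nm)) as.character(zero[1L]) else nm))
    }
    gm <- exp(mean(log(mads)))
    meds <- apply(M, 2L, median, na.rm = TRUE)
    for (j in seq_len(ncol(M)))
      out[, j] <- meds[j] + (M[, j] - meds[j]) * gm / mads[j]
  } else {
    if (anyNA(M))
      stop("quantile normalisation requires complete data")
    n <- nrow(M)
    target <- rowMeans(apply(M, 2L, sort))
    for (j in seq_len(ncol(M))) {
      r <- rank(M[, j], ties.method = "average")
      out[, j] <- if (n == 1L) target else approx(seq_len(n), target, xout = r)$y
    }
  }
  out
}

#' Normalise a MethylArraySet
#'
#' Applies LOESS intra-array correction ([loessWithin()]) to each array's
#' M-values, then inter-array normalisation ([scaleBetween()]). A-values are
#' left untouched and retained for diagnostics. A normalisation report
#' (per-array pre/post MAD, the span and method used) is stored in
#' `metadata(x)$normalization` and can be written with [writeJsonReport()].
#'
#' @param x a [MethylArraySet-class].
#' @param span,degree passed to [loessWithin()].
#' @param between inter-array method, `"scale"` (default) or `"quantile"`.
#' @return The normalised `MethylArraySet`.
#' @examples
#' sim <- simulateMethylArray(simConfig(nLoci = 100, seed = 5))
#' norm <- normalizeArrays(sim$arrays)
#' metadata(norm)$normalization$between
#' @export
normalizeArrays <- function(x, span = 0.3, degree = 1L,
                            between = c("scale", "quantile")) {
  stopifnot(is(x, "MethylArraySet"))
  between <- match.arg(between)
  M <- mValues(x)
  A <- aValues(x)
  preMad <- apply(M, 2L, mad, na.rm = TRUE)
  for (j in seq_len(ncol(M)))
    M[, j] <- loessWithin(M[, j], A[, j], span = span, degree = degree)
  M <- scaleBetween(M, method = between)
  out <- x
  SummarizedExperiment::assay(out, "M") <- M
  metadata(out)$normalization <- list(
    span = span, degree = degree, between = between,
    preMad = as.list(preMad),
    postMad = as.list(apply(M, 2L, mad, na.rm = TRUE))
  )
  out
}

#' Write a list-shaped report as JSON
#'
#' @param report a named list (e.g. `metadata(x)$normalization`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJsonReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
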