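#' Filter CpG units on coverage
#'
#' Drops units observed in fewer than \code{minFraction} of individuals
#' (the study filter keeps units with values in at least 75% of
#' samples), plus any explicitly excluded units (e.g. the unit harbouring
#' a SNP that confounds the methylation call). Idempotent.
#'
#' @param x a \linkS4class{MethylationSet} or an individuals-by-units
#'   matrix.
#' @param minFraction minimum non-missing fraction in \code{(0, 1]}.
#' @param exclude unit ids dropped regardless of coverage.
#' @return The filtered object (same type as \code{x}).
#' @export
filterUnits <- function(x, minFraction = 0.75, exclude = character()) {
  if (minFraction <= 0 || minFraction > 1)
    stop("minFraction must lie in (0, 1]")
  mm <- .meth_matrix(x)
  if (nrow(mm$m) == 0L || ncol(mm$m) == 0L) stop("empty methylation table")
  frac <- colMeans(!is.na(mm$m))
  keep <- frac >= minFraction & !colnames(mm$m) %in% exclude
  if (is(x, "MethylationSet")) x[keep, ] else x[, keep, drop = FALSE]
}

#' Per-unit and per-region methylation summaries
#'
#' Median and interquartile range per CpG unit over non-missing values
#' (linear-interpolation quantiles, type 7), and the unweighted mean of
#' unit IQRs per region.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @return list with \code{units} (data.frame: unit, region, n, median,
#'   iqr) and \code{regions} (data.frame: region, meanIQR).
#' @export
summarizeUnits <- function(x) {
  mm <- .meth_matrix(x)
  m <- mm$m
  units <- data.frame(
    unit = colnames(m), region = unname(mm$region[colnames(m)]),
    n = colSums(!is.na(m)),
    median = apply(m, 2, median, na.rm = TRUE),
    iqr = apply(m, 2, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      diff(quantile(v, c(0.25, 0.75), type = 7, names = FALSE))
    }),
    row.names = NULL, stringsAsFactors = FALSE)
  units$median[units$n == 0L] <- NA_real_
  regions <- do.call(rbind, lapply(split(units, units$region), function(d)
    data.frame(region = d$region[1], meanIQR = mean(d$iqr, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(regions) <- NULL
  list(units = units, regions = regions)
}

#' Pairwise Spearman correlation matrix of CpG units
#'
#' Pairwise-complete Spearman correlations (average ranks for ties)
#' between all CpG units, with the per-cell sample size and the critical
#' correlation at the given significance level. Cells with fewer than
#' \code{minShared} shared observations are \code{NA}.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param minShared minimum shared observations per cell (default 3).
#' @param alpha two-tailed significance level used for the reported
#'   critical correlation.
#' @return list of class \code{"SpearmanMatrix"}: \code{rho} (units x
#'   units), \code{n} (shared observations), \code{threshold} (critical
#'   rho at the median off-diagonal n), \code{alpha}.
#' @export
spearmanMatrix <- function(x, minShared = 3L, alpha = 1e-4) {
  mm <- .meth_matrix(x)
  m <- mm$m
  rho <- suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(m))
  rho[nmat < minShared] <- NA_real_
  diag(rho) <- ifelse(diag(nmat) > 0, 1, NA_real_)
  off <- nmat[upper.tri(nmat)]
  thr <- if (length(off) && median(off) > 3)
    correlationThreshold(median(off), alpha) else NA_real_
  structure(list(rho = rho, n = nmat, threshold = thr, alpha = alpha),
            class = "SpearmanMatrix")
}

#' @export
print.SpearmanMatrix <- function(x, ...) {
  cat("SpearmanMatrix:", nrow(x$rho), "units;",
      sprintf("critical rho %.3f at alpha %g\n", x$threshold, x$alpha))
  invisible(x)
}

#' Critical Spearman correlation at a two-tailed level
#'
#' Inverts the t approximation \code{t = rho * sqrt((n - 2) / (1 -
#' rho^2))}: the smallest correlation significant at two-tailed
#' \code{alpha} with \code{n} observations.
#'
#' @param n sample size (> 3).
#' @param alpha two-tailed level in \code{(0, 1]}.
#' @return critical rho in \code{[0, 1)}.
#' @examples
#' correlationThreshold(512, 1e-4)  # ~0.17
#' correlationThreshold(286, 1e-4)  # ~0.23
#' @export
correlationThreshold <- function(n, alpha = 1e-4) {
  if (n <= 3) stop("n must exceed 3")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}
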