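#' Intra-pair methylation discordance
#'
#' Absolute methylation differences between the two members of each
#' (pseudo-)pair, per CpG unit or aggregated per region. At region level
#' the default aggregate is the mean |difference| over units observed in
#' both members, rescaled by the number of units in the region - a
#' missing-robust equivalent of summing the per-unit differences
#' (\code{mode = "sum"} gives the raw sum over shared units).
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param pairs pair table: data.frame with \code{pair_id},
#'   \code{member1}, \code{member2} and optionally \code{zygosity} (a
#'   \linkS4class{TwinCohort} is accepted). Non-related pseudo-pairs
#'   from \code{\link{makeNonrelatedPairs}} carry group label
#'   \code{"NR"}.
#' @param level \code{"region"} or \code{"unit"}.
#' @param mode region aggregation, \code{"scaled"} (default) or
#'   \code{"sum"}.
#' @return data.frame with \code{pair_id}, \code{group}, \code{unit} or
#'   \code{region}, \code{discordance} (NA when no shared units).
#' @export
pairDiscordance <- function(x, pairs, level = c("region", "unit"),
                            mode = c("scaled", "sum")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (is(pairs, "TwinCohort")) pairs <- pairTable(pairs)
  mm <- .meth_matrix(x)
  m <- mm$m
  grp <- if ("zygosity" %in% colnames(pairs)) pairs$zygosity
         else rep("NR", nrow(pairs))
  d <- abs(m[pairs$member1, , drop = FALSE] -
           m[pairs$member2, , drop = FALSE])
  if (level == "unit") {
    out <- data.frame(
      pair_id = rep(pairs$pair_id, ncol(d)),
      group = rep(grp, ncol(d)),
      unit = rep(colnames(d), each = nrow(d)),
      region = rep(unname(mm$region[colnames(d)]), each = nrow(d)),
      discordance = as.vector(d), stringsAsFactors = FALSE)
    return(out)
  }
  regs <- unique(unname(mm$region))
  res <- lapply(regs, function(rg) {
    du <- d[, mm$region[colnames(d)] == rg, drop = FALSE]
    k <- ncol(du)
    val <- apply(du, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_real_)
      if (mode == "scaled") mean(v) * k else sum(v)
    })
    data.frame(pair_id = pairs$pair_id, group = grp, region = rg,
               discordance = unname(val), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Non-related pseudo-pairs
#'
#' Randomly re-pairs the cohort's individuals into a perfect matching in
#' which no pseudo-pair shares a family id, giving the non-related (NR)
#' null group for the discordance comparison. Same number of pairs as
#' the input cohort; deterministic under a fixed seed.
#'
#' @param cohort a \linkS4class{TwinCohort} (needs at least two
#'   families).
#' @param seed optional integer seed.
#' @param maxTries rejection-sampling budget before giving up.
#' @return data.frame with \code{pair_id} (\code{NR0001, ...}),
#'   \code{member1}, \code{member2}, \code{zygosity = "NR"}.
#' @export
makeNonrelatedPairs <- function(cohort, seed = NULL, maxTries = 1000L) {
  stopifnot(is(cohort, "TwinCohort"))
  p <- pairTable(cohort)
  if (length(unique(p$family_id)) < 2L)
    stop("at least two families are required")
  ind <- individuals(cohort)
  fam <- stats::setNames(rep(p$family_id, each = 2L), ind)
  .with_seed(seed, {
    for (i in seq_len(maxTries)) {
      perm <- sample(ind)
      a <- perm[seq(1, length(perm), 2)]
      b <- perm[seq(2, length(perm), 2)]
      if (!any(fam[a] == fam[b])) {
        return(data.frame(
          pair_id = sprintf("NR%04d", seq_along(a)),
          member1 = a, member2 = b, zygosity = "NR",
          stringsAsFactors = FALSE))
      }
    }
    stop("could not find a family-avoiding matching in ", maxTries,
         " tries")
  })
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (chi-square approximation, k - 1 df)
#' followed by Dunn's z tests on rank means,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum(t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)},}
#' with Bonferroni adjustment over all k(k-1)/2 comparisons.
#'
#' @param groups named list of numeric vectors (NAs dropped).
#' @return list with \code{H}, \code{df}, \code{p.value}, and
#'   \code{comparisons} (data.frame: group1, group2, z, p, p.adj).
#' @export
kruskalWallisDunn <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 1L)) stop("each group needs at least one value")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(vals)
  if (N < 3L) stop("need at least three values in total")
  cmb <- utils::combn(names(groups), 2)
  if (length(unique(vals)) == 1L) {
    comparisons <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                              z = 0, p = 1, p.adj = 1,
                              stringsAsFactors = FALSE)
    return(list(H = 0, df = length(groups) - 1L, p.value = 1,
                comparisons = comparisons))
  }
  kw <- kruskal.test(vals, g)
  r <- rank(vals)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(vals)
  tiesum <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - tiesum / (12 * (N - 1))
  m <- ncol(cmb)
  z <- (rbar[cmb[1, ]] - rbar[cmb[2, ]]) /
    sqrt(s2 * (1 / n[cmb[1, ]] + 1 / n[cmb[2, ]]))
  p <- 2 * pnorm(-abs(z))
  comparisons <- data.frame(
    group1 = cmb[1, ], group2 = cmb[2, ], z = as.numeric(z),
    p = as.numeric(p), p.adj = pmin(1, as.numeric(p) * m),
    stringsAsFactors = FALSE)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, comparisons = comparisons)
}

#' Call loss/gain of methylation per individual and unit
#'
#' An observation is a LOM when its value is more than \code{cutoff}
#' below the unit's reference median, and a GOM when more than
#' \code{cutoff} above (strict inequalities: a value at exactly
#' median - cutoff is not a call). The cutoff is an absolute shift on
#' the 0-1 methylation-fraction scale; the default 0.10 corresponds to
#' calling >10% deviation from the median.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param cutoff call cutoff in \code{(0, 1)}.
#' @param reference \code{"all"} (median over the whole cohort, default)
#'   or \code{"per-zygosity"} (medians within MZ and DZ separately;
#'   requires \code{cohort}).
#' @param cohort \linkS4class{TwinCohort}, needed for per-zygosity
#'   medians.
#' @return list of class \code{"LomGomCalls"}: \code{calls}
#'   (individuals x units character matrix with "LOM"/"GOM"/"none"/NA),
#'   \code{medians}, \code{cutoff}.
#' @export
callLomGom <- function(x, cutoff = 0.10,
                       reference = c("all", "per-zygosity"),
                       cohort = NULL) {
  reference <- match.arg(reference)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  mm <- .meth_matrix(x)
  m <- mm$m
  if (reference == "all") {
    med <- apply(m, 2, median, na.rm = TRUE)
    medm <- matrix(med, nrow(m), ncol(m), byrow = TRUE)
  } else {
    if (is.null(cohort)) stop("per-zygosity reference needs 'cohort'")
    p <- pairTable(cohort)
    zyg <- stats::setNames(rep(p$zygosity, each = 2L), individuals(cohort))
    medm <- matrix(NA_real_, nrow(m), ncol(m))
    med <- list()
    for (z in unique(zyg)) {
      rows <- rownames(m)[zyg[rownames(m)] == z]
      mz <- apply(m[rows, , drop = FALSE], 2, median, na.rm = TRUE)
      medm[rownames(m) %in% rows, ] <-
        matrix(mz, sum(rownames(m) %in% rows), ncol(m), byrow = TRUE)
      med[[z]] <- mz
    }
  }
  calls <- matrix("none", nrow(m), ncol(m), dimnames = dimnames(m))
  calls[m < medm - cutoff] <- "LOM"
  calls[m > medm + cutoff] <- "GOM"
  calls[is.na(m)] <- NA_character_
  structure(list(calls = calls, medians = med, cutoff = cutoff,
                 region = mm$region),
            class = "LomGomCalls")
}

#' @export
print.LomGomCalls <- function(x, ...) {
  tab <- table(x$calls, useNA = "ifany")
  cat("LomGomCalls (cutoff", x$cutoff, "):",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Classify twin-pair concordance of LOM/GOM calls
#'
#' Per pair and unit, separately for LOM and GOM: \code{"concordant"}
#' when both co-twins carry the call, \code{"discordant"} when exactly
#' one does, \code{"none"} otherwise. Observations where either member
#' is missing at the unit are skipped.
#'
#' @param calls a \code{LomGomCalls} object from \code{\link{callLomGom}}.
#' @param pairs pair table (or \linkS4class{TwinCohort}).
#' @return data.frame with \code{pair_id}, \code{zygosity}, \code{unit},
#'   \code{region}, \code{lom}, \code{gom}.
#' @export
classifyPairConcordance <- function(calls, pairs) {
  stopifnot(inherits(calls, "LomGomCalls"))
  if (is(pairs, "TwinCohort")) pairs <- pairTable(pairs)
  cm <- calls$calls
  c1 <- cm[pairs$member1, , drop = FALSE]
  c2 <- cm[pairs$member2, , drop = FALSE]
  cls <- function(type) {
    a <- c1 == type; b <- c2 == type
    ok <- !is.na(a) & !is.na(b)
    out <- matrix(NA_character_, nrow(a), ncol(a))
    out[ok] <- "none"
    out[ok & a & b] <- "concordant"
    out[ok & xor(a, b)] <- "discordant"
    out
  }
  lom <- cls("LOM"); gom <- cls("GOM")
  keep <- !is.na(as.vector(lom))
  data.frame(
    pair_id = rep(pairs$pair_id, ncol(cm))[keep],
    zygosity = rep(if ("zygosity" %in% colnames(pairs)) pairs$zygosity
                   else "NA", ncol(cm))[keep],
    unit = rep(colnames(cm), each = nrow(pairs))[keep],
    region = rep(unname(calls$region[colnames(cm)]),
                 each = nrow(pairs))[keep],
    lom = as.vector(lom)[keep], gom = as.vector(gom)[keep],
    stringsAsFactors = FALSE)
}

#' Tabulate concordance counts and percentages
#'
#' Given classifications from \code{\link{classifyPairConcordance}},
#' counts observations per zygosity and region in the three classes
#' (concordant / discordant / none), separately for LOM and GOM, with
#' percentages \code{100 * count / column total} rounded half away from
#' zero to one decimal. A bare numeric vector of three counts is also
#' accepted and returns its percentage breakdown directly.
#'
#' @param x classification data.frame, or numeric(3) counts
#'   (concordant, discordant, none).
#' @param observation \code{"pair"} (default; one observation per pair
#'   and unit) or \code{"individual"} (each co-twin contributes an
#'   observation classified by its pair's status).
#' @return For counts: data.frame(class, count, pct). For a
#'   classification table: data.frame with \code{zygosity},
#'   \code{region}, \code{type} ("LOM"/"GOM"), \code{class},
#'   \code{count}, \code{pct}.
#' @examples
#' tabulateConcordance(c(60, 265, 2612))  # 2.0 / 9.0 / 88.9
#' @export
tabulateConcordance <- function(x, observation = c("pair", "individual")) {
  observation <- match.arg(observation)
  if (is.numeric(x)) {
    stopifnot(length(x) == 3L, all(x >= 0))
    tot <- sum(x)
    pct <- if (tot > 0) roundHalfUp(100 * x / tot, 1) else rep(NA_real_, 3)
    return(data.frame(class = c("concordant", "discordant", "none"),
                      count = as.numeric(x), pct = pct,
                      stringsAsFactors = FALSE))
  }
  mult <- if (observation == "individual") 2L else 1L
  res <- list()
  for (z in unique(x$zygosity)) for (rg in unique(x$region)) {
    sub <- x[x$zygosity == z & x$region == rg, , drop = FALSE]
    if (!nrow(sub)) next
    for (type in c("lom", "gom")) {
      cnt <- mult * c(concordant = sum(sub[[type]] == "concordant"),
                      discordant = sum(sub[[type]] == "discordant"),
                      none = sum(sub[[type]] == "none"))
      tab <- tabulateConcordance(unname(cnt))
      res[[length(res) + 1L]] <- data.frame(
        zygosity = z, region = rg, type = toupper(type),
        tab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' 3x2 chi-square test for MZ-vs-DZ concordance differences
#'
#' Pearson chi-square comparing the (concordant, discordant, none)
#' breakdown between MZ and DZ twins. Degrees of freedom are fixed at 2
#' (the 3x2 layout) even when a class is empty in both groups; cells
#' with a zero margin contribute nothing to the statistic.
#'
#' @param mzCounts,dzCounts numeric(3) non-negative counts.
#' @return list with \code{statistic}, \code{df = 2}, \code{p.value}.
#' @examples
#' chiSquare3x2(c(22, 17, 2720), c(0, 17, 2732))  # ~22.0, p ~1.7e-5
#' @export
chiSquare3x2 <- function(mzCounts, dzCounts) {
  stopifnot(length(mzCounts) == 3L, length(dzCounts) == 3L)
  o <- rbind(mzCounts, dzCounts)
  if (any(o < 0)) stop("counts must be non-negative")
  if (sum(o) == 0) stop("all-zero table")
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  nz <- e > 0
  stat <- sum((o[nz] - e[nz])^2 / e[nz])
  list(statistic = stat, df = 2L,
       p.value = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Concordance tabulations across a sweep of call cutoffs
#'
#' Re-runs the LOM/GOM caller and concordance tabulation at each cutoff.
#' Total calls are non-increasing in the cutoff.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param pairs pair table or \linkS4class{TwinCohort}.
#' @param cutoffs numeric vector of cutoffs in \code{(0, 1)}.
#' @param ... passed to \code{\link{callLomGom}} and
#'   \code{\link{tabulateConcordance}}.
#' @return named list (one tabulation per cutoff).
#' @export
cutoffSweep <- function(x, pairs, cutoffs, ...) {
  stats::setNames(lapply(cutoffs, function(d) {
    calls <- callLomGom(x, cutoff = d)
    tabulateConcordance(classifyPairConcordance(calls, pairs))
  }), as.character(cutoffs))
}
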