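#' Parent-of-origin genotype groups
#'
#' Orders each individual's genotype label with the maternal allele
#' first (e.g. \code{"[AG]"} = maternal A, paternal G), the grouping
#' used to detect imprinted cis-effects. For an unphased SNP the two
#' heterozygote orientations cannot be separated and are pooled into one
#' group (e.g. \code{"[CG/GC]"}); homozygotes are labelled the same way
#' in either mode. Individuals with a missing genotype are dropped with
#' a message.
#'
#' @param genotypes genotype table (\code{individual}, \code{snp},
#'   \code{maternal}, \code{paternal}).
#' @param snp SNP id to group on.
#' @param phased logical; is parental origin trusted for this SNP?
#' @return named character vector, individual to group label.
#' @export
assignOriginGroups <- function(genotypes, snp, phased = TRUE) {
  g <- genotypes[genotypes$snp == snp, , drop = FALSE]
  if (!nrow(g)) stop("no genotypes for SNP ", snp)
  miss <- is.na(g$maternal) | is.na(g$paternal)
  if (any(miss)) {
    message(sum(miss), " individuals dropped: missing ", snp, " genotype")
    g <- g[!miss, , drop = FALSE]
  }
  lab <- if (phased) {
    sprintf("[%s%s]", g$maternal, g$paternal)
  } else {
    vapply(seq_len(nrow(g)), function(i) {
      a <- sort(c(g$maternal[i], g$paternal[i]))
      if (a[1] == a[2]) sprintf("[%s%s]", a[1], a[2])
      else sprintf("[%s%s/%s%s]", a[1], a[2], a[2], a[1])
    }, "")
  }
  stats::setNames(lab, g$individual)
}

#' Methylation stratified by genotype group
#'
#' Per CpG unit: group medians and a Kruskal-Wallis test with Dunn's
#' post-hoc comparisons across genotype groups. By default one member
#' per MZ pair (the first by id) enters the test, since MZ co-twins
#' duplicate the genotype and would inflate n; set \code{onePerMZ =
#' FALSE} to pool all individuals.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param groups named character vector from
#'   \code{\link{assignOriginGroups}}.
#' @param units unit ids to test (default all).
#' @param onePerMZ drop the second member of each MZ pair.
#' @param cohort \linkS4class{TwinCohort}; required for
#'   \code{onePerMZ} unless \code{x} carries cohort colData.
#' @return list with \code{summary} (data.frame: unit, H, df, p, one
#'   column of medians per group) and \code{comparisons} (named list of
#'   Dunn tables per unit).
#' @export
methylationByGenotype <- function(x, groups, units = NULL,
                                  onePerMZ = TRUE, cohort = NULL) {
  mm <- .meth_matrix(x)
  m <- mm$m
  if (is.null(units)) units <- colnames(m)
  ind <- intersect(rownames(m), names(groups))
  if (onePerMZ) {
    drop2 <- character()
    if (!is.null(cohort)) {
      pt <- pairTable(cohort)
      drop2 <- pt$member2[pt$zygosity == "MZ"]
    } else if (is(x, "MethylationSet") &&
               "pair_id" %in%
                 colnames(SummarizedExperiment::colData(x))) {
      cd <- SummarizedExperiment::colData(x)
      drop2 <- rownames(cd)[cd$zygosity == "MZ" & duplicated(cd$pair_id)]
    }
    ind <- setdiff(ind, drop2)
  }
  gf <- groups[ind]
  lev <- sort(unique(gf))
  if (length(lev) < 2L) stop("need at least two non-empty groups")
  rows <- list(); cmps <- list()
  for (u in units) {
    v <- m[ind, u]
    byg <- split(v, gf)
    byg <- lapply(byg, function(z) z[!is.na(z)])
    nonempty <- lengths(byg) > 0
    if (sum(nonempty) < 2L) next   # unit unobserved in all but one group
    kw <- kruskalWallisDunn(byg[nonempty])
    med <- vapply(lev, function(g)
      if (length(byg[[g]])) median(byg[[g]]) else NA_real_, 0)
    rows[[u]] <- data.frame(unit = u, H = kw$H, df = kw$df,
                            p = kw$p.value, t(med),
                            check.names = FALSE, stringsAsFactors = FALSE)
    cmps[[u]] <- kw$comparisons
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       comparisons = cmps)
}

#' Variance inflation of the pooled heterozygote group
#'
#' When a SNP cannot be phased, both heterozygote orientations are
#' pooled; under an origin-specific methylation effect the pooled group
#' is a mixture of a shifted and an unshifted component and shows
#' inflated variance relative to either homozygote group. Reports
#' per-unit variances and flags units where the pooled heterozygote
#' variance exceeds both homozygote variances.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param pooledGroups named character vector from
#'   \code{\link{assignOriginGroups}(phased = FALSE)}.
#' @param units unit ids to examine (default all).
#' @return data.frame: unit, one variance column per group, and
#'   \code{inflated} (logical; NA when a group has n < 2).
#' @export
pooledHetVarianceCheck <- function(x, pooledGroups, units = NULL) {
  mm <- .meth_matrix(x)
  m <- mm$m
  if (is.null(units)) units <- colnames(m)
  ind <- intersect(rownames(m), names(pooledGroups))
  gf <- pooledGroups[ind]
  lev <- sort(unique(gf))
  het <- grep("/", lev, value = TRUE)
  hom <- setdiff(lev, het)
  if (length(het) != 1L)
    stop("expected exactly one pooled heterozygote group")
  res <- lapply(units, function(u) {
    v <- split(m[ind, u], gf)
    vs <- vapply(lev, function(g) {
      z <- v[[g]][!is.na(v[[g]])]
      if (length(z) < 2L) NA_real_ else var(z)
    }, 0)
    infl <- if (any(is.na(vs))) NA else all(vs[het] > vs[hom])
    data.frame(unit = u, t(vs), inflated = infl,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
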