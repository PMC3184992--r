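#' Simulate SNP genotypes with parental origin
#'
#' Draws parental genotypes per family under Hardy-Weinberg at each lead
#' SNP and transmits one maternal and one paternal allele to each twin.
#' MZ co-twins receive identical transmissions (including origin); DZ
#' co-twins draw their transmissions independently from the same two
#' parental genotypes. A SNP with \code{linkedTo} set is carried on the
#' lead SNP's haplotype: its transmitted allele is the phase image of the
#' transmitted lead allele, so the pair is co-inherited as one block.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param snps list of \code{\link{snpModel}} objects.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{individual}, \code{snp},
#'   \code{maternal}, \code{paternal} (one row per individual per SNP;
#'   alleles are phased, maternal first).
#' @export
simulateGenotypes <- function(cohort, snps, seed = NULL) {
  stopifnot(is(cohort, "TwinCohort"))
  p <- pairTable(cohort)
  if (!all(p$zygosity %in% c("MZ", "DZ"))) stop("unknown zygosity label")
  leads <- Filter(function(s) is.null(s$linkedTo), snps)
  linked <- Filter(function(s) !is.null(s$linkedTo), snps)
  lead_ids <- vapply(leads, `[[`, "", "id")
  for (s in linked)
    if (!s$linkedTo %in% lead_ids)
      stop("linked SNP ", s$id, " references unknown lead SNP ", s$linkedTo)
  nP <- nrow(p)
  out <- list()
  .with_seed(seed, {
    for (s in leads) {
      al <- s$alleles; pr <- c(s$freq, 1 - s$freq)
      # parental genotypes: two haplotypes each, identified by lead allele
      mum <- matrix(sample(al, 2 * nP, TRUE, pr), nP)
      dad <- matrix(sample(al, 2 * nP, TRUE, pr), nP)
      # transmitted haplotype index per twin; MZ share one segregation
      tm1 <- sample(1:2, nP, TRUE); tf1 <- sample(1:2, nP, TRUE)
      tm2 <- sample(1:2, nP, TRUE); tf2 <- sample(1:2, nP, TRUE)
      mz <- p$zygosity == "MZ"
      tm2[mz] <- tm1[mz]; tf2[mz] <- tf1[mz]
      g <- data.frame(
        individual = as.character(rbind(p$member1, p$member2)),
        snp = s$id,
        maternal = as.character(rbind(mum[cbind(seq_len(nP), tm1)],
                                      mum[cbind(seq_len(nP), tm2)])),
        paternal = as.character(rbind(dad[cbind(seq_len(nP), tf1)],
                                      dad[cbind(seq_len(nP), tf2)])),
        stringsAsFactors = FALSE)
      out[[s$id]] <- g
      for (ls in linked) {
        if (!identical(ls$linkedTo, s$id)) next
        out[[ls$id]] <- data.frame(
          individual = g$individual, snp = ls$id,
          maternal = unname(ls$phase[g$maternal]),
          paternal = unname(ls$phase[g$paternal]),
          stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# kinship-structured standard normal: one value per individual with
# cor(MZ co-twins) = 1 and cor(DZ co-twins) = 1/2, built by averaging two
# parental values and adding Mendelian segregation noise
.rkinship <- function(pairs) {
  nP <- nrow(pairs)
  mid <- (rnorm(nP) + rnorm(nP)) / 2            # midparent, var 1/2
  s1 <- rnorm(nP, sd = sqrt(0.5))
  s2 <- rnorm(nP, sd = sqrt(0.5))
  mz <- pairs$zygosity == "MZ"
  s2[mz] <- s1[mz]
  as.numeric(rbind(mid + s1, mid + s2))
}

# shared-by-pair standard normal (common environment)
.rshared <- function(pairs) {
  v <- rnorm(nrow(pairs))
  as.numeric(rbind(v, v))
}

#' Simulate allele-resolved methylation for a twin cohort
#'
#' Per CpG unit and parental allele, the methylation value is
#' \code{baseline + A + C + E + beta}, where A is an additive-genetic
#' component (identical within MZ pairs, correlation 1/2 within DZ
#' pairs), C is shared by both members of any pair, E is individual
#' noise, and \code{beta} is added when the individual's origin-matched
#' effect allele is carried (see \code{\link{snpModel}}). Units of one
#' region share a fraction \code{rhoW} of each component. The A/C/E
#' components are drawn once per individual and unit and applied to both
#' alleles, so the observed (allele-mean) value has variance
#' \code{sigmaA2 + sigmaC2 + sigmaE2} and the classical ACE intra-pair
#' correlations \code{(sigmaA2 + sigmaC2) / total} (MZ) and
#' \code{(sigmaA2/2 + sigmaC2) / total} (DZ). Allele values are clipped
#' to \code{[0, 1]} and the observed value is their mean.
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param genotypes genotype table from \code{\link{simulateGenotypes}}
#'   (may be \code{NULL} when no SNP carries an effect).
#' @param regions list of \code{\link{regionModel}} objects.
#' @param snps list of \code{\link{snpModel}} objects (effects applied).
#' @param seed optional integer seed; fixed seed gives a byte-identical
#'   table.
#' @return An allele-resolved \linkS4class{MethylationSet} whose
#'   \code{colData} carries pair, zygosity and family.
#' @export
simulateMethylation <- function(cohort, genotypes = NULL,
                                regions = defaultRegionModels(),
                                snps = list(), seed = NULL) {
  stopifnot(is(cohort, "TwinCohort"))
  p <- pairTable(cohort)
  ind <- individuals(cohort)
  n <- length(ind)
  all_units <- unlist(lapply(regions, `[[`, "units"), use.names = FALSE)
  for (s in snps)
    if (length(s$effectUnits) && !all(s$effectUnits %in% all_units))
      stop("effect target units of ", s$id, " not found in any region")
  mat <- pat <- matrix(NA_real_, n, length(all_units),
                       dimnames = list(ind, all_units))
  .with_seed(seed, {
    for (r in regions) {
      k <- length(r$units)
      sds <- sqrt(c(a = r$sigmaA2, c = r$sigmaC2, e = r$sigmaE2))
      wS <- sqrt(r$rhoW); wU <- sqrt(1 - r$rhoW)
      a0 <- .rkinship(p); c0 <- .rshared(p); e0 <- rnorm(n)
      X <- matrix(0, n, k)
      for (u in seq_len(k)) {
        X[, u] <- sds["a"] * (wS * a0 + wU * .rkinship(p)) +
                  sds["c"] * (wS * c0 + wU * .rshared(p)) +
                  sds["e"] * (wS * e0 + wU * rnorm(n))
      }
      mat[, r$units] <- sweep(X, 2, r$baselineMat, `+`)
      pat[, r$units] <- sweep(X, 2, r$baselinePat, `+`)
    }
  })
  for (s in snps) {
    if (!length(s$effectUnits) || s$beta == 0) next
    if (is.null(genotypes)) stop("SNP effects require a genotype table")
    g <- genotypes[genotypes$snp == s$id, , drop = FALSE]
    gm <- stats::setNames(g$maternal, g$individual)[ind]
    gp <- stats::setNames(g$paternal, g$individual)[ind]
    carM <- !is.na(gm) & gm == s$effectAllele
    mat[carM, s$effectUnits] <- mat[carM, s$effectUnits] + s$beta
    if (!s$parentalOrigin) {
      carP <- !is.na(gp) & gp == s$effectAllele
      pat[carP, s$effectUnits] <- pat[carP, s$effectUnits] + s$beta
    }
  }
  mat <- pmin(pmax(mat, 0), 1)
  pat <- pmin(pmax(pat, 0), 1)
  region <- rep(vapply(regions, `[[`, "", "name"),
                vapply(regions, function(r) length(r$units), 0L))
  cd <- S4Vectors::DataFrame(
    pair_id = rep(p$pair_id, each = 2L),
    zygosity = rep(p$zygosity, each = 2L),
    family_id = rep(p$family_id, each = 2L),
    row.names = ind)
  MethylationSet(maternal = mat, paternal = pat, region = region,
                 colData = cd)
}

#' Inject loss/gain-of-methylation aberrations
#'
#' Shifts selected twins' methylation by \code{-magnitude} (LOM) or
#' \code{+magnitude} (GOM) over the scope of each event: one unit
#' (local), a contiguous block of units within one region (regional), or
#' units of at least two regions (trans). Concordant events hit both
#' members of the chosen pair, discordant events exactly one. The
#' observed level moves by the full magnitude wherever the alleles can
#' absorb it: a loss is drawn from the methylated allele first (that is
#' where the methylation resides), a gain fills the unmethylated allele
#' first, for a total allele change of twice the magnitude, clipped to
#' \code{[0, 1]}. Event targets are sampled among units whose typical
#' level can express the shift. The ground-truth event log is appended
#' to \code{metadata(x)$aberrations}.
#'
#' @param x an allele-resolved \linkS4class{MethylationSet} (a plain
#'   observed-only set is shifted on its observed assay).
#' @param events list of \code{\link{aberrationEvent}} objects.
#' @param cohort the \linkS4class{TwinCohort}; defaults to the pair
#'   structure stored in \code{colData(x)}.
#' @param pairIds optional character vector assigning a pair to each
#'   event (sampled otherwise).
#' @param seed optional integer seed.
#' @return The modified \code{MethylationSet}.
#' @export
injectAberrations <- function(x, events, cohort = NULL, pairIds = NULL,
                              seed = NULL) {
  stopifnot(is(x, "MethylationSet"))
  cd <- SummarizedExperiment::colData(x)
  if (is.null(cohort)) {
    if (!"pair_id" %in% colnames(cd))
      stop("no pair structure available; supply 'cohort'")
    pdf <- do.call(rbind, lapply(split(seq_len(nrow(cd)), cd$pair_id),
      function(i) data.frame(pair_id = cd$pair_id[i[1]],
                             zygosity = cd$zygosity[i[1]],
                             member1 = rownames(cd)[i[1]],
                             member2 = rownames(cd)[i[2]])))
  } else pdf <- pairTable(cohort)
  units <- rownames(x)
  region <- unitRegions(x)
  has_alleles <- all(c("maternal", "paternal") %in%
                     SummarizedExperiment::assayNames(x))
  asy <- SummarizedExperiment::assays(x)
  med <- apply(asy$methylation, 1, median, na.rm = TRUE)
  log <- list()
  .with_seed(seed, {
    for (ei in seq_along(events)) {
      ev <- events[[ei]]
      stopifnot(is(ev, "AberrationEvent"))
      pr <- if (!is.null(pairIds)) pdf[pdf$pair_id == pairIds[ei], ]
            else pdf[sample(nrow(pdf), 1L), ]
      if (nrow(pr) != 1L) stop("unknown pair id for event ", ei)
      tu <- ev$units
      if (is.null(tu)) {
        # a loss needs methylation to lose (and a gain headroom to
        # gain): sample among units whose typical level can express the
        # full shift without clipping
        elig <- if (ev$direction == "LOM") units[med >= ev$magnitude]
                else units[med <= 1 - ev$magnitude]
        if (!length(elig))
          stop("no unit can express a ", ev$direction, " of magnitude ",
               ev$magnitude)
        eregs <- unique(region[elig])
        tu <- switch(ev$scope,
          local = sample(elig, 1L),
          regional = {
            rg <- sample(eregs, 1L)
            ru <- elig[region[elig] == rg]
            len <- sample(2:max(2L, min(4L, length(ru))), 1L)
            st <- sample(seq_len(max(1L, length(ru) - len + 1L)), 1L)
            ru[st:min(length(ru), st + len - 1L)]
          },
          trans = {
            rgs <- sample(eregs, min(2L, length(eregs)))
            unlist(lapply(rgs, function(rg) {
              ru <- elig[region[elig] == rg]
              sample(ru, min(2L, length(ru)))
            }))
          })
      }
      if (!all(tu %in% units))
        stop("event ", ei, " references unknown units: ",
             paste(setdiff(tu, units), collapse = ", "))
      who <- if (ev$concordance == "concordant")
        c(pr$member1, pr$member2)
      else sample(c(pr$member1, pr$member2), 1L)
      if (has_alleles) {
        # move the observed (allele-mean) level by the magnitude: a
        # loss is drawn from the methylated allele first (that is
        # where the methylation to lose resides), a gain fills the
        # unmethylated allele first; total allele change 2x magnitude
        ma <- asy$maternal[tu, who, drop = FALSE]
        pa <- asy$paternal[tu, who, drop = FALSE]
        m2 <- 2 * ev$magnitude
        hiM <- !is.na(ma) & !is.na(pa) & ma >= pa
        hi <- ifelse(hiM, ma, pa); lo <- ifelse(hiM, pa, ma)
        if (ev$direction == "LOM") {
          d1 <- pmin(hi, m2); d2 <- pmin(lo, m2 - d1)
          hi <- hi - d1; lo <- lo - d2
        } else {
          d1 <- pmin(1 - lo, m2); d2 <- pmin(1 - hi, m2 - d1)
          lo <- lo + d1; hi <- hi + d2
        }
        asy$maternal[tu, who] <- ifelse(hiM, hi, lo)
        asy$paternal[tu, who] <- ifelse(hiM, lo, hi)
      } else {
        shift <- if (ev$direction == "LOM") -ev$magnitude
                 else ev$magnitude
        asy$methylation[tu, who] <-
          pmin(pmax(asy$methylation[tu, who] + shift, 0), 1)
      }
      log[[ei]] <- data.frame(
        event = ei, pair_id = pr$pair_id, scope = ev$scope,
        direction = ev$direction, concordance = ev$concordance,
        magnitude = ev$magnitude,
        individuals = paste(who, collapse = ";"),
        units = paste(tu, collapse = ";"), stringsAsFactors = FALSE)
    }
  })
  if (has_alleles)
    asy$methylation <- (asy$maternal + asy$paternal) / 2
  SummarizedExperiment::assays(x) <- asy
  S4Vectors::metadata(x)$aberrations <-
    rbind(S4Vectors::metadata(x)$aberrations,
          do.call(rbind, log))
  x
}

#' Apply independent missingness to a methylation table
#'
#' Each (individual, unit) entry is set missing with probability
#' \code{rate}, jointly across the observed and allele assays (a failed
#' measurement loses the whole unit for that individual).
#'
#' @param x a \linkS4class{MethylationSet}.
#' @param rate missingness probability in \code{[0, 1)}.
#' @param seed optional integer seed.
#' @return The masked \code{MethylationSet}.
#' @export
applyMissingness <- function(x, rate, seed = NULL) {
  stopifnot(is(x, "MethylationSet"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(x)
  asy <- SummarizedExperiment::assays(x)
  mask <- .with_seed(seed,
    matrix(runif(nrow(x) * ncol(x)) < rate, nrow(x), ncol(x)))
  for (nm in names(asy)) asy[[nm]][mask] <- NA_real_
  SummarizedExperiment::assays(x) <- asy
  x
}
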