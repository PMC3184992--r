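#' SNP model for cohort simulation
#'
#' Describes a biallelic SNP: its allele frequency, optional haplotype
#' linkage to a lead SNP, and an optional effect on the methylation level
#' of target CpG units. When \code{parentalOrigin = TRUE} the effect
#' \code{beta} (a methylation-fraction shift) is applied only to the
#' allele inherited from the mother, which is how an imprinted
#' cis-effect such as the hypermethylating maternal rs10732516 [A] allele
#' behaves; otherwise any allele copy carrying \code{effectAllele} shifts
#' its own allele-level value.
#'
#' Linkage is expressed as complete co-inheritance: \code{phase} maps each
#' allele of the lead SNP (\code{linkedTo}) to the allele this SNP carries
#' on the same haplotype, so co-transmission is deterministic.
#'
#' @param id SNP identifier (e.g. \code{"rs10732516"}).
#' @param alleles character(2), the two alleles; \code{freq} refers to the
#'   first.
#' @param freq frequency of \code{alleles[1]} in \code{[0, 1]}.
#' @param linkedTo,phase lead SNP id and a named character vector mapping
#'   lead alleles to this SNP's alleles (both \code{NULL} for an
#'   independent SNP).
#' @param effectUnits CpG unit ids shifted by the effect allele.
#' @param beta methylation-fraction shift in \code{[-1, 1]}.
#' @param effectAllele the allele carrying the effect (default
#'   \code{alleles[1]}).
#' @param parentalOrigin logical; restrict the effect to the maternal
#'   allele.
#' @return A list of class \code{"SnpModel"}.
#' @export
snpModel <- function(id, alleles, freq, linkedTo = NULL, phase = NULL,
                     effectUnits = character(), beta = 0,
                     effectAllele = alleles[1], parentalOrigin = TRUE) {
  stopifnot(length(alleles) == 2L, is.character(alleles))
  if (freq < 0 || freq > 1) stop("allele frequency must lie in [0, 1]")
  if (abs(beta) > 1) stop("beta must lie in [-1, 1]")
  if (!is.null(linkedTo) && is.null(phase))
    stop("a linked SNP needs a phase map")
  if (!is.null(phase) && !all(phase %in% alleles))
    stop("phase map must yield alleles of this SNP")
  structure(list(id = id, alleles = alleles, freq = freq,
                 linkedTo = linkedTo, phase = phase,
                 effectUnits = as.character(effectUnits), beta = beta,
                 effectAllele = effectAllele,
                 parentalOrigin = isTRUE(parentalOrigin)),
            class = "SnpModel")
}

#' Region model for cohort simulation
#'
#' A genomic region measured as a set of CpG units, with per-allele
#' baseline methylation and an ACE variance decomposition: additive
#' genetic variance \code{sigmaA2} (shared fully by MZ co-twins, half by
#' DZ), common-environment variance \code{sigmaC2} (shared by any
#' co-twins), and unique-environment variance \code{sigmaE2}. Units of a
#' region share a fraction \code{rhoW} of each variance component, giving
#' within-region correlation \code{rhoW} between unit values of one
#' individual.
#'
#' @param name region name; unit ids become \code{"<name>:uNN"}.
#' @param nUnits number of CpG units.
#' @param baselineMat,baselinePat baseline methylation of the maternal /
#'   paternal allele, recycled across units, each in \code{[0, 1]}.
#' @param sigmaA2,sigmaC2,sigmaE2 non-negative variance components (on
#'   the methylation-fraction scale, applied to both alleles jointly).
#' @param rhoW within-region correlation in \code{[0, 1]}.
#' @return A list of class \code{"RegionModel"} with element \code{units}.
#' @export
regionModel <- function(name, nUnits, baselineMat, baselinePat,
                        sigmaA2 = 0, sigmaC2 = 0, sigmaE2 = 0,
                        rhoW = 0) {
  stopifnot(nUnits >= 1)
  baselineMat <- rep_len(baselineMat, nUnits)
  baselinePat <- rep_len(baselinePat, nUnits)
  if (any(c(baselineMat, baselinePat) < 0 | c(baselineMat, baselinePat) > 1))
    stop("baselines must lie in [0, 1]")
  if (any(c(sigmaA2, sigmaC2, sigmaE2) < 0))
    stop("variance components must be non-negative")
  if (rhoW < 0 || rhoW > 1) stop("rhoW must lie in [0, 1]")
  units <- sprintf("%s:u%02d", name, seq_len(nUnits))
  structure(list(name = name, units = units, baselineMat = baselineMat,
                 baselinePat = baselinePat, sigmaA2 = sigmaA2,
                 sigmaC2 = sigmaC2, sigmaE2 = sigmaE2, rhoW = rhoW),
            class = "RegionModel")
}

#' Aberration event for injection into a methylation table
#'
#' A loss (LOM) or gain (GOM) of methylation affecting one twin
#' (discordant) or both members of a pair (concordant), at local scope
#' (one unit), regional scope (a contiguous block of units of one
#' region), or in trans (units drawn from at least two regions).
#'
#' @param scope one of \code{"local"}, \code{"regional"}, \code{"trans"}.
#' @param direction \code{"LOM"} or \code{"GOM"}.
#' @param concordance \code{"concordant"} or \code{"discordant"}.
#' @param magnitude positive methylation-fraction shift.
#' @param units optional explicit unit ids (otherwise sampled when the
#'   event is injected).
#' @return A list of class \code{"AberrationEvent"}.
#' @export
aberrationEvent <- function(scope = c("local", "regional", "trans"),
                            direction = c("LOM", "GOM"),
                            concordance = c("discordant", "concordant"),
                            magnitude, units = NULL) {
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  concordance <- match.arg(concordance)
  if (magnitude <= 0) stop("magnitude must be positive")
  structure(list(scope = scope, direction = direction,
                 concordance = concordance, magnitude = magnitude,
                 units = units),
            class = "AberrationEvent")
}

#' Default region models of the study design
#'
#' Five regions emulating the measured loci: four imprinted regions whose
#' observed methylation sits near 50% (maternal/paternal allele baselines
#' 0.05/0.95 for paternally methylated H19-ICR and IGF2-DMR; 0.95/0.05
#' for the maternally methylated KvDMR and NESPAS-ICR) and a
#' non-imprinted RUNX1-like promoter with low methylation on both alleles
#' (medians 0 to 0.18 across units). Unit counts total 54. Total variance
#' per region is calibrated so the observed inter-individual IQR matches
#' the reported values (0.12, 0.12, 0.05, 0.05, 0.06 for H19-ICR,
#' IGF2-DMR, NESPAS-ICR, KvDMR, RUNX1): for a Gaussian component,
#' sigma = IQR / 1.349. The split between A, C and E and the within-region
#' correlation are simulation choices documented in the methods vignette.
#'
#' @return Named list of \code{\link{regionModel}} objects.
#' @export
defaultRegionModels <- function() {
  tot <- function(iqr) (iqr / 1.349)^2  # Gaussian IQR -> variance
  split3 <- function(v, a = 0.5, c = 0.2) {
    list(a = a * v, c = c * v, e = (1 - a - c) * v)
  }
  h19 <- split3(tot(0.12)); igf2 <- split3(tot(0.12), a = 0.3, c = 0.2)
  kv <- split3(tot(0.05), a = 0.3, c = 0.2)
  nespas <- split3(tot(0.05), a = 0.3, c = 0.2)
  runx1 <- split3(tot(0.06), a = 0.35, c = 0.15)
  list(
    `H19-ICR` = regionModel("H19-ICR", 9, 0.05, 0.95,
                            h19$a, h19$c, h19$e, rhoW = 0.7),
    `IGF2-DMR` = regionModel("IGF2-DMR", 5, 0.05, 0.95,
                             igf2$a, igf2$c, igf2$e, rhoW = 0.6),
    KvDMR = regionModel("KvDMR", 10, 0.95, 0.05,
                        kv$a, kv$c, kv$e, rhoW = 0.75),
    `NESPAS-ICR` = regionModel("NESPAS-ICR", 11, 0.95, 0.05,
                               nespas$a, nespas$c, nespas$e, rhoW = 0.7),
    RUNX1 = regionModel("RUNX1", 19,
                        seq(0.0, 0.18, length.out = 19),
                        seq(0.0, 0.18, length.out = 19),
                        runx1$a, runx1$c, runx1$e, rhoW = 0.3)
  )
}

#' Default SNP models of the study design
#'
#' Two SNPs of the IGF2/H19 haplotype block: the lead SNP rs10732516
#' (A/G) whose maternal [A] allele hypermethylates the 5' H19-ICR units
#' (effect size \code{beta}), and the co-inherited rs2839701 (C/G) whose
#' [G] allele rides on the same haplotype as rs10732516 [A]. Allele
#' frequency defaults to 0.5 (Hardy-Weinberg).
#'
#' @param beta maternal-allele methylation shift of the [A] allele
#'   (default 0.15).
#' @param freq frequency of the rs10732516 [A] allele.
#' @param effectUnits CpG units affected (default the early H19-ICR
#'   units u02-u04, mirroring the strongest effect at CpG sites 2-4).
#' @return Named list of \code{\link{snpModel}} objects.
#' @export
defaultSnpModels <- function(beta = 0.15, freq = 0.5,
                             effectUnits = c("H19-ICR:u02", "H19-ICR:u03",
                                             "H19-ICR:u04")) {
  list(
    rs10732516 = snpModel("rs10732516", c("A", "G"), freq = freq,
                          effectUnits = effectUnits, beta = beta,
                          effectAllele = "A", parentalOrigin = TRUE),
    rs2839701 = snpModel("rs2839701", c("G", "C"), freq = freq,
                         linkedTo = "rs10732516",
                         phase = c(A = "G", G = "C"))
  )
}
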