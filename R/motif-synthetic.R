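#' Synthetic CTCF-like PWM
#'
#' A 12-column toy matrix emulating the shape of the CTCF binding
#' preference that matters here: a near-deterministic cytosine at
#' position 6 (counts 97/1/1/1) flanked by moderately informative
#' positions (70/10/10/10 on the consensus base). The sharp position-6
#' column carries enough score weight that a single C-to-T substitution
#' there drops a site below a 0.85 fractional match, so consensus and
#' variant scans separate cleanly. Synthetic; it is not the JASPAR
#' matrix.
#'
#' @return A \code{"MotifPWM"} with consensus \code{GCCACCAGGTGG}
#'   (C at position 6).
#' @export
exampleCtcfPWM <- function() {
  consensus <- strsplit("GCCACCAGGTGG", "")[[1]]
  counts <- matrix(10, 4, length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 70
  counts[, 6] <- 1
  counts["C", 6] <- 97
  motifPWM(counts)
}

#' Planted-signal genome and enrichment track
#'
#' Builds a random genome sequence with the PWM's consensus planted at
#' \code{nConsensus} sites and the position-substituted variant motif
#' (e.g. C-to-T at position 6) at \code{nVariant} sites, all spaced at
#' least \code{2 * flank + width} apart, plus an enrichment track with a
#' triangular peak of height \code{peakHeight} over each consensus site
#' and \code{peakHeight * variantFrac} over each variant site. This is
#' the construction used to check that the variant-motif meta-profile
#' carries about \code{1 / variantFrac} times less signal.
#'
#' @param pwm consensus \code{"MotifPWM"}.
#' @param position,from,to the substitution defining the variant motif.
#' @param nConsensus,nVariant numbers of planted sites.
#' @param flank spacing half-window (peaks do not overlap windows).
#' @param peakHeight consensus peak height.
#' @param peakHalfWidth half-width of the triangular peak in bp.
#' @param variantFrac variant peak height as a fraction of
#'   \code{peakHeight} (default 0.5).
#' @param seed optional integer seed.
#' @return list: \code{sequences} (named character), \code{track}
#'   (named list of numeric), \code{sites} (data.frame: start, kind),
#'   \code{variantPwm}.
#' @export
plantedMotifGenome <- function(pwm, position = 6, from = "C", to = "T",
                               nConsensus = 40, nVariant = 40,
                               flank = 500L, peakHeight = 10,
                               peakHalfWidth = 150L, variantFrac = 0.5,
                               seed = NULL) {
  L <- ncol(pwm$logodds)
  slot_len <- 2L * flank + L + 100L
  nsites <- nConsensus + nVariant
  glen <- slot_len * nsites + 2L * flank
  variantPwm <- mutatePWM(pwm, position, from, to)
  cons <- pwm$consensus
  varcons <- variantPwm$consensus
  .with_seed(seed, {
    ch <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    kind <- sample(rep(c("consensus", "variant"), c(nConsensus, nVariant)))
    starts <- flank + slot_len * (seq_len(nsites) - 1L) +
      sample(0:99, nsites, replace = TRUE)
    for (i in seq_len(nsites)) {
      motif <- if (kind[i] == "consensus") cons else varcons
      ch[(starts[i] + 1L):(starts[i] + L)] <- strsplit(motif, "")[[1]]
    }
    gseq <- paste(ch, collapse = "")
    track <- numeric(glen)
    for (i in seq_len(nsites)) {
      h <- if (kind[i] == "consensus") peakHeight
           else peakHeight * variantFrac
      mid <- starts[i] + L %/% 2L
      offs <- -peakHalfWidth:peakHalfWidth
      pos <- mid + offs
      ok <- pos >= 0 & pos < glen
      track[pos[ok] + 1L] <- track[pos[ok] + 1L] +
        h * (1 - abs(offs[ok]) / (peakHalfWidth + 1))
    }
    list(sequences = c(genome = gseq),
         track = list(genome = track),
         sites = data.frame(start = starts, kind = kind,
                            stringsAsFactors = FALSE),
         variantPwm = variantPwm)
  })
}
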