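#' AssayDesign: a bisulfite MassCleave amplicon assay
#'
#' Describes one amplicon interrogated by the T-cleavage MassCleave
#' chemistry: the genomic plus-strand sequence (5'->3'), the CpG site
#' positions, primer spans, and any SNPs inside the amplicon. The assay
#' transcribes the reverse strand of the bisulfite-converted PCR product
#' from a T7-tagged reverse primer; because dCTP is incorporated instead
#' of rCTP, RNase A cleaves only 3' of rU, so cleavage sites correspond
#' to plus-strand adenines and are independent of methylation.
#'
#' @slot name assay/region name, used as the unit id prefix.
#' @slot sequence plus-strand amplicon sequence.
#' @slot cpgSites 0-based positions of the C of each CpG on the plus
#'   strand (reference allele).
#' @slot fwdPrimer,revPrimer integer(2) 0-based half-open spans.
#' @slot snps data.frame with columns \code{id}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}.
#' @exportClass AssayDesign
setClass("AssayDesign",
  representation(name = "character", sequence = "character",
                 cpgSites = "integer", fwdPrimer = "integer",
                 revPrimer = "integer", snps = "data.frame"))

setValidity("AssayDesign", function(object) {
  s <- object@sequence
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "T")))
    return("sequence may contain only A/C/G/T")
  cs <- object@cpgSites
  if (length(cs) && (any(cs < 0) || any(cs + 1 >= n)))
    return("CpG positions out of range")
  if (length(cs) && !all(ch[cs + 1] == "C" & ch[cs + 2] == "G"))
    return("every CpG position must index a C followed by G")
  for (p in list(object@fwdPrimer, object@revPrimer))
    if (length(p) != 2L || p[1] < 0 || p[2] > n || p[1] >= p[2])
      return("primer spans must lie within the amplicon")
  if (nrow(object@snps) &&
      !all(ch[object@snps$pos + 1] == object@snps$ref))
    return("SNP reference alleles disagree with the sequence")
  TRUE
})

#' Construct an AssayDesign
#'
#' @param name assay name (unit id prefix).
#' @param sequence plus-strand amplicon (character).
#' @param cpgSites 0-based CpG C positions; auto-detected when
#'   \code{NULL}.
#' @param fwdPrimer,revPrimer integer(2) 0-based half-open spans; default
#'   to the amplicon ends (length-20 primers).
#' @param snps data.frame(\code{id}, \code{pos}, \code{ref}, \code{alt})
#'   of SNPs within the amplicon.
#' @return An \linkS4class{AssayDesign}.
#' @export
assayDesign <- function(name, sequence, cpgSites = NULL,
                        fwdPrimer = NULL, revPrimer = NULL,
                        snps = data.frame(id = character(), pos = integer(),
                                          ref = character(),
                                          alt = character())) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (is.null(cpgSites)) {
    m <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
    cpgSites <- if (m[1] == -1L) integer() else as.integer(m) - 1L
  }
  if (is.null(fwdPrimer)) fwdPrimer <- c(0L, min(20L, n))
  if (is.null(revPrimer)) revPrimer <- c(max(0L, n - 20L), n)
  new("AssayDesign", name = name, sequence = sequence,
      cpgSites = as.integer(cpgSites), fwdPrimer = as.integer(fwdPrimer),
      revPrimer = as.integer(revPrimer), snps = snps)
}

#' @rdname AssayDesign-class
#' @param object an \code{AssayDesign}
#' @export
setMethod("show", "AssayDesign", function(object) {
  cat("AssayDesign '", object@name, "': ", nchar(object@sequence),
      " bp, ", length(object@cpgSites), " CpG sites, ",
      nrow(object@snps), " SNP(s)\n", sep = "")
})

#' Mass conventions for MassCleave fragments
#'
#' Average (not monoisotopic) residue masses of the transcript bases:
#' rA 329.21, rG 345.21, rU 306.17 and 289.18 for the deoxy-C that the
#' dCTP chemistry incorporates. A methylated CpG places G instead of A in
#' the transcript, shifting the fragment mass by 16.00 Da per CpG. The
#' terminal adjustment (default +18.02, one water for the free fragment
#' ends) is a stated convention: absolute masses depend on the terminal
#' chemistry assumed, mass differences do not.
#'
#' @param terminal terminal-group mass adjustment in Da.
#' @return list with elements \code{residues}, \code{terminal},
#'   \code{methylShift}.
#' @export
massCleaveMasses <- function(terminal = 18.02) {
  list(residues = c(A = 329.21, G = 345.21, U = 306.17, C = 289.18),
       terminal = terminal, methylShift = 16.00)
}

#' Bisulfite conversion of a sequence given a methylation pattern
#'
#' Unmethylated cytosines deaminate to uracil and read as T after PCR;
#' 5-methylcytosine is protected. Every C is converted to T except CpG
#' cytosines listed as methylated.
#'
#' @param sequence plus-strand sequence (character scalar).
#' @param methylated 0-based positions of methylated CpG cytosines.
#' @return The converted sequence.
#' @examples
#' bisulfiteConvert("ACGTCT", methylated = 1)  # "ACGTTT"
#' bisulfiteConvert("ACGTCT")                  # "ATGTTT"
#' @export
bisulfiteConvert <- function(sequence, methylated = integer()) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  methylated <- as.integer(methylated)
  if (length(methylated)) {
    if (any(methylated < 0 | methylated >= length(ch)))
      stop("methylation pattern out of range")
    if (!all(ch[methylated + 1] == "C"))
      stop("methylation pattern indexes a non-C position")
    if (any(methylated + 2 > length(ch)) ||
        !all(ch[methylated + 2] == "G"))
      stop("methylation pattern must index CpG cytosines")
  }
  isC <- ch == "C"
  isC[methylated + 1] <- FALSE
  ch[isC] <- "T"
  paste(ch, collapse = "")
}

# apply an allele selection (named vector snp id -> base) to the
# plus-strand sequence; unspecified SNPs keep the reference base
.apply_allele <- function(design, allele = NULL) {
  s <- design@sequence
  if (is.null(allele) || !nrow(design@snps)) return(s)
  ch <- strsplit(s, "")[[1]]
  for (id in names(allele)) {
    row <- design@snps[design@snps$id == id, ]
    if (nrow(row) != 1L) stop("unknown SNP id: ", id)
    if (!allele[[id]] %in% c(row$ref, row$alt))
      stop("allele ", allele[[id]], " is not an allele of ", id)
    ch[row$pos + 1] <- allele[[id]]
  }
  paste(ch, collapse = "")
}

# CpG C positions (0-based) of a plus-strand sequence
.cpg_sites <- function(sequence) {
  m <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

#' Cleave a transcript 3' of every uracil
#'
#' RNase A T-cleavage on the dCTP transcript: the chain is cut after
#' every U (C is incorporated as a non-cleavable deoxy base).
#' Concatenating the fragments reconstructs the transcript exactly.
#'
#' @param transcript character scalar over A/C/G/U.
#' @return character vector of fragments, 5' to 3'.
#' @examples
#' cleaveTranscript("GGAUAACUUAG")  # "GGAU" "AACU" "U" "AG"
#' @export
cleaveTranscript <- function(transcript) .cleave_transcript(transcript)

.cleave_transcript <- function(transcript) {
  ch <- strsplit(transcript, "")[[1]]
  cut <- which(ch == "U")
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(ch))
  keep <- starts <= ends
  vapply(which(keep), function(i)
    paste(ch[starts[i]:ends[i]], collapse = ""), "")
}

#' In-silico T-cleavage digestion of a bisulfite amplicon
#'
#' Builds the reverse-strand transcript of the bisulfite-converted
#' amplicon (reverse complement, T7 from the reverse primer; plus-strand
#' A reads as rU, plus-strand G as non-cleavable deoxy-C) and cleaves
#' after every U. A methylated plus-strand CpG leaves C after conversion
#' and therefore places G instead of A in the transcript (+16.00 Da); an
#' allele substitution can create or destroy cleavage sites, yielding
#' allele-specific fragment sets.
#'
#' @param design an \linkS4class{AssayDesign}.
#' @param methylated \code{"none"}, \code{"all"}, or 0-based positions of
#'   methylated CpG cytosines (on the selected allele's sequence).
#' @param allele optional named character vector, SNP id to allele base.
#' @return data.frame with one row per fragment, 5'->3' along the
#'   transcript: \code{fragment} (sequence, unmethylated form),
#'   \code{start} (0-based transcript offset), \code{nCpG},
#'   \code{cpgSites} (list column, 0-based plus-strand C positions),
#'   \code{mass0} (mass of the unmethylated fragment, Da).
#' @examples
#' d <- assayDesign("demo", "TTAGTCGGTTCAGTT")
#' digestAmplicon(d)
#' @export
digestAmplicon <- function(design, methylated = "none", allele = NULL) {
  stopifnot(is(design, "AssayDesign"))
  seqA <- .apply_allele(design, allele)
  sites <- .cpg_sites(seqA)
  meth <- if (identical(methylated, "none")) integer()
          else if (identical(methylated, "all")) sites
          else as.integer(methylated)
  conv <- bisulfiteConvert(seqA, meth)
  n <- nchar(conv)
  transcript <- paste(rev(strsplit(chartr("ACGT", "UGCA", conv), "")[[1]]),
                      collapse = "")
  frags <- .cleave_transcript(transcript)
  starts <- c(0L, cumsum(nchar(frags)))[seq_along(frags)]
  # transcript position of a CpG's informative base (A unmeth / G meth)
  tpos <- n - 1L - sites
  masses <- massCleaveMasses()
  res <- lapply(seq_along(frags), function(i) {
    span <- c(starts[i], starts[i] + nchar(frags[i]))  # half-open
    inside <- tpos >= span[1] & tpos < span[2]
    fs <- strsplit(frags[i], "")[[1]]
    # canonical unmethylated form: CpG positions carry A
    fs[tpos[inside] - span[1] + 1L] <- "A"
    fseq <- paste(fs, collapse = "")
    data.frame(fragment = fseq, start = starts[i],
               nCpG = sum(inside), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$cpgSites <- lapply(seq_along(frags), function(i) {
    span <- c(starts[i], starts[i] + nchar(frags[i]))
    sort(sites[tpos >= span[1] & tpos < span[2]])
  })
  out$mass0 <- vapply(out$fragment, function(f)
    sum(masses$residues[strsplit(f, "")[[1]]]) + masses$terminal,
    0, USE.NAMES = FALSE)
  out
}

#' Mass of a cleavage fragment at a given methylation count
#'
#' The mass series of a k-CpG fragment is an arithmetic progression:
#' \code{mass(c) = mass(0) + c * 16.00} Da, because each methylated CpG
#' substitutes G (345.21) for A (329.21) in the transcript.
#'
#' @param fragment a one-row data.frame from \code{\link{digestAmplicon}},
#'   or a fragment sequence (unmethylated form) as character.
#' @param nMethylated number of methylated CpGs, \code{0 <= n <= k}.
#' @param nCpG required when \code{fragment} is a bare sequence.
#' @param masses mass table from \code{\link{massCleaveMasses}}.
#' @return mass in Da.
#' @export
fragmentMass <- function(fragment, nMethylated = 0, nCpG = NULL,
                         masses = massCleaveMasses()) {
  if (is.data.frame(fragment)) {
    stopifnot(nrow(fragment) == 1L)
    k <- fragment$nCpG
    base <- fragment$mass0
  } else {
    if (is.null(nCpG)) stop("supply nCpG for a bare fragment sequence")
    k <- nCpG
    base <- sum(masses$residues[strsplit(fragment, "")[[1]]]) +
      masses$terminal
  }
  if (nMethylated < 0 || nMethylated > k)
    stop("nMethylated must lie in [0, nCpG]")
  base + nMethylated * masses$methylShift
}

#' Build the CpG-unit map of an assay
#'
#' CpG sites sharing one cleavage fragment are measured jointly as a
#' single CpG unit. Units whose mass series overlaps another fragment's
#' series within \code{tol} are flagged as collisions (the intensities
#' are confounded and the unit is not quantified), and units whose
#' fragment overlaps a SNP are marked for exclusion.
#'
#' @param design an \linkS4class{AssayDesign}.
#' @param tol mass tolerance in Da for collision detection (default 0.5).
#' @return data.frame of class \code{"CpGUnitMap"}: one row per unit with
#'   \code{unit}, \code{nCpG}, \code{cpgSites} (list column),
#'   \code{mass0}, \code{collision}, \code{collidesWith}, \code{snp}.
#'   The full fragment table is attached as \code{attr(, "fragments")}.
#' @export
buildUnitMap <- function(design, tol = 0.5) {
  fr <- digestAmplicon(design)
  shift <- massCleaveMasses()$methylShift
  series <- lapply(seq_len(nrow(fr)), function(i)
    fr$mass0[i] + shift * (0:fr$nCpG[i]))
  unit_idx <- which(fr$nCpG > 0)
  collision <- logical(nrow(fr))
  collidesWith <- rep(NA_integer_, nrow(fr))
  for (i in seq_len(nrow(fr))) for (j in seq_len(nrow(fr))) {
    if (i == j) next
    if (any(abs(outer(series[[i]], series[[j]], `-`)) <= tol)) {
      collision[i] <- TRUE
      if (is.na(collidesWith[i])) collidesWith[i] <- j
    }
  }
  # SNP overlap on the transcript
  n <- nchar(design@sequence)
  snp_t <- n - 1L - design@snps$pos
  ends <- fr$start + nchar(fr$fragment)
  snp_hit <- vapply(seq_len(nrow(fr)), function(i)
    any(snp_t >= fr$start[i] & snp_t < ends[i]), NA)
  out <- fr[unit_idx, c("nCpG", "mass0", "start")]
  out$cpgSites <- fr$cpgSites[unit_idx]
  out$unit <- sprintf("%s:u%02d", design@name, seq_along(unit_idx))
  out$collision <- collision[unit_idx]
  out$collidesWith <- collidesWith[unit_idx]
  out$snp <- snp_hit[unit_idx]
  rownames(out) <- out$unit
  out <- out[, c("unit", "nCpG", "cpgSites", "mass0", "start",
                 "collision", "collidesWith", "snp")]
  attr(out, "fragments") <- fr
  attr(out, "tol") <- tol
  class(out) <- c("CpGUnitMap", "data.frame")
  out
}

#' Simulate a MassCleave spectrum
#'
#' Forward model: per-molecule CpG methylation states are digested and
#' each fragment contributes a peak at \code{mass0 + 16 * c} Da, with
#' intensity proportional to the abundance of molecules whose state has
#' \code{c} methylated CpGs on that fragment. For a heterozygote,
#' each allele contributes its own fragment set at weight 1/2 (this is
#' what makes simultaneous genotyping and allele-specific methylation
#' readable from one spectrum). Multiplicative log-normal noise with
#' standard deviation \code{noiseSd} (log scale) is applied per peak.
#'
#' @param design an \linkS4class{AssayDesign}.
#' @param states either \code{list(patterns = 0/1 matrix with one column
#'   per CpG site, abundance = numeric summing to 1)}, or a named list
#'   \code{list(maternal = ..., paternal = ...)} of two such state sets
#'   for an allele-resolved simulation.
#' @param genotype named character vector \code{c(maternal = , paternal
#'   = )} giving the allele base of the design's SNP on each parental
#'   allele (reference allele when \code{NULL}).
#' @param noiseSd log-normal noise sd (0 = noiseless).
#' @param seed optional integer seed.
#' @return data.frame (\code{mass}, \code{intensity}) sorted by mass.
#' @export
simulateSpectrum <- function(design, states, genotype = NULL,
                             noiseSd = 0, seed = NULL) {
  stopifnot(is(design, "AssayDesign"))
  per_allele <- all(c("maternal", "paternal") %in% names(states))
  snp_id <- if (nrow(design@snps)) design@snps$id[1] else NULL
  comps <- if (per_allele) {
    if (is.null(genotype))
      genotype <- c(maternal = design@snps$ref[1],
                    paternal = design@snps$ref[1])
    lapply(c("maternal", "paternal"), function(a)
      list(states = states[[a]], weight = 0.5,
           allele = if (!is.null(snp_id))
             stats::setNames(genotype[[a]], snp_id)))
  } else list(list(states = states, weight = 1,
                   allele = if (!is.null(genotype) && !is.null(snp_id))
                     stats::setNames(genotype[[1]], snp_id)))
  peaks <- list()
  for (cmp in comps) {
    st <- cmp$states
    ab <- st$abundance
    if (abs(sum(ab) - 1) > 1e-8)
      stop("state abundances must sum to 1")
    pat <- st$patterns
    if (is.null(dim(pat))) pat <- matrix(pat, nrow = 1)
    seqA <- .apply_allele(design, cmp$allele)
    sites <- .cpg_sites(seqA)
    # patterns are given over the reference site order; sites destroyed
    # by the allele are dropped, sites created default to unmethylated
    ref_sites <- design@cpgSites
    if (ncol(pat) != length(ref_sites))
      stop("patterns must have one column per reference CpG site")
    patA <- matrix(0L, nrow(pat), length(sites))
    keep <- match(sites, ref_sites)
    patA[, !is.na(keep)] <- pat[, keep[!is.na(keep)], drop = FALSE]
    fr <- digestAmplicon(design, allele = cmp$allele)
    shift <- massCleaveMasses()$methylShift
    for (i in seq_len(nrow(fr))) {
      if (fr$nCpG[i] == 0) {
        peaks[[length(peaks) + 1L]] <-
          c(fr$mass0[i], cmp$weight)
        next
      }
      idx <- match(fr$cpgSites[[i]], sites)
      cnt <- as.integer(patA[, idx, drop = FALSE] %*%
                          rep(1L, length(idx)))
      for (c0 in unique(cnt))
        peaks[[length(peaks) + 1L]] <-
          c(fr$mass0[i] + shift * c0,
            cmp$weight * sum(ab[cnt == c0]))
    }
  }
  pk <- do.call(rbind, peaks)
  sp <- data.frame(mass = pk[, 1], intensity = pk[, 2])
  sp <- stats::aggregate(intensity ~ mass, sp, sum)
  sp <- sp[order(sp$mass), ]
  if (noiseSd > 0)
    sp$intensity <- .with_seed(seed,
      sp$intensity * exp(rnorm(nrow(sp), sd = noiseSd)))
  rownames(sp) <- NULL
  sp
}

#' Estimate per-unit methylation ratios from a spectrum
#'
#' For a k-CpG unit with peak intensities \code{I_0..I_k} along the
#' 16-Da series, the methylation ratio is
#' \code{sum(c * I_c) / (k * sum(I_c))}. Units flagged as mass
#' collisions or SNP-overlapping return \code{NA}.
#'
#' @param spectrum data.frame (\code{mass}, \code{intensity}).
#' @param unitMap a \code{CpGUnitMap} from \code{\link{buildUnitMap}}.
#' @param tol peak-matching tolerance in Da.
#' @return named numeric vector of ratios in \code{[0, 1]} (NA for
#'   flagged or absent units).
#' @export
estimateMethylation <- function(spectrum, unitMap, tol = 0.5) {
  shift <- massCleaveMasses()$methylShift
  out <- rep(NA_real_, nrow(unitMap))
  names(out) <- unitMap$unit
  for (i in seq_len(nrow(unitMap))) {
    if (unitMap$collision[i] || unitMap$snp[i]) next
    k <- unitMap$nCpG[i]
    I <- vapply(0:k, function(c0) {
      m <- unitMap$mass0[i] + shift * c0
      sum(spectrum$intensity[abs(spectrum$mass - m) <= tol])
    }, 0)
    if (sum(I) <= 0) {
      warning("no intensity for unit ", unitMap$unit[i])
      next
    }
    out[i] <- sum((0:k) * I) / (k * sum(I))
  }
  out
}

#' Call SNP alleles and allele-specific methylation from a spectrum
#'
#' The SNP changes the fragment set, so each allele produces diagnostic
#' peaks at allele-specific masses. An allele is called present when any
#' peak of its diagnostic fragment's series exceeds \code{floorFrac}
#' times the strongest peak in the spectrum; the methylation ratio of
#' each detected allele is estimated from its own series. Diagnostic
#' series overlapping other fragments' masses within \code{tol} yield a
#' low-confidence call.
#'
#' @param spectrum data.frame (\code{mass}, \code{intensity}).
#' @param design an \linkS4class{AssayDesign} with at least one SNP.
#' @param tol mass tolerance in Da.
#' @param floorFrac detection floor as a fraction of the maximum peak.
#' @return list with \code{genotype} (character vector of detected
#'   alleles, or \code{NA} for a no-call), \code{ratios} (named
#'   per-allele methylation), and \code{confidence} (\code{"ok"} or
#'   \code{"low"}).
#' @export
callSnpAlleles <- function(spectrum, design, tol = 0.5,
                           floorFrac = 0.05) {
  stopifnot(is(design, "AssayDesign"), nrow(design@snps) >= 1)
  snp <- design@snps[1, ]
  shift <- massCleaveMasses()$methylShift
  floor_abs <- floorFrac * max(spectrum$intensity)
  alleles <- c(snp$ref, snp$alt)
  digs <- lapply(alleles, function(a)
    digestAmplicon(design, allele = stats::setNames(a, snp$id)))
  names(digs) <- alleles
  n <- nchar(design@sequence)
  snp_t <- n - 1L - snp$pos
  diagnostic <- lapply(alleles, function(a) {
    fr <- digs[[a]]
    other <- digs[[setdiff(alleles, a)]]
    ends <- fr$start + nchar(fr$fragment)
    hit <- fr[snp_t >= fr$start & snp_t < ends, , drop = FALSE]
    # keep only fragments absent from the other allele's digest
    hit[!hit$fragment %in% other$fragment, , drop = FALSE]
  })
  names(diagnostic) <- alleles
  # all masses any fragment of either allele can produce, for collision
  all_series <- unlist(lapply(alleles, function(a) {
    fr <- digs[[a]]
    unlist(lapply(seq_len(nrow(fr)), function(i)
      fr$mass0[i] + shift * (0:fr$nCpG[i])))
  }))
  detected <- character()
  ratios <- numeric()
  confidence <- "ok"
  for (a in alleles) {
    d <- diagnostic[[a]]
    if (nrow(d) == 0L) next
    d <- d[which.max(d$nCpG), , drop = FALSE]   # most informative fragment
    k <- d$nCpG
    ser <- d$mass0 + shift * (0:k)
    # each mass occurs once in its own series; extra matches in the
    # combined fragment mass list mean another fragment's peak coincides
    for (m in ser)
      if (sum(abs(all_series - m) <= tol) > 1L) confidence <- "low"
    I <- vapply(ser, function(m)
      sum(spectrum$intensity[abs(spectrum$mass - m) <= tol]), 0)
    if (max(I) >= floor_abs) {
      detected <- c(detected, a)
      ratios[a] <- if (k > 0 && sum(I) > 0)
        sum((0:k) * I) / (k * sum(I)) else NA_real_
    }
  }
  if (!length(detected))
    return(list(genotype = NA_character_, ratios = numeric(),
                confidence = "no-call"))
  list(genotype = sort(detected), ratios = ratios,
       confidence = confidence)
}

#' Example H19-ICR-like assay design (synthetic)
#'
#' A synthetic amplicon built to exercise the SNP-dependent fragmentation
#' the real H19-ICR assay shows: the reference [G] allele leaves a
#' 4-CpG fragment (mass series spaced 16 Da, span 64 Da), while the [A]
#' allele introduces a novel cleavage site that splits it, leaving a
#' diagnostic SNP fragment carrying exactly one CpG. The sequence is
#' synthetic; it reproduces the assay's logic, not the genomic locus.
#'
#' @return An \linkS4class{AssayDesign} with one SNP (rs-like id
#'   \code{"snpAG"}, ref G / alt A).
#' @export
exampleH19Design <- function() {
  seq <- paste0("GGTTGGATTATTGGGTTTAG",   # fwd primer span
                "TTCGGTTCGTTTA",          # 2-CpG unit
                "TTCGTCGTCGTGTCGTT",      # SNP-bearing 4-CpG stretch
                "ATTCGTTTTCGGTTA",        # further units
                "TTGGTTAGGGTTGGTTGGAT")   # rev primer span
  snp_pos <- 20L + 13L + 11L              # the G of the SNP stretch
  assayDesign("H19-ICR", seq,
              fwdPrimer = c(0L, 20L),
              revPrimer = c(nchar(seq) - 20L, nchar(seq)),
              snps = data.frame(id = "snpAG", pos = snp_pos,
                                ref = "G", alt = "A",
                                stringsAsFactors = FALSE))
}
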