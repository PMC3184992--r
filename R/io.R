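#' Write / read a methylation table as TSV
#'
#' Rows are individuals, columns are \code{region:unit} ids, missing
#' entries are serialized as empty fields. The write/read round trip is
#' lossless, including the missingness mask.
#'
#' @param x a \linkS4class{MethylationSet} or individuals-by-units
#'   matrix.
#' @param file path.
#' @export
writeMethTable <- function(x, file) {
  mm <- .meth_matrix(x)
  df <- data.frame(individual = rownames(mm$m), mm$m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' @rdname writeMethTable
#' @return \code{readMethTable} returns a \linkS4class{MethylationSet}
#'   (observed assay only; region taken from the unit id prefix).
#' @export
readMethTable <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  if (colnames(df)[1] != "individual")
    stop("expected first column 'individual' (line 1)")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1, function(r)
      any(is.na(suppressWarnings(as.numeric(r))) & !is.na(r))))[1]
    stop("non-numeric methylation value at line ", bad + 1L)
  }
  rownames(m) <- df$individual
  MethylationSet(methylation = m)
}

#' Write / read a twin cohort as TSV
#'
#' @param cohort a \linkS4class{TwinCohort}.
#' @param file path.
#' @export
writeCohort <- function(cohort, file) {
  p <- pairTable(cohort)
  if (length(cohort@sex)) p$sex1 <- unname(cohort@sex[p$member1])
  if (length(cohort@sex)) p$sex2 <- unname(cohort@sex[p$member2])
  write.table(p, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeCohort
#' @export
readCohort <- function(file) {
  p <- read.delim(file, stringsAsFactors = FALSE)
  sex <- character()
  if (all(c("sex1", "sex2") %in% colnames(p))) {
    sex <- stats::setNames(as.character(rbind(p$sex1, p$sex2)),
                           as.character(rbind(p$member1, p$member2)))
    p$sex1 <- p$sex2 <- NULL
  }
  TwinCohort(p, sex = sex)
}

#' Write / read a genotype table as TSV
#'
#' Columns: individual, snp, maternal, paternal.
#' @param genotypes genotype data.frame.
#' @param file path.
#' @export
writeGenotypes <- function(genotypes, file) {
  write.table(genotypes, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(file) {
  read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
}

#' Read FASTA sequences
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} returning a
#' named character vector. Soft-masked (lowercase) bases are accepted
#' and uppercased; the result carries a \code{"softmasked"} attribute
#' flagging whether any were present.
#'
#' @param file FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
readFasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  # Biostrings uppercases on read; look at the raw lines for masking
  body <- readLines(file)
  body <- body[!startsWith(body, ">")]
  soft <- any(grepl("[acgtn]", body))
  out <- stats::setNames(toupper(as.character(ss)),
                         sub("\\s.*$", "", names(ss)))
  attr(out, "softmasked") <- soft
  out
}

#' Write sequences as FASTA
#' @param sequences named character vector.
#' @param file path.
#' @export
writeFasta <- function(sequences, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), file)
}

#' Read a bedGraph enrichment track
#'
#' Parses a bedGraph (chrom, start, end, score; 0-based half-open) into
#' per-sequence score vectors. Overlapping intervals are rejected with
#' the offending interval named; positions not covered score 0.
#'
#' @param file bedGraph path.
#' @param seqlengths optional named integer vector of sequence lengths
#'   (defaults to the maximum end per sequence).
#' @return named list of numeric vectors.
#' @export
readBedGraph <- function(file, seqlengths = NULL) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
    i <- which(GenomicRanges::countOverlaps(gr, gr) > 1L)[1]
    stop("overlapping bedGraph intervals at ",
         as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i] - 1L, "-",
         GenomicRanges::end(gr)[i])
  }
  seqs <- as.character(unique(GenomicRanges::seqnames(gr)))
  if (is.null(seqlengths))
    seqlengths <- vapply(seqs, function(s)
      max(GenomicRanges::end(gr[GenomicRanges::seqnames(gr) == s])), 0)
  track <- lapply(seqs, function(s) {
    v <- numeric(seqlengths[[s]])
    sub <- gr[GenomicRanges::seqnames(gr) == s]
    for (i in seq_along(sub)) {
      v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <-
        S4Vectors::mcols(sub)$score[i]
    }
    v
  })
  stats::setNames(track, seqs)
}

#' Write a track as bedGraph
#' @param track named list of numeric vectors.
#' @param file path.
#' @export
writeBedGraph <- function(track, file) {
  con <- file(file, "w"); on.exit(close(con))
  for (s in names(track)) {
    v <- track[[s]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", s, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(file)
}

#' Write motif hits as BED (0-based half-open, with strand)
#' @param hits hit table from \code{\link{scanPWM}}.
#' @param file path.
#' @export
writeBedHits <- function(hits, file) {
  df <- data.frame(hits$seqname, hits$start, hits$end,
                   name = sprintf("hit%04d", seq_len(nrow(hits))),
                   score = round(1000 * hits$match),
                   strand = hits$strand)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Write / read a spectrum as TSV (mass, intensity)
#' @param spectrum data.frame (\code{mass}, \code{intensity}).
#' @param file path.
#' @export
writeSpectrum <- function(spectrum, file) {
  write.table(spectrum, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(file) {
  sp <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("mass", "intensity") %in% colnames(sp)))
    stop("expected columns mass, intensity")
  sp
}

#' Write the assay report of a unit map
#'
#' TSV with one row per CpG unit: fragment, CpG site positions, the
#' mass series across methylation counts, and collision/SNP flags.
#'
#' @param unitMap a \code{CpGUnitMap}.
#' @param file path.
#' @export
writeUnitMap <- function(unitMap, file) {
  shift <- massCleaveMasses()$methylShift
  df <- data.frame(
    unit = unitMap$unit, nCpG = unitMap$nCpG,
    cpgSites = vapply(unitMap$cpgSites, paste, "", collapse = ","),
    masses = vapply(seq_len(nrow(unitMap)), function(i)
      paste(sprintf("%.2f", unitMap$mass0[i] +
                      shift * (0:unitMap$nCpG[i])), collapse = ","), ""),
    collision = unitMap$collision, snp = unitMap$snp,
    stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
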