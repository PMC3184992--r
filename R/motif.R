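#' Construct a position weight matrix
#'
#' Normalizes per-position base counts (or probabilities) to
#' probabilities with a pseudocount of \code{pseudo} times the column
#' total, and derives log2-odds scores against a uniform background
#' plus the achievable score bounds used for fractional matching.
#'
#' @param counts 4 x L numeric matrix with rownames A, C, G, T.
#' @param pseudo pseudocount as a fraction of the column total
#'   (default 0.01; avoids -Inf log-odds on zero counts).
#' @return list of class \code{"MotifPWM"}: \code{counts}, \code{probs},
#'   \code{logodds}, \code{minScore}, \code{maxScore}, \code{consensus}.
#' @export
motifPWM <- function(counts, pseudo = 0.01) {
  counts <- as.matrix(counts)
  if (!identical(rownames(counts), c("A", "C", "G", "T")))
    stop("counts must have rownames A, C, G, T")
  if (ncol(counts) < 1L) stop("PWM width must be at least 1")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative numbers")
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every position needs positive total weight")
  probs <- sweep(counts + rep(pseudo * tot, each = 4L), 2,
                 tot * (1 + 4 * pseudo), `/`)
  lo <- log2(probs / 0.25)
  structure(list(counts = counts, probs = probs, logodds = lo,
                 minScore = sum(apply(lo, 2, min)),
                 maxScore = sum(apply(lo, 2, max)),
                 consensus = paste(rownames(lo)[apply(lo, 2, which.max)],
                                   collapse = "")),
            class = "MotifPWM")
}

#' @export
print.MotifPWM <- function(x, ...) {
  cat("MotifPWM: width", ncol(x$counts), "consensus", x$consensus, "\n")
  invisible(x)
}

#' Read a JASPAR-format PWM
#'
#' Accepts the JASPAR plain-text layout: an optional \code{>} header
#' line and four rows, either bare numbers or
#' \code{A  [ 10  5 ... ]}.
#'
#' @param file path to the matrix file (or a character vector of its
#'   lines via \code{text}).
#' @param text optional character vector of lines instead of a file.
#' @param pseudo pseudocount fraction, see \code{\link{motifPWM}}.
#' @return A \code{"MotifPWM"}.
#' @export
readJaspar <- function(file, text = NULL, pseudo = 0.01) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- trimws(lines[nzchar(trimws(lines))])
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) != 4L)
    stop("expected four base rows, found ", length(lines))
  parse_row <- function(ln, i) {
    base <- NA_character_
    if (grepl("^[ACGT]\\b", ln)) {
      base <- substr(ln, 1, 1)
      ln <- sub("^[ACGT]", "", ln)
    }
    ln <- gsub("[][]", " ", ln)
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (any(is.na(v))) stop("non-numeric entry in PWM row ", i)
    list(base = base, v = v)
  }
  rows <- lapply(seq_len(4L), function(i) parse_row(lines[i], i))
  lens <- vapply(rows, function(r) length(r$v), 0L)
  if (length(unique(lens)) != 1L) stop("ragged PWM rows")
  m <- do.call(rbind, lapply(rows, `[[`, "v"))
  bases <- vapply(rows, `[[`, "", "base")
  rownames(m) <- if (all(!is.na(bases))) bases else c("A", "C", "G", "T")
  motifPWM(m[c("A", "C", "G", "T"), , drop = FALSE], pseudo = pseudo)
}

#' Write a PWM in JASPAR plain-text format
#'
#' @param pwm a \code{"MotifPWM"}.
#' @param file output path.
#' @param name header name.
#' @export
writeJaspar <- function(pwm, file, name = "motif") {
  rows <- vapply(c("A", "C", "G", "T"), function(b)
    sprintf("%s  [ %s ]", b,
            paste(format(pwm$counts[b, ], trim = TRUE), collapse = " ")),
    "")
  writeLines(c(paste0(">", name), rows), file)
}

#' Substitute one base for another at a PWM position
#'
#' Exchanges the weights of \code{from} and \code{to} at the given
#' position, so the dominant \code{from} base hands its weight to
#' \code{to} (e.g. replacing the cytosine at position 6 of the CTCF PWM
#' with a thymidine to model the variant binding site). Applying the
#' inverse substitution restores the original matrix.
#'
#' @param pwm a \code{"MotifPWM"}.
#' @param position 1-based position in \code{[1, L]}.
#' @param from,to single bases; \code{from} must have positive weight at
#'   the position.
#' @return The mutated \code{"MotifPWM"}.
#' @export
mutatePWM <- function(pwm, position, from, to) {
  stopifnot(inherits(pwm, "MotifPWM"))
  L <- ncol(pwm$counts)
  if (position < 1 || position > L) stop("position out of range [1, ", L, "]")
  cnt <- pwm$counts
  if (cnt[from, position] <= 0)
    stop("base ", from, " has no weight at position ", position)
  w <- cnt[from, position]
  cnt[from, position] <- cnt[to, position]
  cnt[to, position] <- w
  motifPWM(cnt, pseudo = attr(pwm, "pseudo") %||% 0.01)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

# fractional match scores of every window of one sequence (plus strand
# as given); ambiguous bases score log-odds 0 (background)
.window_scores <- function(seq, pwm) {
  L <- ncol(pwm$logodds)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < L) return(numeric())
  idx <- .BASE_IDX[ch]                      # NA for N and friends
  sc <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    col <- pwm$logodds[, j]
    v <- col[idx[j:(j + n - L)]]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  rng <- pwm$maxScore - pwm$minScore
  # a flat matrix cannot discriminate: every window is a full match
  if (rng <= 0) return(rep(1, length(sc)))
  (sc - pwm$minScore) / rng
}

#' Scan sequences for PWM matches
#'
#' Scores every window of every sequence on both strands and reports
#' hits whose fractional match \code{s = (score - min) / (max - min)}
#' reaches \code{minMatch} (default 0.80, i.e. at least an 80% sequence
#' match to the PWM). An alternative \code{mode = "consensus"} counts
#' the fraction of positions equal to the consensus base instead.
#'
#' @param sequences named character vector of DNA sequences, or a
#'   \code{Biostrings::DNAStringSet}.
#' @param pwm a \code{"MotifPWM"}.
#' @param minMatch match threshold in \code{(0, 1]}.
#' @param mode \code{"score"} (fractional PWM score) or
#'   \code{"consensus"} (base-identity fraction).
#' @return data.frame of hits in coordinate order: \code{seqname},
#'   \code{start} (0-based), \code{end} (half-open), \code{strand},
#'   \code{match}.
#' @export
scanPWM <- function(sequences, pwm, minMatch = 0.80,
                    mode = c("score", "consensus")) {
  mode <- match.arg(mode)
  if (minMatch <= 0 || minMatch > 1) stop("minMatch must lie in (0, 1]")
  if (is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  sequences <- toupper(sequences)
  L <- ncol(pwm$logodds)
  score_fun <- if (mode == "score") function(s) .window_scores(s, pwm)
  else function(s) {
    ch <- strsplit(s, "")[[1]]
    cons <- strsplit(pwm$consensus, "")[[1]]
    n <- length(ch)
    if (n < L) return(numeric())
    sc <- numeric(n - L + 1L)
    for (j in seq_len(L))
      sc <- sc + (ch[j:(j + n - L)] == cons[j])
    sc / L
  }
  hits <- list()
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    n <- nchar(s)
    fw <- score_fun(s)
    rv <- score_fun(.revcomp(s))
    h <- list()
    if (length(fw)) {
      i <- which(fw >= minMatch)
      if (length(i)) h$fw <- data.frame(seqname = nm, start = i - 1L,
                                        strand = "+", match = fw[i])
    }
    if (length(rv)) {
      i <- which(rv >= minMatch)
      # window i (1-based) on the reverse complement maps to plus-strand
      # start n - (i - 1) - L
      if (length(i)) h$rv <- data.frame(seqname = nm,
                                        start = n - (i - 1L) - L,
                                        strand = "-", match = rv[i])
    }
    if (length(h)) hits[[nm]] <- do.call(rbind, h)
  }
  if (!length(hits))
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      match = numeric()))
  out <- do.call(rbind, hits)
  out$end <- out$start + L
  out <- out[order(out$seqname, out$start, out$strand), ]
  rownames(out) <- NULL
  out[, c("seqname", "start", "end", "strand", "match")]
}

#' Mean enrichment meta-profile around motif hits
#'
#' Averages an enrichment track over windows centred on each hit's
#' motif midpoint, from \code{-flank} to \code{+flank} bp. Minus-strand
#' hits are reversed before averaging so profile coordinates are
#' orientation-consistent; positions outside the track are treated as 0.
#'
#' @param hits hit table from \code{\link{scanPWM}}.
#' @param track named list of non-negative numeric vectors (per-position
#'   scores per sequence), e.g. from \code{\link{readBedGraph}}.
#' @param flank half-window in bp (default 500).
#' @return list of class \code{"MetaProfile"}: \code{profile} (named
#'   numeric, offsets -flank..flank), \code{mean} (overall mean
#'   enrichment), \code{nHits}, \code{flank}.
#' @export
metaProfile <- function(hits, track, flank = 500L) {
  if (!nrow(hits)) {
    warning("no hits; empty profile")
    return(structure(list(profile = numeric(), mean = NA_real_,
                          nHits = 0L, flank = flank),
                     class = "MetaProfile"))
  }
  offs <- -flank:flank
  acc <- numeric(length(offs))
  L <- hits$end[1] - hits$start[1]
  mid <- hits$start + L %/% 2L               # 0-based anchor
  for (i in seq_len(nrow(hits))) {
    tv <- track[[hits$seqname[i]]]
    if (is.null(tv)) tv <- numeric()
    pos <- if (hits$strand[i] == "-") mid[i] - offs else mid[i] + offs
    v <- numeric(length(pos))
    ok <- pos >= 0 & pos < length(tv)
    v[ok] <- tv[pos[ok] + 1L]
    acc <- acc + v
  }
  prof <- acc / nrow(hits)
  names(prof) <- offs
  structure(list(profile = prof, mean = mean(prof), nHits = nrow(hits),
                 flank = flank),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat("MetaProfile:", x$nHits, "hits, flank", x$flank,
      sprintf("bp, mean enrichment %.3f\n", x$mean))
  invisible(x)
}

#' Compare two meta-profiles over a central window
#'
#' Reports each profile's mean over \code{[-window, +window]} and their
#' ratio. The comparison is meaningful within one track (one sample),
#' where read-depth normalization cancels.
#'
#' @param a,b \code{"MetaProfile"} objects with equal flank.
#' @param window central half-window in bp (default 100).
#' @return list with \code{meanA}, \code{meanB}, \code{ratio} (A / B).
#' @export
compareProfiles <- function(a, b, window = 100L) {
  stopifnot(inherits(a, "MetaProfile"), inherits(b, "MetaProfile"))
  if (a$flank != b$flank || length(a$profile) != length(b$profile))
    stop("profiles have mismatched flanks")
  sel <- abs(as.integer(names(a$profile))) <= window
  ma <- mean(a$profile[sel]); mb <- mean(b$profile[sel])
  list(meanA = ma, meanB = mb, ratio = ma / mb)
}
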