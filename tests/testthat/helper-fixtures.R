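# small builders shared across test files

tiny_cohort <- function(nMZ = 4, nDZ = 4, seed = 101) {
  simulatePedigree(nMZ, nDZ, seed = seed)
}

# a flat-baseline one-region methylation matrix (individuals x units)
flat_meth <- function(n_ind = 8, n_unit = 4, value = 0.5,
                      prefix = "R") {
  m <- matrix(value, n_ind, n_unit,
              dimnames = list(sprintf("i%02d", seq_len(n_ind)),
                              sprintf("%s:u%02d", prefix,
                                      seq_len(n_unit))))
  m
}

# independent brute-force T-cleavage oracle: walk the converted plus
# strand via Biostrings reverseComplement and cut with substring scans
oracle_digest <- function(sequence, methylated = integer()) {
  conv <- twinmeth::bisulfiteConvert(sequence, methylated)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(conv)))
  tr <- chartr("T", "U", rc)
  frags <- character()
  cur <- ""
  for (i in seq_len(nchar(tr))) {
    ch <- substr(tr, i, i)
    cur <- paste0(cur, ch)
    if (ch == "U") { frags <- c(frags, cur); cur <- "" }
  }
  if (nzchar(cur)) frags <- c(frags, cur)
  frags
}

# brute-force Spearman: rank (average ties) then Pearson on shared rows
oracle_spearman <- function(m) {
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) >= 3)
      out[i, j] <- cor(rank(m[ok, i]), rank(m[ok, j]))
    if (i == j && sum(ok) > 0) out[i, j] <- 1
  }
  out
}

# exhaustive PWM window scan oracle (both strands, fractional score)
oracle_scan <- function(seqs, pwm, minMatch) {
  L <- ncol(pwm$logodds)
  score1 <- function(w) {
    ch <- strsplit(w, "")[[1]]
    s <- 0
    for (j in seq_len(L)) {
      v <- pwm$logodds[ch[j], j]
      s <- s + if (ch[j] %in% c("A", "C", "G", "T")) v else 0
    }
    (s - pwm$minScore) / (pwm$maxScore - pwm$minScore)
  }
  rc1 <- function(w) paste(rev(strsplit(chartr("ACGTN", "TGCAN", w),
                                        "")[[1]]), collapse = "")
  res <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    for (st in 0:(n - L)) {
      w <- substr(s, st + 1, st + L)
      fs <- score1(w)
      if (fs >= minMatch)
        res[[length(res) + 1]] <- data.frame(
          seqname = nm, start = st, strand = "+", match = fs)
      rs <- score1(rc1(w))
      if (rs >= minMatch)
        res[[length(res) + 1]] <- data.frame(
          seqname = nm, start = st, strand = "-", match = rs)
    }
  }
  if (!length(res)) return(data.frame(seqname = character(),
                                      start = integer(),
                                      strand = character(),
                                      match = numeric()))
  out <- do.call(rbind, res)
  out[order(out$seqname, out$start, out$strand), ]
}
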