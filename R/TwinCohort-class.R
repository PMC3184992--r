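#' TwinCohort: twin pairs with zygosity and family structure
#'
#' An S4 container for a twin cohort. Each pair has a zygosity label
#' (\code{"MZ"} or \code{"DZ"}), two member identifiers and a family
#' identifier shared by the co-twins. Every individual belongs to exactly
#' one pair.
#'
#' @slot pairs data.frame with columns \code{pair_id}, \code{zygosity},
#'   \code{member1}, \code{member2}, \code{family_id}.
#' @slot sex named character vector (\code{"F"}/\code{"M"}), one entry per
#'   individual; may be empty.
#'
#' @seealso \code{\link{simulatePedigree}}
#' @exportClass TwinCohort
setClass("TwinCohort",
  representation(pairs = "data.frame", sex = "character"),
  prototype(
    pairs = data.frame(pair_id = character(), zygosity = character(),
                       member1 = character(), member2 = character(),
                       family_id = character(), stringsAsFactors = FALSE),
    sex = character()
  )
)

setValidity("TwinCohort", function(object) {
  p <- object@pairs
  need <- c("pair_id", "zygosity", "member1", "member2", "family_id")
  if (!all(need %in% colnames(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) == 0L) return(TRUE)
  if (!all(p$zygosity %in% c("MZ", "DZ")))
    return("zygosity labels must be 'MZ' or 'DZ'")
  ind <- c(p$member1, p$member2)
  if (anyDuplicated(ind))
    return("an individual may belong to only one pair")
  if (anyDuplicated(p$pair_id))
    return("pair ids must be unique")
  if (length(object@sex) && !all(names(object@sex) %in% ind))
    return("sex labels refer to unknown individuals")
  TRUE
})

#' Construct a TwinCohort
#'
#' @param pairs data.frame with columns \code{pair_id}, \code{zygosity},
#'   \code{member1}, \code{member2}, \code{family_id}.
#' @param sex optional named character vector of sex labels per individual.
#' @return A \linkS4class{TwinCohort}.
#' @export
TwinCohort <- function(pairs, sex = character()) {
  pairs[] <- lapply(pairs, as.character)
  new("TwinCohort", pairs = as.data.frame(pairs, stringsAsFactors = FALSE),
      sex = sex)
}

#' @describeIn TwinCohort-class individual identifiers (members of all
#'   pairs, pair-major order)
#' @param x,object a \code{TwinCohort}
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname TwinCohort-class
#' @export
setMethod("individuals", "TwinCohort", function(x) {
  p <- x@pairs
  as.character(rbind(p$member1, p$member2))
})

#' @describeIn TwinCohort-class the pair table
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname TwinCohort-class
#' @export
setMethod("pairTable", "TwinCohort", function(x) x@pairs)

#' @describeIn TwinCohort-class number of pairs
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname TwinCohort-class
#' @export
setMethod("nPairs", "TwinCohort", function(x) nrow(x@pairs))

#' @rdname TwinCohort-class
#' @export
setMethod("show", "TwinCohort", function(object) {
  p <- object@pairs
  cat("TwinCohort:", nrow(p), "pairs (",
      sum(p$zygosity == "MZ"), "MZ,", sum(p$zygosity == "DZ"), "DZ ),",
      2L * nrow(p), "individuals\n")
})

#' Simulate a twin pedigree
#'
#' Generates a cohort of \code{nMZ} monozygotic and \code{nDZ} dizygotic
#' twin pairs with unique family identifiers (one nuclear family per
#' pair). Sex is assigned at random; MZ co-twins always share sex, DZ
#' co-twins are sampled independently, so opposite-sex DZ pairs occur.
#'
#' @param nMZ,nDZ non-negative pair counts.
#' @param seed optional integer seed; a fixed seed gives a reproducible
#'   cohort.
#' @return A \linkS4class{TwinCohort} with \code{2 * (nMZ + nDZ)}
#'   individuals.
#' @examples
#' simulatePedigree(128, 128, seed = 1)
#' @export
simulatePedigree <- function(nMZ, nDZ, seed = NULL) {
  stopifnot(length(nMZ) == 1L, length(nDZ) == 1L)
  if (nMZ < 0 || nDZ < 0) stop("pair counts must be non-negative")
  nMZ <- as.integer(nMZ); nDZ <- as.integer(nDZ)
  n <- nMZ + nDZ
  if (n == 0L) return(TwinCohort(data.frame(
    pair_id = character(), zygosity = character(), member1 = character(),
    member2 = character(), family_id = character())))
  zyg <- rep(c("MZ", "DZ"), c(nMZ, nDZ))
  fam <- sprintf("fam%04d", seq_len(n))
  pid <- sprintf("%s%04d", zyg, c(seq_len(nMZ), seq_len(nDZ)))
  m1 <- paste0(pid, "-1"); m2 <- paste0(pid, "-2")
  sex <- .with_seed(seed, {
    s1 <- sample(c("F", "M"), n, replace = TRUE)
    s2 <- ifelse(zyg == "MZ", s1, sample(c("F", "M"), n, replace = TRUE))
    stats::setNames(as.character(rbind(s1, s2)), as.character(rbind(m1, m2)))
  })
  TwinCohort(data.frame(pair_id = pid, zygosity = zyg, member1 = m1,
                        member2 = m2, family_id = fam,
                        stringsAsFactors = FALSE),
             sex = sex)
}
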