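#' MethylationSet: CpG-unit methylation with optional allele resolution
#'
#' A \linkS4class{SummarizedExperiment} subclass holding CpG-unit
#' methylation fractions. Rows are CpG units (with a \code{region} column
#' in \code{rowData}), columns are individuals. The \code{"methylation"}
#' assay holds observed (allele-averaged) levels in \code{[0, 1]}; when
#' the table is allele-resolved, \code{"maternal"} and \code{"paternal"}
#' assays hold the per-parental-allele levels and the observed level is
#' their mean wherever both are present. Cohort structure (pair,
#' zygosity, family) lives in \code{colData}.
#'
#' @seealso \code{\link{simulateMethylation}}, \code{\link{filterUnits}}
#' @exportClass MethylationSet
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!"methylation" %in% names(a))
    return("a 'methylation' assay is required")
  if (!"region" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain a 'region' column")
  for (nm in intersect(c("methylation", "maternal", "paternal"), names(a))) {
    v <- a[[nm]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      return(sprintf("assay '%s' has values outside [0, 1]", nm))
  }
  if (all(c("maternal", "paternal") %in% names(a))) {
    both <- !is.na(a$maternal) & !is.na(a$paternal) & !is.na(a$methylation)
    if (any(abs(a$methylation[both] -
                (a$maternal[both] + a$paternal[both]) / 2) > 1e-6))
      return("observed methylation must equal the allele mean")
  }
  TRUE
})

#' Construct a MethylationSet
#'
#' @param methylation numeric matrix of observed methylation fractions,
#'   individuals in rows and CpG units in columns (the orientation of the
#'   on-disk table); transposed internally to the units-by-individuals
#'   SummarizedExperiment layout. If \code{NULL} it is computed as the
#'   allele mean.
#' @param region character vector mapping each unit (column) to a region;
#'   defaults to the prefix of the unit id before \code{":"}.
#' @param maternal,paternal optional allele-level matrices with the same
#'   orientation and dimnames as \code{methylation}.
#' @param colData optional per-individual annotation (e.g. pair,
#'   zygosity, family_id).
#' @param metadata optional list stored in the object metadata.
#' @return A \linkS4class{MethylationSet}.
#' @export
MethylationSet <- function(methylation = NULL, region = NULL,
                           maternal = NULL, paternal = NULL,
                           colData = NULL, metadata = list()) {
  if (is.null(methylation)) {
    if (is.null(maternal) || is.null(paternal))
      stop("supply 'methylation' or both allele matrices")
    methylation <- (maternal + paternal) / 2
  }
  methylation <- as.matrix(methylation)
  units <- colnames(methylation)
  if (is.null(units)) stop("unit (column) names are required")
  if (is.null(region)) region <- sub(":.*$", "", units)
  assays <- list(methylation = t(methylation))
  if (!is.null(maternal)) assays$maternal <- t(as.matrix(maternal))
  if (!is.null(paternal)) assays$paternal <- t(as.matrix(paternal))
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = rownames(methylation))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(region = region, row.names = units),
    colData = colData, metadata = metadata)
  new("MethylationSet", se)
}

#' @describeIn MethylationSet-class observed methylation as an
#'   individuals-by-units matrix (the analysis orientation)
#' @param x,object a \code{MethylationSet}
#' @export
setGeneric("methLevels", function(x) standardGeneric("methLevels"))

#' @rdname MethylationSet-class
#' @export
setMethod("methLevels", "MethylationSet", function(x)
  t(SummarizedExperiment::assay(x, "methylation")))

#' @describeIn MethylationSet-class allele-level matrix
#'   (individuals-by-units)
#' @param allele \code{"maternal"} or \code{"paternal"}
#' @export
setGeneric("alleleLevels", function(x, allele) standardGeneric("alleleLevels"))

#' @rdname MethylationSet-class
#' @export
setMethod("alleleLevels", "MethylationSet", function(x, allele) {
  allele <- match.arg(allele, c("maternal", "paternal"))
  if (!allele %in% SummarizedExperiment::assayNames(x))
    stop("this MethylationSet is not allele-resolved")
  t(SummarizedExperiment::assay(x, allele))
})

#' @describeIn MethylationSet-class region of each CpG unit (named
#'   character)
#' @export
setGeneric("unitRegions", function(x) standardGeneric("unitRegions"))

#' @rdname MethylationSet-class
#' @export
setMethod("unitRegions", "MethylationSet", function(x)
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$region),
                  rownames(x)))

#' @rdname MethylationSet-class
#' @export
setMethod("show", "MethylationSet", function(object) {
  cat("MethylationSet:", nrow(object), "CpG units x", ncol(object),
      "individuals\n")
  reg <- table(SummarizedExperiment::rowData(object)$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(reg), reg),
                          collapse = ", "), "\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  miss <- mean(is.na(SummarizedExperiment::assay(object, "methylation")))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
})

# internal: accept a MethylationSet or a plain individuals x units matrix
# and return list(m = matrix, region = named character)
.meth_matrix <- function(x) {
  if (is(x, "MethylationSet"))
    list(m = methLevels(x), region = unitRegions(x))
  else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) stop("unit column names are required")
    list(m = m, region = stats::setNames(sub(":.*$", "", colnames(m)),
                                         colnames(m)))
  }
}
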