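#' @import methods
#' @importFrom Rcpp evalCpp
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowRanges
#' @useDynLib DivergeScan, .registration = TRUE
NULL

#' GenotypeData: diploid SNP dosages with variant and sample annotation
#'
#' An S4 container for diploid biallelic SNP genotypes, extending
#' \linkS4class{RangedSummarizedExperiment}. The single assay, \code{"dosage"},
#' is a variants-by-samples integer matrix counting ALT alleles (0, 1, 2, or
#' \code{NA} for missing). Row ranges carry the 1-based variant coordinates
#' plus \code{ref}, \code{alt} and \code{depth} (per-variant mean read depth)
#' metadata columns; column data carry the sample sheet (population, region,
#' habitat, latitude, longitude, altitude).
#'
#' Variants must be sorted by position within each chromosome; all standard
#' \code{[} subsetting from SummarizedExperiment applies and preserves the
#' class.
#'
#' @seealso [makeGenotypeData()], [readGenotypeVcf()], [applyFilters()]
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    byc <- split(GenomicRanges::start(rr),
                 as.character(GenomicRanges::seqnames(rr)))
    if (!all(vapply(byc, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "variant positions must be strictly increasing within chromosome")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("population", "region", "habitat")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosages integer matrix, variants x samples, ALT-allele counts with
#'   NA for missing genotypes.
#' @param variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   and optionally \code{ref}, \code{alt}, \code{depth}.
#' @param samples data.frame with columns \code{sample_id}, \code{population},
#'   \code{region}, \code{habitat} and optionally \code{latitude},
#'   \code{longitude}, \code{altitude}. Region/habitat are filled from the
#'   population code when absent (prefix "A" = mainland, "B" = island;
#'   trailing "D" = deciduous, "E" = evergreen).
#' @return a [GenotypeData-class] object.
#' @export
makeGenotypeData <- function(dosages, variants, samples) {
  stopifnot(is.matrix(dosages), nrow(dosages) == nrow(variants),
            ncol(dosages) == nrow(samples))
  samples <- completeSampleMeta(samples)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  dosages <- dosages[o, , drop = FALSE]
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "T"
  if (is.null(variants$depth)) variants$depth <- NA_real_
  rr <- GRanges(variants$chrom, IRanges(variants$pos, width = 1L),
                ref = variants$ref, alt = variants$alt, depth = variants$depth)
  names(rr) <- paste(variants$chrom, variants$pos, sep = ":")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(names(rr), samples$sample_id)
  cd <- DataFrame(samples, row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(dosage = dosages),
                             rowRanges = rr, colData = cd)
  new("GenotypeData", se)
}

# Fill region/habitat from the population naming convention when missing.
completeSampleMeta <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample_id", "population") %in% colnames(samples)))
  if (is.null(samples$region) || anyNA(samples$region)) {
    pref <- substr(samples$population, 1, 1)
    reg <- ifelse(pref == "A", "mainland", ifelse(pref == "B", "island", NA))
    if (is.null(samples$region)) samples$region <- reg
    else samples$region[is.na(samples$region)] <- reg[is.na(samples$region)]
  }
  if (is.null(samples$habitat) || anyNA(samples$habitat)) {
    suf <- substr(samples$population, nchar(samples$population),
                  nchar(samples$population))
    hab <- ifelse(suf == "D", "deciduous", ifelse(suf == "E", "evergreen", NA))
    if (is.null(samples$habitat)) samples$habitat <- hab
    else samples$habitat[is.na(samples$habitat)] <- hab[is.na(samples$habitat)]
  }
  for (col in c("latitude", "longitude", "altitude"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_real_
  samples
}

#' @describeIn makeGenotypeData dosage matrix accessor (variants x samples)
#' @param x a GenotypeData object
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn makeGenotypeData sample sheet as a data.frame
#' @export
sampleMeta <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn makeGenotypeData variant table (chrom, pos, ref, alt, depth)
#' @export
variantTable <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = rr$ref, alt = rr$alt, depth = rr$depth,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn makeGenotypeData population label per sample
#' @export
populations <- function(x) SummarizedExperiment::colData(x)$population

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  populations:", paste(sort(unique(cd$population)), collapse = " "), "\n")
  cat("  chromosomes:",
      paste(unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object)))), collapse = " "), "\n")
  mr <- mean(is.na(SummarizedExperiment::assay(object, "dosage")))
  cat(sprintf("  missing rate: %.3f\n", mr))
})
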