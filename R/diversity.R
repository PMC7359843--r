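#' Observed heterozygosity and polymorphism per group
#'
#' Ho is the fraction of heterozygous calls among non-missing genotypes in a
#' group, pooled over variants. Polymorphism is reported both as the count of
#' variants segregating in the group and as the count with within-group minor
#' allele frequency above 0.05.
#'
#' @param g a [GenotypeData-class] object.
#' @param by grouping vector per sample (default population).
#' @return data.frame: group, n_samples, ho, n_polymorphic, n_maf05,
#'   prop_polymorphic.
#' @export
observedHet <- function(g, by = populations(g)) {
  by <- as.character(by)
  d <- dosages(g)
  rows <- lapply(sort(unique(by)), function(grp) {
    dg <- d[, by == grp, drop = FALSE]
    nm <- sum(!is.na(dg))
    ho <- if (nm > 0) sum(dg == 1L, na.rm = TRUE) / nm else NA_real_
    n <- rowSums(!is.na(dg)); s <- rowSums(dg, na.rm = TRUE)
    poly <- n > 0 & s > 0 & s < 2 * n
    af <- ifelse(n > 0, s / (2 * n), NA)
    maf <- pmin(af, 1 - af)
    data.frame(group = grp, n_samples = ncol(dg), ho = ho,
               n_polymorphic = sum(poly),
               n_maf05 = sum(maf > 0.05, na.rm = TRUE),
               prop_polymorphic = mean(poly), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Minor-allele-frequency spectrum per group
#'
#' @param g a [GenotypeData-class] object.
#' @param by grouping vector per sample (default population).
#' @param breaks histogram breaks on \[0, 0.5\].
#' @return data.frame: group, bin_low, bin_high, count.
#' @export
mafSpectrum <- function(g, by = populations(g), breaks = seq(0, 0.5, by = 0.05)) {
  by <- as.character(by)
  d <- dosages(g)
  rows <- lapply(sort(unique(by)), function(grp) {
    dg <- d[, by == grp, drop = FALSE]
    n <- rowSums(!is.na(dg)); s <- rowSums(dg, na.rm = TRUE)
    af <- s / (2 * n)
    maf <- pmin(af, 1 - af)[n > 0]
    h <- graphics::hist(maf, breaks = breaks, plot = FALSE)
    data.frame(group = grp, bin_low = utils::head(h$breaks, -1),
               bin_high = utils::tail(h$breaks, -1), count = h$counts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Realized genomic relationship matrix
#'
#' VanRaden-type GRM: dosages centered at twice the allele frequency, missing
#' values mean-imputed, cross-product scaled by \eqn{\sum 2 p (1 - p)} over
#' the variants used. Monomorphic variants are excluded automatically.
#' Self-relatedness is approximately \eqn{1 + F}; the matrix is symmetric.
#'
#' @param g a [GenotypeData-class] object (ideally MAF-filtered).
#' @return symmetric n x n numeric matrix with sample ids as dimnames.
#' @export
relatednessMatrix <- function(g) {
  d <- dosages(g)
  n <- rowSums(!is.na(d)); s <- rowSums(d, na.rm = TRUE)
  p <- s / (2 * pmax(n, 1L))
  keep <- n > 0 & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic variants for relatedness")
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  z <- d - 2 * p
  z[is.na(z)] <- 0
  den <- sum(2 * p * (1 - p))
  grm <- crossprod(z) / den
  dimnames(grm) <- list(colnames(d), colnames(d))
  grm
}
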