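#' Per-SNP Weir-Cockerham variance components
#'
#' Computes the Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) for every SNP, from diploid dosages, for two or more groups.
#' The per-SNP estimate is \eqn{a / (a + b + c)}; components are returned so
#' that windowed and genome-wide estimates can be formed as ratios of sums.
#'
#' A SNP needs at least two groups with at least two genotyped diploids each;
#' otherwise its components are \code{NA}. Groups with fewer than two
#' genotyped individuals at a SNP are excluded from that SNP's estimate.
#'
#' @param g a [GenotypeData-class] object.
#' @param grouping factor/character of length \code{ncol(g)} (defaults to the
#'   population column); must contain at least two groups.
#' @return data.frame with columns chrom, pos, a, b, c, denom, fst.
#' @export
wcFstPerSnp <- function(g, grouping = populations(g)) {
  grouping <- as.factor(as.character(grouping))
  if (nlevels(grouping) < 2L)
    stop("grouping must define at least two groups")
  d <- dosages(g)
  vt <- variantTable(g)
  comp <- wcComponents(d, grouping)
  data.frame(chrom = vt$chrom, pos = vt$pos,
             a = comp$a, b = comp$b, c = comp$c,
             denom = comp$a + comp$b + comp$c,
             fst = ifelse(comp$a + comp$b + comp$c != 0,
                          comp$a / (comp$a + comp$b + comp$c), NA_real_),
             stringsAsFactors = FALSE)
}

# Vectorized WC84 components from a variants x samples dosage matrix.
wcComponents <- function(d, grouping) {
  levs <- levels(grouping)
  nv <- nrow(d)
  n <- p <- h <- matrix(0, nv, length(levs))
  for (j in seq_along(levs)) {
    dj <- d[, grouping == levs[j], drop = FALSE]
    nj <- rowSums(!is.na(dj))
    n[, j] <- nj
    p[, j] <- ifelse(nj > 0, rowSums(dj, na.rm = TRUE) / (2 * nj), 0)
    h[, j] <- ifelse(nj > 0, rowSums(dj == 1L, na.rm = TRUE) / pmax(nj, 1), 0)
  }
  # drop groups with < 2 genotyped diploids at a SNP
  use <- n >= 2
  n[!use] <- 0; p[!use] <- 0; h[!use] <- 0
  r <- rowSums(use)
  ok <- r >= 2
  nsum <- rowSums(n)
  nbar <- nsum / r
  nc <- (nsum - rowSums(n^2) / nsum) / (r - 1)
  pbar <- rowSums(n * p) / nsum
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / nsum
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; c[!ok] <- NA_real_
  list(a = a, b = b, c = c)
}

#' Pairwise FST between populations with locus bootstrap
#'
#' Genome-wide Weir-Cockerham FST for every population pair as the ratio of
#' summed variance components over loci, overall and split by chromosome
#' class (autosome vs Z when a class map is given). Significance of
#' \eqn{F_{ST} > 0} comes from bootstrap resampling of loci: the reported
#' p-value is the fraction of bootstrap replicates with FST <= 0.
#'
#' @param g a [GenotypeData-class] object.
#' @param n_boot number of locus bootstrap replicates (default 1000).
#' @param chrom_classes optional named character vector mapping chromosome to
#'   class ("autosome" or "Z"); when given, per-class FST and the Z/autosome
#'   ratio are reported, and a class with no SNPs yields \code{NA}.
#' @return data.frame with one row per pair: pop1, pop2, fst_all, p_boot,
#'   and (with a class map) fst_autosome, fst_Z, fst_z_auto_ratio.
#' @export
pairwiseFst <- function(g, n_boot = 1000, chrom_classes = NULL) {
  pops <- sort(unique(as.character(populations(g))))
  if (length(pops) < 2L) stop("need at least two populations")
  d <- dosages(g)
  vt <- variantTable(g)
  cls <- if (!is.null(chrom_classes)) unname(chrom_classes[vt$chrom]) else NULL
  rows <- list()
  for (i in seq_len(length(pops) - 1L)) for (j in seq(i + 1L, length(pops))) {
    sel <- populations(g) %in% c(pops[i], pops[j])
    comp <- wcComponents(d[, sel, drop = FALSE],
                         droplevels(factor(populations(g)[sel])))
    a <- comp$a; den <- comp$a + comp$b + comp$c
    okv <- !is.na(a)
    ros <- function(ix) {
      if (!length(ix)) return(NA_real_)
      s <- sum(den[ix]); if (s == 0) NA_real_ else sum(a[ix]) / s
    }
    all_ix <- which(okv)
    fst_all <- ros(all_ix)
    boots <- replicate(n_boot, ros(sample(all_ix, replace = TRUE)))
    p_boot <- mean(boots <= 0, na.rm = TRUE)
    row <- data.frame(pop1 = pops[i], pop2 = pops[j], fst_all = fst_all,
                      p_boot = p_boot, stringsAsFactors = FALSE)
    if (!is.null(cls)) {
      fa <- ros(which(okv & cls == "autosome"))
      fz <- ros(which(okv & cls == "Z"))
      row$fst_autosome <- fa; row$fst_Z <- fz
      row$fst_z_auto_ratio <- if (!is.na(fa) && !is.na(fz) && fa != 0)
        fz / fa else NA_real_
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Windowed FST genome scan
#'
#' Aggregates per-SNP Weir-Cockerham components into windows as a ratio of
#' sums, either in physical windows (default 200 kb, non-overlapping) or in
#' SNP blocks (default 50 SNPs stepping by 5). Windows containing no SNP are
#' omitted; windows in the top 1\% of the window FST distribution are flagged
#' as outliers. Reported bounds are 1-based inclusive.
#'
#' @param components per-SNP component table from [wcFstPerSnp()]; variants
#'   must be position-sorted within chromosome (an error otherwise).
#' @param mode "kb" or "snp".
#' @param window_bp,step_bp physical window and step (mode "kb").
#' @param block_snps,step_snps block size and step in SNPs (mode "snp").
#' @param outlier_quantile windows above this quantile are flagged.
#' @return data.frame: chrom, start, end, n_snps, fst, outlier.
#' @export
windowFst <- function(components, mode = c("kb", "snp"),
                      window_bp = 200000, step_bp = window_bp,
                      block_snps = 50, step_snps = 5,
                      outlier_quantile = 0.99) {
  mode <- match.arg(mode)
  sp <- split(components, components$chrom)
  out <- list()
  for (chrom in names(sp)) {
    x <- sp[[chrom]]
    if (is.unsorted(x$pos, strictly = TRUE))
      stop("variants not sorted by position on ", chrom)
    ok <- !is.na(x$a)
    if (mode == "kb") {
      last <- max(x$pos)
      starts <- seq(1, last, by = step_bp)
      for (s in starts) {
        e <- s + window_bp - 1
        ix <- which(x$pos >= s & x$pos <= e & ok)
        if (!length(ix)) next
        den <- sum(x$denom[ix])
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = s, end = e, n_snps = length(ix),
          fst = if (den != 0) sum(x$a[ix]) / den else NA_real_,
          stringsAsFactors = FALSE)
      }
    } else {
      nv <- nrow(x)
      starts <- if (nv <= block_snps) 1L else seq(1L, nv - block_snps + 1L,
                                                  by = step_snps)
      for (s in starts) {
        e <- min(s + block_snps - 1L, nv)
        ix <- seq(s, e); ix <- ix[ok[ix]]
        if (!length(ix)) next
        den <- sum(x$denom[ix])
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = x$pos[s], end = x$pos[e], n_snps = length(ix),
          fst = if (den != 0) sum(x$a[ix]) / den else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), n_snps = integer(),
                                      fst = numeric(), outlier = logical()))
  res <- res[order(res$chrom, res$start), ]
  thr <- stats::quantile(res$fst, outlier_quantile, na.rm = TRUE)
  res$outlier <- !is.na(res$fst) & res$fst > thr
  rownames(res) <- NULL
  res
}
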