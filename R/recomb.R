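#' Read a recombination-rate track
#'
#' BED-like TSV: chrom, start (0-based), end, rho, where rho is the
#' population-scaled recombination rate 4*Ne*r per bp. Intervals must be
#' non-overlapping within chromosome and rho non-negative.
#'
#' @param path file path.
#' @return data.frame: chrom, start (1-based), end, rho.
#' @export
readRecombinationTrack <- function(path) {
  tr <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "rho"),
                          stringsAsFactors = FALSE)
  tr$start <- tr$start + 1L
  validateRecombinationTrack(tr)
  tr
}

validateRecombinationTrack <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "rho") %in% colnames(track)))
  if (any(track$rho < 0)) stop("rho must be non-negative")
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1 && any(t$start[-1] <= t$end[-nrow(t)] - 0))
      if (any(t$start[-1] <= t$end[-nrow(t)]))
        stop("overlapping intervals on ", ch)
  }
  invisible(track)
}

#' FST versus local recombination rate
#'
#' Assigns each SNP the rho of its containing track interval (SNPs outside
#' the track are dropped), then reports (1) an ordinary least-squares fit of
#' per-SNP FST on rho with slope and p-value plus a LOESS smooth, (2) an
#' outlier-enrichment chi-square: rho is cut into deciles of the all-SNP
#' distribution and observed outlier counts per decile are compared to
#' counts proportional to the SNP totals, and (3) the outlier/non-outlier
#' mean-rho ratio with a Welch t-test. Enrichment is skipped (NULL, with a
#' message) when fewer than two rho bins are populated.
#'
#' @param persnp_fst data.frame from [wcFstPerSnp()] (chrom, pos, fst).
#' @param track recombination track as from [readRecombinationTrack()]
#'   (1-based start/end, rho).
#' @param outliers logical vector along \code{persnp_fst} rows (or a
#'   data.frame with chrom+pos of outlier SNPs) marking outlier SNPs.
#' @return list: data (per-SNP fst/rho/outlier), lm (slope, p, model),
#'   loess fit, enrichment (observed, expected, chisq, p or NULL),
#'   rho_ratio (mean rho outliers / non-outliers), t_test.
#' @export
fstVsRecombination <- function(persnp_fst, track, outliers) {
  validateRecombinationTrack(track)
  if (is.data.frame(outliers)) {
    key <- paste(persnp_fst$chrom, persnp_fst$pos)
    outliers <- key %in% paste(outliers$chrom, outliers$pos)
  }
  stopifnot(length(outliers) == nrow(persnp_fst))
  rho <- rep(NA_real_, nrow(persnp_fst))
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$start), ]
    sel <- which(persnp_fst$chrom == ch)
    if (!length(sel)) next
    iv <- findInterval(persnp_fst$pos[sel], t$start)
    ok <- iv >= 1 & persnp_fst$pos[sel] <= t$end[pmax(iv, 1)]
    rho[sel[ok]] <- t$rho[iv[ok]]
  }
  keep <- !is.na(rho) & !is.na(persnp_fst$fst)
  dat <- data.frame(chrom = persnp_fst$chrom[keep], pos = persnp_fst$pos[keep],
                    fst = persnp_fst$fst[keep], rho = rho[keep],
                    outlier = outliers[keep], stringsAsFactors = FALSE)
  if (nrow(dat) < 3) stop("too few SNPs covered by the recombination track")
  if (stats::var(dat$rho) > 0) {
    fit <- stats::lm(fst ~ rho, data = dat)
    sm <- summary(fit)$coefficients
    lmres <- list(slope = unname(sm["rho", "Estimate"]),
                  p_value = unname(sm["rho", "Pr(>|t|)"]), model = fit)
    lo <- tryCatch(suppressWarnings(stats::loess(fst ~ rho, data = dat)),
                   error = function(e) NULL)
  } else {
    lmres <- list(slope = NA_real_, p_value = NA_real_, model = NULL)
    lo <- NULL
  }

  enrichment <- NULL
  qs <- unique(stats::quantile(dat$rho, probs = seq(0, 1, 0.1)))
  if (length(qs) >= 3 && any(dat$outlier)) {
    bins <- cut(dat$rho, breaks = qs, include.lowest = TRUE)
    tot <- table(bins)
    obs <- table(bins[dat$outlier])
    expd <- sum(dat$outlier) * as.numeric(tot) / sum(tot)
    chisq <- sum((as.numeric(obs) - expd)^2 / expd)
    df <- length(tot) - 1L
    enrichment <- list(bins = names(tot), n_snps = as.integer(tot),
                      observed = as.integer(obs), expected = expd,
                      chisq = chisq, df = df,
                      p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
  } else {
    message("enrichment skipped: fewer than two populated rho bins ",
            "or no outliers")
  }
  rr <- NULL; tt <- NULL
  if (any(dat$outlier) && any(!dat$outlier)) {
    rr <- mean(dat$rho[dat$outlier]) / mean(dat$rho[!dat$outlier])
    tt <- tryCatch(stats::t.test(dat$rho[dat$outlier], dat$rho[!dat$outlier]),
                   error = function(e) NULL)
  }
  list(data = dat, lm = lmres, loess = lo, enrichment = enrichment,
       rho_ratio = rr, t_test = tt)
}
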