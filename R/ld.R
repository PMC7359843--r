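#' Pairwise linkage disequilibrium r-squared
#'
#' Composite (dosage-correlation) r-squared for all variant pairs on the same
#' chromosome separated by at most \code{max_dist_bp}. Phase is not required.
#' Pairs involving a monomorphic member are skipped.
#'
#' @param g a [GenotypeData-class] object.
#' @param max_dist_bp maximum pair separation in bp.
#' @return data.frame: chrom, pos1, pos2, dist, r2.
#' @export
ldR2 <- function(g, max_dist_bp = 100000) {
  d <- dosages(g)
  vt <- variantTable(g)
  out <- list()
  for (chrom in unique(vt$chrom)) {
    ix <- which(vt$chrom == chrom)
    pos <- vt$pos[ix]
    dc <- d[ix, , drop = FALSE]
    sds <- apply(dc, 1, stats::sd, na.rm = TRUE)
    for (i in seq_along(ix)) {
      if (is.na(sds[i]) || sds[i] == 0) next
      jmax <- findInterval(pos[i] + max_dist_bp, pos)
      js <- seq_len(jmax)
      js <- js[js > i & !is.na(sds[js]) & sds[js] > 0]
      if (!length(js)) next
      r <- suppressWarnings(
        stats::cor(dc[i, ], t(dc[js, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos1 = pos[i], pos2 = pos[js],
        dist = pos[js] - pos[i], r2 = as.numeric(r)^2,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos1 = integer(), pos2 = integer(),
                      dist = integer(), r2 = numeric())
  res[!is.na(res$r2), , drop = FALSE]
}

#' Binned LD decay curve
#'
#' Mean r-squared per distance bin, optionally smoothed by a centered moving
#' average over bins.
#'
#' @param pairs output of [ldR2()].
#' @param bin_bp distance bin width.
#' @param smooth_k odd moving-average width in bins (1 = no smoothing).
#' @return data.frame: dist (bin midpoint, bp), n_pairs, r2, r2_smooth.
#' @export
ldDecayCurve <- function(pairs, bin_bp = 5000, smooth_k = 1) {
  if (!nrow(pairs)) stop("no LD pairs to bin")
  bin <- floor((pairs$dist - 1) / bin_bp)
  agg <- stats::aggregate(pairs$r2, list(bin = bin),
                          function(v) c(mean(v), length(v)))
  res <- data.frame(dist = (agg$bin + 0.5) * bin_bp,
                    n_pairs = agg$x[, 2], r2 = agg$x[, 1])
  res <- res[order(res$dist), ]
  res$r2_smooth <- if (smooth_k > 1)
    as.numeric(stats::filter(res$r2, rep(1 / smooth_k, smooth_k), sides = 2))
  else res$r2
  rownames(res) <- NULL
  res
}

#' Recent effective population size from LD decay
#'
#' Inverts the Sved-type expectation \eqn{E[r^2] = 1/(\alpha + 4 N c)} per
#' distance bin after removing the sample-size bias:
#' \eqn{r^2_{adj} = r^2 - 1/(2n)} with n diploid samples. The physical
#' distance is converted to Morgans with a constant map (default 1 cM/Mb),
#' and each bin dates \eqn{t = 1/(2c)} generations ago. Bins with
#' non-positive adjusted r-squared are skipped with a warning.
#'
#' @param curve [ldDecayCurve()] output (column r2 is used).
#' @param n_samples number of diploid samples behind the r-squared values.
#' @param alpha mutation adjustment (2 by default; 0 disables).
#' @param cm_per_mb constant recombination map, cM per Mb.
#' @return data.frame: dist, c_morgans, t_generations, r2_adj, ne.
#' @export
neFromLd <- function(curve, n_samples, alpha = 2, cm_per_mb = 1) {
  c_m <- curve$dist * cm_per_mb * 1e-8  # bp -> Morgans
  r2_adj <- curve$r2 - 1 / (2 * n_samples)
  bad <- r2_adj <= 0 | c_m <= 0
  if (any(bad))
    warning(sum(bad), " bin(s) skipped (non-positive adjusted r2 or distance)")
  res <- data.frame(dist = curve$dist, c_morgans = c_m,
                    t_generations = 1 / (2 * c_m), r2_adj = r2_adj,
                    ne = (1 / (4 * c_m)) * (1 / r2_adj - alpha))
  res[!bad, , drop = FALSE]
}
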