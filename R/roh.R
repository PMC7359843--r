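#' Runs of homozygosity
#'
#' Scans each sample and chromosome for contiguous stretches of homozygous
#' genotypes. A run is broken by more than \code{max_het} heterozygous calls
#' (default 0); missing genotypes neither break a run nor count towards its
#' SNP tally. Runs longer than \code{max_snp} SNPs are segmented into
#' consecutive chunks of at most \code{max_snp} SNPs. Segments spanning at
#' least \code{min_len} bp are reported.
#'
#' @param g a [GenotypeData-class] object with sorted variants.
#' @param min_len minimum segment length in bp (default 500 kb).
#' @param max_snp maximum SNPs per reported segment (default 100).
#' @param max_het heterozygous calls tolerated inside a run (default 0).
#' @return list with \code{segments} (sample_id, chrom, start, end, n_snps,
#'   length) and \code{per_sample} (sample_id, n_roh, total_bp, mean_bp).
#' @export
rohScan <- function(g, min_len = 500000, max_snp = 100, max_het = 0) {
  d <- dosages(g)
  vt <- variantTable(g)
  ids <- colnames(g)
  segs <- list()
  for (chrom in unique(vt$chrom)) {
    ix <- which(vt$chrom == chrom)
    pos <- vt$pos[ix]
    dc <- d[ix, , drop = FALSE]
    for (s in seq_along(ids)) {
      v <- dc[, s]
      obs <- which(!is.na(v))
      if (!length(obs)) next
      het <- v[obs] == 1L
      # split observed genotypes into runs with at most max_het hets:
      # with max_het = 0 every het is a breakpoint
      run_id <- integer(length(obs))
      cur <- 1L; hcount <- 0L
      for (k in seq_along(obs)) {
        if (het[k]) {
          hcount <- hcount + 1L
          if (hcount > max_het) { cur <- cur + 1L; hcount <- 0L
            run_id[k] <- 0L; next }
        }
        run_id[k] <- cur
      }
      for (r in unique(run_id[run_id > 0L])) {
        snps <- obs[run_id == r]
        if (length(snps) < 2L) next
        # segment long runs into chunks of at most max_snp SNPs
        chunks <- split(snps, ceiling(seq_along(snps) / max_snp))
        for (ch in chunks) {
          if (length(ch) < 2L) next
          len <- pos[ch[length(ch)]] - pos[ch[1]] + 1L
          if (len >= min_len)
            segs[[length(segs) + 1L]] <- data.frame(
              sample_id = ids[s], chrom = chrom,
              start = pos[ch[1]], end = pos[ch[length(ch)]],
              n_snps = length(ch), length = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), n_snps = integer(),
               length = integer(), stringsAsFactors = FALSE)
  per_sample <- data.frame(sample_id = ids,
                           n_roh = vapply(ids, function(i)
                             sum(segments$sample_id == i), integer(1)),
                           total_bp = vapply(ids, function(i)
                             sum(segments$length[segments$sample_id == i]),
                             numeric(1)),
                           stringsAsFactors = FALSE, row.names = NULL)
  per_sample$mean_bp <- ifelse(per_sample$n_roh > 0,
                               per_sample$total_bp / per_sample$n_roh, NA_real_)
  list(segments = segments, per_sample = per_sample)
}

#' Compare ROH length distributions between two groups
#'
#' Wilcoxon rank-sum test on segment lengths pooled within each group
#' (e.g., island vs mainland samples).
#'
#' @param roh result of [rohScan()].
#' @param groups named vector mapping sample_id to group (exactly 2 groups).
#' @return list: per-group mean length, and the wilcox.test result.
#' @export
rohCompareGroups <- function(roh, groups) {
  segs <- roh$segments
  segs$group <- unname(groups[segs$sample_id])
  segs <- segs[!is.na(segs$group), ]
  gl <- split(segs$length, segs$group)
  if (length(gl) != 2L) stop("need segments in exactly two groups")
  list(mean_length = vapply(gl, mean, numeric(1)),
       n_segments = vapply(gl, length, integer(1)),
       test = stats::wilcox.test(gl[[1]], gl[[2]]))
}
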