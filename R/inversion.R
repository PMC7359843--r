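#' Sliding-window PCA scan for inversion-like sample clustering
#'
#' For each physical window, runs a PCA on mean-imputed centered dosages and
#' clusters the PC1 scores with a one-dimensional Gaussian mixture, the
#' number of components k in 1..3 chosen by BIC. A window is
#' flagged "trimodal" when k = 3 wins
#' and the middle centroid lies within 25\% of the midpoint between the
#' outer centroids — the pattern expected from the three arrangement
#' karyotypes of a polymorphic inversion. Windows with fewer than
#' \code{min_snps} SNPs are skipped.
#'
#' @param g a [GenotypeData-class] object.
#' @param window_bp,step_bp window and step sizes in bp (e.g. 10 Mb / 1 Mb
#'   coarse pass, then 1 Mb / 100 kb fine pass).
#' @param min_snps minimum SNPs per window (default 20).
#' @return data.frame: chrom, start, end, n_snps, k, trimodal, plus a
#'   \code{scores} attribute (list of PC1 score vectors per window).
#' @export
slidingPca <- function(g, window_bp = 1e6, step_bp = 1e5, min_snps = 20) {
  vt <- variantTable(g)
  d <- dosages(g)
  out <- list(); scores <- list()
  for (chrom in unique(vt$chrom)) {
    ix <- which(vt$chrom == chrom)
    pos <- vt$pos[ix]
    last <- max(pos)
    for (s in seq(1, max(last - window_bp + 1, 1), by = step_bp)) {
      e <- s + window_bp - 1
      w <- ix[pos >= s & pos <= e]
      if (length(w) < min_snps) next
      pc1 <- windowPc1(d[w, , drop = FALSE])
      km <- chooseClusters1d(pc1, kmax = 3)
      trimodal <- FALSE
      if (km$k == 3) {
        o <- order(km$centers)
        cen <- km$centers[o]; sds <- km$sds[o]
        mid <- (cen[1] + cen[3]) / 2
        # middle cluster near the midpoint of the outer two, and clusters
        # clearly separated (adjacent gaps beyond the component spreads)
        gaps_ok <- (cen[2] - cen[1]) > 3 * (sds[1] + sds[2]) / 2 &&
          (cen[3] - cen[2]) > 3 * (sds[2] + sds[3]) / 2
        trimodal <- gaps_ok &&
          abs(cen[2] - mid) <= 0.25 * (cen[3] - cen[1]) / 2
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, n_snps = length(w),
        k = km$k, trimodal = trimodal, stringsAsFactors = FALSE)
      scores[[length(scores) + 1L]] <- pc1
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_snps = integer(), k = integer(), trimodal = logical())
  attr(res, "scores") <- scores
  res
}

# Leading principal-component scores of a variants x samples dosage block.
windowPc1 <- function(dblock, k = 1) {
  X <- t(dblock)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.na(mu)] <- 0
    ii <- which(is.na(X), arr.ind = TRUE)
    X[ii] <- mu[ii[, 2]]
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = k, nv = 0)
  sc <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(sc) <- rownames(X)
  if (k == 1) sc[, 1] else sc
}

# 1-D clustering of PC1 scores: Gaussian mixture fitted by EM from a
# k-means start, components (1..kmax) chosen by BIC on the mixture
# likelihood. A naive k-means within-SS BIC is not usable here: for
# continuous unimodal scores splitting always reduces within-SS enough to
# defeat a k log(n) penalty, so a proper mixture likelihood is required.
chooseClusters1d <- function(x, kmax = 3) {
  n <- length(x)
  kmax <- min(kmax, length(unique(x)))
  vfloor <- 1e-6 * stats::var(x) + 1e-12
  best <- NULL
  for (k in seq_len(kmax)) {
    cl <- if (k == 1) rep(1L, n) else
      suppressWarnings(stats::kmeans(x, k, nstart = 20))$cluster
    mu <- vapply(seq_len(k), function(j) mean(x[cl == j]), numeric(1))
    s2 <- vapply(seq_len(k), function(j) {
      v <- stats::var(x[cl == j])
      max(if (is.na(v)) 0 else v, vfloor)
    }, numeric(1))
    pr <- tabulate(cl, k) / n
    ll <- -Inf
    for (it in seq_len(100)) {  # EM refinement from the k-means partition
      dens <- vapply(seq_len(k), function(j)
        pr[j] * stats::dnorm(x, mu[j], sqrt(s2[j])), numeric(n))
      dens <- matrix(dens, n, k)
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll_new <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      nk[nk <= 0] <- .Machine$double.xmin
      pr <- nk / n
      mu <- colSums(resp * x) / nk
      s2 <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, vfloor)
      if (is.finite(ll) && abs(ll_new - ll) < 1e-8) { ll <- ll_new; break }
      ll <- ll_new
    }
    bic <- 2 * ll - (3 * k - 1) * log(n)
    if (is.null(best) || bic > best$bic) {
      dens <- matrix(vapply(seq_len(k), function(j)
        pr[j] * stats::dnorm(x, mu[j], sqrt(s2[j])), numeric(n)), n, k)
      best <- list(k = k, bic = bic, centers = mu, sds = sqrt(s2),
                   cluster = max.col(dens))
    }
  }
  best
}

#' Local PCA / MDS scan over SNP blocks
#'
#' Splits each chromosome into consecutive blocks of \code{block_snps} SNPs
#' (blocks never span a chromosome boundary). Each block is summarized by
#' the rank-\code{k} eigen-approximation of its sample-by-sample covariance
#' matrix, normalized to unit Frobenius norm; block dissimilarity is the
#' Frobenius distance between these normalized approximations, embedded in
#' two dimensions by classical MDS. Outlier blocks have
#' |MDS1 - median| > 3 * mad(MDS1) (the scaled median absolute deviation,
#' a robust 3-standard-deviation rule).
#'
#' @param g a [GenotypeData-class] object.
#' @param block_snps SNPs per block (default 100).
#' @param k rank of the per-block approximation (default 2).
#' @param min_blocks minimum number of blocks required (default 10).
#' @return data.frame: block, chrom, start, end, n_snps, mds1, mds2, outlier.
#' @export
localPcaMds <- function(g, block_snps = 100, k = 2, min_blocks = 10) {
  vt <- variantTable(g)
  d <- dosages(g)
  blocks <- list()
  for (chrom in unique(vt$chrom)) {
    ix <- which(vt$chrom == chrom)
    nb <- floor(length(ix) / block_snps)
    if (nb < 1) next
    for (b in seq_len(nb)) {
      w <- ix[seq((b - 1) * block_snps + 1, b * block_snps)]
      blocks[[length(blocks) + 1L]] <- w
    }
  }
  if (length(blocks) < min_blocks)
    stop("fewer than ", min_blocks, " blocks; reduce block_snps")
  mats <- lapply(blocks, function(w) {
    X <- t(d[w, , drop = FALSE])
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE); mu[is.na(mu)] <- 0
      ii <- which(is.na(X), arr.ind = TRUE)
      X[ii] <- mu[ii[, 2]]
    }
    X <- scale(X, center = TRUE, scale = FALSE)
    C <- tcrossprod(X) / max(ncol(X) - 1, 1)
    eg <- eigen(C, symmetric = TRUE)
    kk <- min(k, sum(eg$values > 0))
    A <- eg$vectors[, seq_len(kk), drop = FALSE] %*%
      (eg$values[seq_len(kk)] * t(eg$vectors[, seq_len(kk), drop = FALSE]))
    nf <- sqrt(sum(A^2))
    if (nf > 0) A / nf else A
  })
  nb <- length(mats)
  D <- matrix(0, nb, nb)
  for (i in seq_len(nb - 1)) for (j in seq(i + 1, nb)) {
    D[i, j] <- D[j, i] <- sqrt(sum((mats[[i]] - mats[[j]])^2))
  }
  mds <- stats::cmdscale(D, k = 2)
  mds1 <- mds[, 1]; mds2 <- if (ncol(mds) > 1) mds[, 2] else rep(0, nb)
  thr <- 3 * stats::mad(mds1)
  res <- do.call(rbind, lapply(seq_len(nb), function(b) {
    w <- blocks[[b]]
    data.frame(block = b, chrom = vt$chrom[w[1]],
               start = vt$pos[w[1]], end = vt$pos[w[length(w)]],
               n_snps = length(w), mds1 = mds1[b], mds2 = mds2[b],
               stringsAsFactors = FALSE)
  }))
  res$outlier <- abs(res$mds1 - stats::median(res$mds1)) > thr
  res
}

#' Call candidate inversions from the local PCA / MDS scan
#'
#' Consolidates [localPcaMds()] outlier blocks into candidate regions:
#' runs of at least \code{min_blocks_run} consecutive outlier blocks on the
#' same chromosome whose MDS1 deviations share a sign (isolated outlier
#' blocks, typically local-LD haplotype artifacts, are discarded). Each
#' candidate region is then karyotyped with [assignKaryotypes()]; a region
#' whose PC1 scores support three clusters becomes a "called" inversion,
#' otherwise it stays a "candidate".
#'
#' @param g a [GenotypeData-class] object.
#' @param block_snps,k,min_blocks forwarded to [localPcaMds()].
#' @param min_blocks_run minimum consecutive outlier blocks (default 3).
#' @return list of calls; each has region (chrom, start, end), n_blocks,
#'   status, and the [assignKaryotypes()] result. Empty list when nothing
#'   is found.
#' @export
callInversions <- function(g, block_snps = 100, k = 2, min_blocks = 10,
                           min_blocks_run = 3) {
  lp <- localPcaMds(g, block_snps = block_snps, k = k,
                    min_blocks = min_blocks)
  calls <- list()
  ob <- lp[lp$outlier, , drop = FALSE]
  if (!nrow(ob)) return(calls)
  med <- stats::median(lp$mds1)
  ob$sign <- sign(ob$mds1 - med)
  runs <- split(ob, cumsum(c(1, diff(ob$block) != 1 |
                               diff(ob$sign) != 0 |
                               ob$chrom[-1] != ob$chrom[-nrow(ob)])))
  for (r in runs) {
    if (nrow(r) < min_blocks_run) next
    region <- list(chrom = r$chrom[1], start = min(r$start),
                   end = max(r$end))
    kc <- tryCatch(assignKaryotypes(g, region), error = function(e) NULL)
    if (is.null(kc)) next
    calls[[length(calls) + 1L]] <- list(region = region,
                                        n_blocks = nrow(r),
                                        status = kc$status,
                                        karyotypes = kc)
  }
  calls
}

#' Assign inversion karyotypes within a candidate region
#'
#' PCA on the region's SNPs followed by 1-D Gaussian-mixture clustering of
#' PC1 (BIC-selected k, see [slidingPca()]). The
#' middle cluster is called heterozygous (INV/STD); of the outer clusters
#' the minor one (fewer samples) is called the inverted homozygote
#' (INV/INV), following the convention that the inverted arrangement is the
#' rarer one. If BIC does not support three clusters the call is demoted to
#' "candidate" with all karyotypes unassigned. Hardy-Weinberg equilibrium
#' of the arrangement is tested with [hweChisq()] on the karyotype counts.
#'
#' @param g a [GenotypeData-class] object.
#' @param region list or data.frame with chrom, start, end (1-based).
#' @return list of class \code{karyotype_call}: status ("called" or
#'   "candidate"), karyotype (factor per sample: INV/INV, INV/STD, STD/STD,
#'   unassigned), counts, inv_freq (overall), inv_freq_by_pop, hwe, pc1.
#' @export
assignKaryotypes <- function(g, region) {
  vt <- variantTable(g)
  w <- which(vt$chrom == region$chrom & vt$pos >= region$start &
               vt$pos <= region$end)
  if (length(w) < 3) stop("region contains too few SNPs")
  pc1 <- windowPc1(dosages(g)[w, , drop = FALSE])
  km <- chooseClusters1d(pc1, kmax = 3)
  ids <- colnames(g)
  kar <- factor(rep("unassigned", ncol(g)),
                levels = c("INV/INV", "INV/STD", "STD/STD", "unassigned"))
  names(kar) <- ids
  if (km$k != 3) {
    return(structure(list(status = "candidate", karyotype = kar,
                          counts = NULL, inv_freq = NA_real_,
                          inv_freq_by_pop = NULL, hwe = NULL, pc1 = pc1),
                     class = "karyotype_call"))
  }
  ord <- order(km$centers)
  lo <- which(km$cluster == ord[1]); mid <- which(km$cluster == ord[2])
  hi <- which(km$cluster == ord[3])
  if (length(lo) <= length(hi)) { inv_hom <- lo; std_hom <- hi }
  else { inv_hom <- hi; std_hom <- lo }
  kar[inv_hom] <- "INV/INV"; kar[mid] <- "INV/STD"; kar[std_hom] <- "STD/STD"
  counts <- c(inv_hom = length(inv_hom), het = length(mid),
              std_hom = length(std_hom))
  n_assigned <- sum(counts)
  inv_freq <- (2 * counts[["inv_hom"]] + counts[["het"]]) / (2 * n_assigned)
  pop <- as.character(populations(g))
  by_pop <- vapply(sort(unique(pop)), function(p) {
    kp <- kar[pop == p]
    kp <- kp[kp != "unassigned"]
    if (!length(kp)) return(NA_real_)
    (2 * sum(kp == "INV/INV") + sum(kp == "INV/STD")) / (2 * length(kp))
  }, numeric(1))
  hwe <- hweChisq(counts[["inv_hom"]], counts[["het"]], counts[["std_hom"]])
  structure(list(status = "called", karyotype = kar, counts = counts,
                 inv_freq = inv_freq, inv_freq_by_pop = by_pop, hwe = hwe,
                 pc1 = pc1),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat("Inversion karyotype call:", x$status, "\n")
  if (!is.null(x$counts)) {
    print(x$counts)
    cat(sprintf("inverted-arrangement frequency: %.3f (HWE p = %.3g)\n",
                x$inv_freq, x$hwe$p_value))
  }
  invisible(x)
}

#' Arrangement-stratified statistics for an inversion region
#'
#' Between the two homozygote karyotype groups: per-SNP Weir-Cockerham FST
#' averaged (ratio of sums) inside versus outside the region; nucleotide
#' diversity per karyotype group in 10-kb windows inside the region
#' (genotype-based, per callable bp); dxy between the homozygote groups
#' from group allele frequencies, \eqn{d_{xy} = \sum_s p_x (1-p_y) +
#' p_y (1-p_x)} per callable bp (equal to the haplotype dxy in expectation);
#' and the net divergence Da = dxy - (pi_inv + pi_std)/2.
#'
#' With a sparse (e.g. RAD) panel the per-bp denominators should be the
#' callable sequence, not the window span; pass \code{callable_bp} (total
#' callable bp in the region) when known, else the region width is used.
#'
#' @param g a [GenotypeData-class] object.
#' @param region list with chrom, start, end.
#' @param karyotypes factor per sample as in [assignKaryotypes()] output.
#' @param window_bp window size for group pi profiles (default 10 kb).
#' @param callable_bp callable bp in the region (default region width).
#' @return list: fst_in, fst_out, fst_per_snp, pi_windows (data.frame),
#'   pi_group (region-wide per group), dxy, da, and ld (mean pairwise r2
#'   across the region for all samples vs standard homozygotes only —
#'   a segregating inversion maintains long-range LD that disappears once
#'   heterokaryotypes are excluded).
#' @export
arrangementStats <- function(g, region, karyotypes, window_bp = 10000,
                             callable_bp = NULL) {
  stopifnot(length(karyotypes) == ncol(g))
  vt <- variantTable(g)
  inreg <- vt$chrom == region$chrom & vt$pos >= region$start &
    vt$pos <= region$end
  if (is.null(callable_bp)) callable_bp <- region$end - region$start + 1
  hom <- karyotypes %in% c("INV/INV", "STD/STD")
  if (sum(karyotypes == "INV/INV") < 2 || sum(karyotypes == "STD/STD") < 2)
    stop("need at least two samples in each homozygote group")
  ghom <- g[, hom]
  grp <- droplevels(factor(karyotypes[hom]))
  fst <- wcFstPerSnp(ghom, grouping = grp)
  ros <- function(sel) {
    ok <- sel & !is.na(fst$a)
    den <- sum(fst$denom[ok])
    if (den > 0) sum(fst$a[ok]) / den else NA_real_
  }
  fst_in <- ros(inreg); fst_out <- ros(!inreg)

  d <- dosages(g)
  groups <- c("INV/INV", "INV/STD", "STD/STD")
  piGroupSites <- function(sel_sites, grp_name) {
    cols <- which(karyotypes == grp_name)
    if (length(cols) < 2) return(NA_real_)
    dg <- d[sel_sites, cols, drop = FALSE]
    n <- rowSums(!is.na(dg)); s <- rowSums(dg, na.rm = TRUE)
    ok <- n >= 2
    ch <- 2 * n[ok]  # chromosomes
    p <- s[ok] / ch
    sum(2 * p * (1 - p) * ch / (ch - 1))
  }
  # group pi in 10-kb windows inside the region (per callable bp, scaled by
  # the fraction of callable sequence falling in the window)
  wstarts <- seq(region$start, region$end, by = window_bp)
  frac_callable <- callable_bp / (region$end - region$start + 1)
  pi_windows <- do.call(rbind, lapply(wstarts, function(ws) {
    we <- min(ws + window_bp - 1, region$end)
    sel <- inreg & vt$pos >= ws & vt$pos <= we
    denom_bp <- (we - ws + 1) * frac_callable
    row <- data.frame(chrom = region$chrom, start = ws, end = we,
                      n_snps = sum(sel))
    for (grp_name in groups)
      row[[gsub("/", "_", grp_name)]] <-
        piGroupSites(sel, grp_name) / denom_bp
    row
  }))
  pi_group <- vapply(groups, function(grp_name)
    piGroupSites(inreg, grp_name) / callable_bp, numeric(1))
  names(pi_group) <- gsub("/", "_", groups)

  freq <- function(grp_name) {
    cols <- which(karyotypes == grp_name)
    dg <- d[inreg, cols, drop = FALSE]
    n <- rowSums(!is.na(dg)); s <- rowSums(dg, na.rm = TRUE)
    ifelse(n > 0, s / (2 * n), NA_real_)
  }
  p_inv <- freq("INV/INV"); p_std <- freq("STD/STD")
  okp <- !is.na(p_inv) & !is.na(p_std)
  dxy <- sum(p_inv[okp] * (1 - p_std[okp]) +
               p_std[okp] * (1 - p_inv[okp])) / callable_bp
  da <- dxy - (pi_group[["INV_INV"]] + pi_group[["STD_STD"]]) / 2

  # region LD contrast: the arrangement polymorphism maintains long-range
  # r2 across all samples that vanishes among standard homozygotes
  meanR2 <- function(cols) {
    ix <- which(inreg)
    if (length(ix) > 80) ix <- sort(sample(ix, 80))
    dd <- d[ix, cols, drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(dd), use = "pairwise.complete.obs"))^2
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  ld <- list(r2_all = meanR2(seq_len(ncol(g))),
             r2_std_hom = if (sum(karyotypes == "STD/STD") >= 4)
               meanR2(which(karyotypes == "STD/STD")) else NA_real_)

  list(fst_in = fst_in, fst_out = fst_out, fst_per_snp = fst,
       pi_windows = pi_windows, pi_group = pi_group, dxy = dxy, da = da,
       ld = ld)
}

#' Date an inversion from net divergence
#'
#' Arrangement age from \eqn{T = D_a / (2 \mu)} generations, converted to
#' years with the generation time. Negative Da (arrangement groups not
#' differentiated) is an error.
#'
#' @param Da net divergence per bp between arrangement groups (>= 0).
#' @param mu mutation rate per bp per generation (default 1e-8).
#' @param generation_time years per generation (default 2.3).
#' @return list: age_generations, age_years.
#' @export
dateInversion <- function(Da, mu = 1e-8, generation_time = 2.3) {
  if (is.na(Da) || Da < 0)
    stop("Da must be non-negative: arrangement groups not differentiated")
  t_gen <- Da / (2 * mu)
  list(age_generations = t_gen,
       age_years = gensToYears(t_gen, generation_time))
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration producing an ultrametric tree, serialized
#' to newick.
#'
#' @param distance_matrix symmetric non-negative matrix, zero diagonal;
#'   NA/NaN distances are an error.
#' @param labels tip labels (default rownames).
#' @return list: phylo (an \pkg{ape} tree), newick (string).
#' @export
upgmaTree <- function(distance_matrix, labels = rownames(distance_matrix)) {
  m <- as.matrix(distance_matrix)
  if (any(is.na(m))) stop("distance matrix contains NA/NaN")
  if (any(m < 0)) stop("distances must be non-negative")
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  tree <- ape::as.phylo(hc)
  list(phylo = tree, newick = ape::write.tree(tree))
}
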