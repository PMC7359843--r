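#' Redundancy analysis of genotypes on environmental predictors
#'
#' Fits a constrained ordination (RDA) of the sample-by-SNP dosage matrix on
#' a predictor table via \pkg{vegan}. Missing dosages are mean-imputed per
#' SNP beforehand; numeric predictors are standardized to zero mean and unit
#' variance and two-level factors coded 0/1, so predictor-axis correlations
#' are comparable across predictors. Global and per-predictor (marginal)
#' significance come from permutation tests of the pseudo-F statistic.
#'
#' @param Y samples x SNPs dosage matrix (or a [GenotypeData-class] object,
#'   transposed internally).
#' @param X predictor data.frame (one row per sample).
#' @param n_perm permutations for the significance tests (default 1000).
#' @param marginal also run per-predictor marginal permutation tests.
#' @return list of class \code{rda_result}: eigenvalues, proportion of total
#'   variance per constrained axis, sample scores, SNP loadings,
#'   predictor-axis correlations, global p, marginal p table, and the
#'   underlying \pkg{vegan} fit.
#' @export
rdaFit <- function(Y, X, n_perm = 1000, marginal = TRUE) {
  Y <- rdaResponse(Y)
  Xs <- standardizePredictors(X)
  dat <- as.data.frame(Xs)
  fit <- vegan::rda(Y ~ ., data = dat)
  finishRda(fit, Y, dat, n_perm, marginal, conditioned = FALSE)
}

#' Partial RDA with conditioning covariates
#'
#' Removes the effect of the conditioning table Z from both genotypes and
#' predictors (residualization, via \pkg{vegan}'s Condition term), then
#' proceeds as [rdaFit()]. With an empty Z this reduces exactly to
#' [rdaFit()].
#'
#' @param Y,X,n_perm,marginal as in [rdaFit()].
#' @param Z conditioning data.frame (or NULL/empty for none).
#' @return list of class \code{rda_result}.
#' @export
partialRda <- function(Y, X, Z = NULL, n_perm = 1000, marginal = TRUE) {
  if (is.null(Z) || NCOL(Z) == 0) return(rdaFit(Y, X, n_perm, marginal))
  Y <- rdaResponse(Y)
  Xs <- standardizePredictors(X)
  Zs <- standardizePredictors(Z)
  colnames(Zs) <- paste0(".cond_", colnames(Zs))
  dat <- as.data.frame(cbind(Xs, Zs))
  fml <- stats::as.formula(paste(
    "Y ~", paste(colnames(Xs), collapse = " + "),
    "+ Condition(", paste(colnames(Zs), collapse = " + "), ")"))
  fit <- vegan::rda(fml, data = dat)
  finishRda(fit, Y, dat, n_perm, marginal, conditioned = TRUE)
}

rdaResponse <- function(Y) {
  if (is(Y, "GenotypeData")) Y <- t(dosages(Y))
  Y <- as.matrix(Y)
  # per-SNP mean imputation
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    ix <- which(is.na(Y), arr.ind = TRUE)
    Y[ix] <- mu[ix[, 2]]
  }
  Y
}

standardizePredictors <- function(X) {
  X <- as.data.frame(X)
  out <- lapply(colnames(X), function(nm) {
    v <- X[[nm]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) {
        warning("dropping constant predictor: ", nm)
        return(NULL)
      }
      return(stats::setNames(data.frame((v - mean(v)) / s), nm))
    }
    f <- as.factor(v)
    if (nlevels(f) < 2) { warning("dropping constant predictor: ", nm)
                          return(NULL) }
    mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(mm) <- paste0(nm, "_", levels(f)[-1])
    as.data.frame(scale(mm))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  res <- do.call(cbind, out)
  # drop exactly collinear columns
  qr_ <- qr(as.matrix(res))
  if (qr_$rank < ncol(res)) {
    drop <- setdiff(seq_len(ncol(res)), qr_$pivot[seq_len(qr_$rank)])
    warning("dropping collinear predictor(s): ",
            paste(colnames(res)[drop], collapse = ", "))
    res <- res[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
  }
  res
}

finishRda <- function(fit, Y, dat, n_perm, marginal, conditioned) {
  eig <- fit$CCA$eig
  total <- fit$tot.chi
  xnum <- dat[, !grepl("^\\.cond_", colnames(dat)), drop = FALSE]
  if (length(eig)) {
    # constrained (linear-combination) sample scores: positions on the
    # fitted axes, matching the explicit regression + eigen construction
    site <- vegan::scores(fit, display = "lc",
                          choices = seq_along(eig), scaling = 1)
    spec <- vegan::scores(fit, display = "species",
                          choices = seq_along(eig), scaling = 1)
    pred_cor <- stats::cor(as.matrix(xnum), site)
  } else {
    site <- matrix(0, nrow(dat), 0)
    spec <- matrix(0, ncol(Y), 0)
    pred_cor <- NULL
  }
  glob <- vegan::anova.cca(fit, permutations = n_perm)
  marg <- NULL
  if (marginal && ncol(xnum) > 1) {
    marg <- tryCatch(vegan::anova.cca(fit, by = "margin",
                                      permutations = n_perm),
                     error = function(e) NULL)
  }
  structure(list(eig = eig,
                 prop_variance = eig / total,
                 total_inertia = total,
                 constrained_inertia = fit$CCA$tot.chi,
                 residual_inertia = if (!is.null(fit$CA)) fit$CA$tot.chi else 0,
                 conditioned_inertia = if (!is.null(fit$pCCA))
                   fit$pCCA$tot.chi else 0,
                 sample_scores = site, snp_loadings = spec,
                 predictor_axis_cor = pred_cor,
                 global_p = glob[["Pr(>F)"]][1],
                 global_F = glob[["F"]][1],
                 marginal = marg, fit = fit),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("RDA:", length(x$eig), "constrained axes;",
      sprintf("%.2f%%", 100 * sum(x$prop_variance)),
      "of total variance; global p =", format(x$global_p), "\n")
  print(round(utils::head(x$prop_variance, 5), 4))
  invisible(x)
}

#' SNP loading outliers on the leading RDA axes
#'
#' Flags SNPs whose loading deviates from the axis mean by more than
#' \code{sd_cutoff} standard deviations on any of the first \code{n_axes}
#' constrained axes; the list is deduplicated across axes.
#'
#' @param result an \code{rda_result}.
#' @param n_axes number of leading axes scanned (default 1).
#' @param sd_cutoff standard-deviation cutoff (default 3).
#' @return data.frame: snp, axis, loading, z (one row per SNP, the axis of
#'   its largest |z| among flagged axes).
#' @export
loadingOutliers <- function(result, n_axes = 1, sd_cutoff = 3) {
  load <- result$snp_loadings
  if (ncol(load) < n_axes) stop("result has fewer than n_axes axes")
  hits <- list()
  for (ax in seq_len(n_axes)) {
    v <- load[, ax]
    z <- (v - mean(v)) / stats::sd(v)
    ix <- which(abs(z) > sd_cutoff | sd_cutoff == 0)
    if (length(ix))
      hits[[ax]] <- data.frame(snp = rownames(load)[ix], axis = ax,
                               loading = v[ix], z = z[ix],
                               stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(snp = character(), axis = integer(),
                      loading = numeric(), z = numeric()))
  all <- do.call(rbind, hits)
  all <- all[order(-abs(all$z)), ]
  all <- all[!duplicated(all$snp), ]
  rownames(all) <- NULL
  all
}

#' LD pruning by windowed pairwise r-squared
#'
#' Slides a window of \code{window_snps} SNPs stepping by \code{step_snps};
#' within each window, for every pair with dosage-correlation r-squared above
#' \code{r2_max} the later SNP is marked for removal. Mirrors the common
#' "indep"-style pruning used before ordination.
#'
#' @param g a [GenotypeData-class] object.
#' @param window_snps,step_snps window and step in SNPs (default 50 / 5).
#' @param r2_max prune threshold (default 0.5, the VIF-2 equivalent).
#' @return pruned [GenotypeData-class] object.
#' @export
ldPrune <- function(g, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  vt <- variantTable(g)
  d <- dosages(g)
  drop <- rep(FALSE, nrow(g))
  for (chrom in unique(vt$chrom)) {
    ix <- which(vt$chrom == chrom)
    nv <- length(ix)
    starts <- if (nv <= window_snps) 1L else
      seq(1L, nv - window_snps + 1L, by = step_snps)
    for (s in starts) {
      w <- ix[seq(s, min(s + window_snps - 1L, nv))]
      w <- w[!drop[w]]
      if (length(w) < 2) next
      cc <- suppressWarnings(stats::cor(t(d[w, , drop = FALSE]),
                                        use = "pairwise.complete.obs"))^2
      for (i in seq_len(length(w) - 1L)) {
        if (drop[w[i]]) next
        hi <- which(cc[i, ] > r2_max)
        hi <- hi[hi > i & !drop[w[hi]]]
        if (length(hi)) drop[w[hi]] <- TRUE
      }
    }
  }
  g[!drop, ]
}
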