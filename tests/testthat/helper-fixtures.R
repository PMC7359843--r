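# Shared fixtures and independent oracles for the test suite.

# Small GenotypeData from a dosage matrix (variants x samples).
toyGenotypes <- function(dos, pops = NULL, chrom = "chr1",
                         pos = NULL, depth = 50) {
  nv <- nrow(dos); ns <- ncol(dos)
  if (is.null(pops)) pops <- rep(c("A1D", "B1D"), length.out = ns)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = nv)
  makeGenotypeData(
    dos,
    data.frame(chrom = rep(chrom, length.out = nv), pos = pos,
               depth = rep(depth, length.out = nv)),
    data.frame(sample_id = sprintf("s%03d", seq_len(ns)),
               population = pops, stringsAsFactors = FALSE))
}

# Independent per-SNP Weir-Cockerham (1984) oracle: straight scalar
# transcription of the two-allele variance components for r groups,
# written separately from the vectorized implementation.
wc84Oracle <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  r <- length(groups)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n <- vapply(groups, length, numeric(1))
  p <- vapply(groups, function(v) sum(v) / (2 * length(v)), numeric(1))
  h <- vapply(groups, function(v) mean(v == 1), numeric(1))
  nbar <- mean(n)
  nsum <- sum(n)
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  pbar <- sum(n * p) / nsum
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / nsum
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

# Brute-force nucleotide diversity / Watterson theta from a 0/1 haplotype
# matrix, by explicit pairwise comparison loops.
piThetaOracle <- function(hap, L) {
  n <- nrow(hap)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + sum(hap[i, ] != hap[j, ])
    np <- np + 1
  }
  S <- sum(apply(hap, 2, function(col) length(unique(col)) > 1))
  list(pi = tot / np / L, thetaW = S / (sum(1 / seq_len(n - 1)) * L))
}

# Two-step RDA oracle: explicit multivariate regression of centered Y on
# standardized X, then eigendecomposition of the fitted values.
rdaOracle <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(as.matrix(X))
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  Yhat <- H %*% Yc
  sv <- svd(Yhat)
  eig <- sv$d^2 / (nrow(Y) - 1)
  list(eig = eig[eig > 1e-12 * eig[1]], site = sv$u, total = sum(Yc^2) / (nrow(Y) - 1))
}

# Haplotype dataset constructed directly (bypassing the simulator).
handDataset <- function(loci, L = 100) {
  structure(loci, class = "haplotype_dataset", locus_bp = L)
}
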