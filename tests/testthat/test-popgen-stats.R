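test_that("per-SNP FST hits the fixed-difference and identical-pop limits", {
  dos <- cbind(matrix(0L, 1, 10), matrix(2L, 1, 10))
  g <- toyGenotypes(dos, pops = rep(c("P1", "P2"), each = 10))
  expect_equal(wcFstPerSnp(g)$fst, 1.0)
  # identical genotype vectors in both populations -> estimate <= 0
  v <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 1L)
  g2 <- toyGenotypes(matrix(c(v, v), 1, 20), pops = rep(c("P1", "P2"), each = 10))
  expect_lte(wcFstPerSnp(g2)$fst, 0)
  expect_error(wcFstPerSnp(g, grouping = rep("P1", 20)), "two groups")
})

test_that("vectorized WC components match the scalar oracle on random tables", {
  set.seed(101)
  for (rep in seq_len(100)) {
    r <- sample(2:4, 1)
    sizes <- sample(3:8, r, replace = TRUE)
    pops <- rep(paste0("P", seq_len(r)), sizes)
    dos <- matrix(sample(c(0:2, NA), sum(sizes), replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 1)
    g <- toyGenotypes(dos, pops = pops)
    got <- wcFstPerSnp(g)
    want <- wc84Oracle(split(dos[1, ], pops))
    if (is.na(want["a"])) {
      expect_true(is.na(got$a))
    } else {
      expect_equal(got$a, unname(want["a"]), tolerance = 1e-12)
      expect_equal(got$b, unname(want["b"]), tolerance = 1e-12)
      expect_equal(got$c, unname(want["c"]), tolerance = 1e-12)
    }
  }
})

test_that("pairwise FST is near zero under panmixia and tracks divergence", {
  set.seed(102)
  p <- runif(1000, 0.1, 0.9)
  dos <- vapply(p, function(pp) rbinom(60, 2, pp), integer(60))
  g <- toyGenotypes(t(dos), pops = rep(c("P1", "P2"), each = 30))
  pf <- pairwiseFst(g, n_boot = 200)
  expect_lt(abs(pf$fst_all), 0.01)
  expect_gt(pf$p_boot, 0.05)
  # strongly diverged populations -> high FST, significant bootstrap
  p1 <- runif(300, 0.05, 0.25); p2 <- 1 - p1
  dos2 <- cbind(t(vapply(p1, function(pp) rbinom(20, 2, pp), integer(20))),
                t(vapply(p2, function(pp) rbinom(20, 2, pp), integer(20))))
  g2 <- toyGenotypes(dos2, pops = rep(c("P1", "P2"), each = 20))
  pf2 <- pairwiseFst(g2, n_boot = 200)
  expect_gt(pf2$fst_all, 0.5)
  expect_lt(pf2$p_boot, 0.01)
})

test_that("chromosome classes split FST and empty classes yield NA", {
  set.seed(103)
  dos <- matrix(rbinom(40 * 100, 2, 0.4), 100, 40)
  g <- toyGenotypes(dos, pops = rep(c("P1", "P2"), each = 20),
                    chrom = rep(c("chr1", "chrZ"), each = 50),
                    pos = rep(seq(1000, by = 1000, length.out = 50), 2))
  pf <- pairwiseFst(g, n_boot = 50,
                    chrom_classes = c(chr1 = "autosome", chrZ = "Z"))
  expect_true(is.finite(pf$fst_autosome) && is.finite(pf$fst_Z))
  pf2 <- pairwiseFst(g[variantTable(g)$chrom == "chr1", ], n_boot = 50,
                     chrom_classes = c(chr1 = "autosome", chrZ = "Z"))
  expect_true(is.na(pf2$fst_Z))
})

test_that("window FST aggregates components and flags planted segments", {
  set.seed(104)
  # 10 SNPs with a block size of 50 -> a single partial window
  comp10 <- wcFstPerSnp(toyGenotypes(matrix(rbinom(200, 2, .5), 10, 20),
                                     pops = rep(c("P1", "P2"), each = 10)))
  w10 <- windowFst(comp10, "snp", block_snps = 50, step_snps = 5)
  expect_equal(nrow(w10), 1L)
  expect_equal(w10$n_snps, 10L)
  # uniform components -> every window equals the per-SNP ratio
  compU <- data.frame(chrom = "chr1", pos = seq(1e4, by = 1e4, length.out = 100),
                      a = 0.2, b = 0.1, c = 0.1, denom = 0.4, fst = 0.5)
  wU <- windowFst(compU, "kb", window_bp = 2e5)
  expect_true(all(abs(wU$fst - 0.5) < 1e-12))
  # planted 50-SNP divergent segment is a top-1% outlier in both modes
  n_snps <- 2000
  p <- runif(n_snps, 0.2, 0.8)
  dos <- t(vapply(p, function(pp) rbinom(40, 2, pp), integer(40)))
  plant <- 1001:1050
  dos[plant, 1:20] <- t(vapply(rep(0.05, 50), function(pp)
    rbinom(20, 2, pp), integer(20)))
  dos[plant, 21:40] <- t(vapply(rep(0.95, 50), function(pp)
    rbinom(20, 2, pp), integer(20)))
  g <- toyGenotypes(dos, pops = rep(c("P1", "P2"), each = 20),
                    pos = seq(2000, by = 2000, length.out = n_snps))
  comp <- wcFstPerSnp(g)
  for (mode in c("kb", "snp")) {
    w <- windowFst(comp, mode, window_bp = 1e5)
    hit <- w$outlier & w$start <= max(comp$pos[plant]) &
      w$end >= min(comp$pos[plant])
    expect_true(any(hit), label = paste("plant recovered in mode", mode))
  }
  # unsorted input is rejected
  bad <- compU[c(2, 1, 3:100), ]
  expect_error(windowFst(bad, "kb"), "sorted")
})

test_that("window FST ratio-of-sums stays within member per-SNP ratios", {
  set.seed(105)
  comp <- data.frame(chrom = "chr1", pos = seq(1e3, by = 1e3, length.out = 200),
                     a = runif(200, 0, .5), b = runif(200, 0, .3),
                     c = runif(200, 0, .3))
  comp$denom <- comp$a + comp$b + comp$c
  comp$fst <- comp$a / comp$denom
  w <- windowFst(comp, "snp", block_snps = 20, step_snps = 20)
  for (i in seq_len(nrow(w))) {
    members <- comp$fst[comp$pos >= w$start[i] & comp$pos <= w$end[i]]
    expect_gte(w$fst[i], min(members) - 1e-12)
    expect_lte(w$fst[i], max(members) + 1e-12)
  }
})

test_that("observed heterozygosity and MAF spectra match hand values", {
  g <- toyGenotypes(matrix(c(0L, 0L, 0L, 0L), 1, 4), pops = rep("P1", 4))
  expect_equal(observedHet(g)$ho, 0)
  g2 <- toyGenotypes(matrix(c(0L, 1L, 1L, 2L), 1, 4), pops = rep("P1", 4))
  oh <- observedHet(g2)
  expect_equal(oh$ho, 0.5)
  ms <- mafSpectrum(g2, breaks = seq(0, 0.5, 0.25))
  expect_equal(ms$count[ms$bin_low == 0.25], 1L)  # MAF = 0.5
})

test_that("island-like smaller populations show reduced heterozygosity", {
  set.seed(106)
  p_main <- rbeta(800, 0.8, 0.8)    # older, larger population: flatter SFS
  p_isl <- rbeta(800, 0.35, 0.35)   # drifted: U-shaped frequency spectrum
  dos <- cbind(t(vapply(p_main, function(pp) rbinom(25, 2, pp), integer(25))),
               t(vapply(p_isl, function(pp) rbinom(25, 2, pp), integer(25))))
  g <- toyGenotypes(dos, pops = rep(c("A1D", "B1D"), each = 25))
  oh <- observedHet(g)
  expect_lt(oh$ho[oh$group == "B1D"], oh$ho[oh$group == "A1D"])
})

test_that("GRM recovers duplicates, parent-offspring, and unrelatedness", {
  set.seed(107)
  n_snp <- 3000
  p <- runif(n_snp, 0.1, 0.9)
  draw <- function() rbinom(n_snp, 2, p)
  gametes <- function(geno) ifelse(geno == 1, rbinom(n_snp, 1, .5), geno / 2)
  mum <- draw(); dad <- draw()
  kid <- gametes(mum) + gametes(dad)
  # enough unrelated samples that the allele-frequency centering is stable
  others <- vapply(1:50, function(i) draw(), integer(n_snp))
  dos <- cbind(mum, dad, kid, mum, others)
  colnames(dos) <- NULL
  g <- toyGenotypes(dos, pops = rep("P1", ncol(dos)),
                    pos = seq(1e3, by = 1e3, length.out = n_snp))
  grm <- relatednessMatrix(g)
  expect_equal(grm[1, 4], grm[1, 1], tolerance = 1e-8)   # duplicate
  expect_equal(grm[1, 3], 0.5, tolerance = 0.1)           # parent-offspring
  expect_lt(max(abs(grm[1, 5:54])), 0.1)                  # unrelated
  expect_true(isSymmetric(grm))
  expect_gt(min(eigen(grm, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("LD r2 behaves at the duplicate and independence limits", {
  set.seed(108)
  v <- rbinom(80, 2, 0.4)
  dup <- toyGenotypes(rbind(v, v), pops = rep("P1", 80),
                      pos = c(1000, 2000))
  expect_equal(ldR2(dup, 5000)$r2, 1, tolerance = 1e-12)
  # independent SNPs: E[r2] ~ 1/n
  n <- 100
  dos <- t(vapply(runif(120, .2, .8), function(p) rbinom(n, 2, p),
                  integer(n)))
  g <- toyGenotypes(dos, pops = rep("P1", n),
                    pos = seq(1e3, by = 1e3, length.out = 120))
  r2 <- ldR2(g, 2e4)$r2
  expect_gt(mean(r2), 0.3 / n)
  expect_lt(mean(r2), 3 / n)
  # monomorphic members are skipped
  dos[1, ] <- 0L
  g2 <- toyGenotypes(dos, pops = rep("P1", n),
                     pos = seq(1e3, by = 1e3, length.out = 120))
  expect_false(any(ldR2(g2, 2e4)$pos1 == 1000))
})

test_that("binned LD decay declines with distance under recombination", {
  set.seed(109)
  # two tightly linked clusters of SNPs far apart: within-cluster pairs
  # share genealogy (copied haplotypes), between-cluster pairs do not
  n <- 80
  base1 <- rbinom(n, 2, .5); base2 <- rbinom(n, 2, .5)
  flip <- function(v) { i <- sample(n, 6); v[i] <- rbinom(6, 2, .5); v }
  dos <- rbind(base1, flip(base1), flip(base1),
               base2, flip(base2), flip(base2))
  g <- toyGenotypes(dos, pops = rep("P1", n),
                    pos = c(1e3, 2e3, 3e3, 5e5, 5.01e5, 5.02e5))
  curve <- ldDecayCurve(ldR2(g, 1e6), bin_bp = 1e5)
  expect_gt(curve$r2[1], utils::tail(curve$r2, 1))
})

test_that("Ne-from-LD inverts the Sved expectation exactly", {
  curve <- data.frame(dist = 1e5, n_pairs = 10,
                      r2 = 1 / (2 + 4 * 1000 * 0.001))
  ne <- neFromLd(curve, n_samples = 1e9, alpha = 2)  # no sampling bias
  expect_equal(ne$ne, 1000, tolerance = 1e-6)
  expect_equal(ne$t_generations, 500)
  curve2 <- data.frame(dist = 1e5, n_pairs = 10, r2 = 1 / (4 * 500 * 0.001))
  ne2 <- neFromLd(curve2, n_samples = 1e9, alpha = 0)
  expect_equal(ne2$ne, 500, tolerance = 1e-6)
  # non-positive adjusted r2 is skipped with a warning
  expect_warning(res <- neFromLd(data.frame(dist = 1e5, r2 = 0.001),
                                 n_samples = 50), "skipped")
  expect_equal(nrow(res), 0L)
})

test_that("ROH scan finds homozygous stretches and splits at heterozygotes", {
  pos <- seq(0, 600e3, by = 15e3) + 1   # 41 SNPs over 600 kb
  dos <- matrix(0L, length(pos), 1)
  g <- toyGenotypes(dos, pops = "P1", pos = pos)
  roh <- rohScan(g)
  expect_equal(nrow(roh$segments), 1L)
  expect_gte(roh$segments$length, 5e5)
  # a heterozygote in the middle splits the run; halves are < 500 kb
  dos2 <- dos; dos2[21, 1] <- 1L
  g2 <- toyGenotypes(dos2, pops = "P1", pos = pos)
  expect_equal(nrow(rohScan(g2)$segments), 0L)
})

test_that("inbred samples carry longer ROH than outbred (rank-sum)", {
  set.seed(110)
  pos <- seq(1, by = 5e4, length.out = 400)  # 20 Mb, 50 kb spacing
  p <- runif(400, 0.1, 0.35)
  outbred <- vapply(1:10, function(i) rbinom(400, 2, p), integer(400))
  inbred <- vapply(1:10, function(i) 2L * rbinom(400, 1, p), integer(400))
  g <- toyGenotypes(cbind(inbred, outbred), pops = rep(c("I", "O"), each = 10),
                    pos = pos)
  roh <- rohScan(g, min_len = 5e5, max_snp = 100)
  groups <- setNames(rep(c("inbred", "outbred"), each = 10),
                     sprintf("s%03d", 1:20))
  cmp <- rohCompareGroups(roh, groups)
  expect_gt(cmp$mean_length["inbred"], cmp$mean_length["outbred"])
  expect_lt(cmp$test$p.value, 0.05)
})

test_that("HWE chi-square matches the closed form on printed counts", {
  h <- hweChisq(4, 23, 86)
  expect_equal(h$p_hat, 31 / 226)
  expect_equal(h$chisq, 2.2185, tolerance = 1e-4)
  expect_equal(h$p_value, 0.1364, tolerance = 1e-3)
  expect_gt(h$p_value, 0.1)
  expect_equal(hweChisq(25, 50, 25)$chisq, 0)
  h2 <- hweChisq(50, 0, 50)
  expect_equal(h2$chisq, 100)
  expect_lt(h2$p_value, 1e-20)
  # fixed allele: defined as chisq 0, p 1
  expect_equal(hweChisq(10, 0, 0)$p_value, 1)
})

test_that("FST-recombination regression has valid null p-values", {
  set.seed(111)
  track <- data.frame(chrom = "chr1",
                      start = seq(1, by = 1e5, length.out = 50),
                      end = seq(1e5, by = 1e5, length.out = 50),
                      rho = runif(50, 0.001, 0.02))
  pos <- seq(5e4, by = 1e5, length.out = 50)
  pos <- rep(pos, each = 10) + seq(0, 9000, by = 1000)
  over <- 0
  for (r in 1:100) {
    fst <- data.frame(chrom = "chr1", pos = pos, fst = rbeta(500, .5, 10))
    res <- fstVsRecombination(fst, track, outliers = rep(FALSE, 500))
    if (res$lm$p_value > 0.05) over <- over + 1
  }
  expect_gte(over, 88)  # ~95% of null replicates non-significant
})

test_that("outliers planted in the lowest-rho decile enrich significantly", {
  set.seed(112)
  rho <- seq(0.001, 0.05, length.out = 100)
  track <- data.frame(chrom = "chr1",
                      start = seq(1, by = 1e5, length.out = 100),
                      end = seq(1e5, by = 1e5, length.out = 100),
                      rho = rho)
  pos <- seq(5e4, by = 1e5, length.out = 100)
  pos <- rep(pos, each = 5) + seq(0, 4000, by = 1000)
  fst <- data.frame(chrom = "chr1", pos = sort(pos), fst = rbeta(500, .5, 10))
  out <- rep(FALSE, 500)
  out[fst$pos < 1e6] <- TRUE  # all outliers in the lowest-rho stretch
  res <- fstVsRecombination(fst, track, out)
  expect_lt(res$enrichment$p_value, 0.01)
  expect_lt(res$rho_ratio, 1)
  # constant track -> single bin -> enrichment skipped
  track2 <- track; track2$rho <- 0.01
  expect_message(res2 <- fstVsRecombination(fst, track2, out), "skipped")
  expect_null(res2$enrichment)
})
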