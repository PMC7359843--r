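test_that("sliding PCA finds one cluster in noise windows", {
  set.seed(61)
  dos <- matrix(rbinom(40 * 60, 2, 0.3), 40, 60)
  g <- toyGenotypes(dos, pops = rep("P1", 60),
                    pos = seq(1000, by = 1000, length.out = 40))
  sw <- slidingPca(g, window_bp = 50000, step_bp = 50000, min_snps = 10)
  expect_equal(sw$k, 1L)
  expect_false(any(sw$trimodal))
})

test_that("two-deme structure gives two clusters, not a trimodal flag", {
  set.seed(62)
  p1 <- runif(60, 0.1, 0.4); p2 <- p1 + 0.45
  dos <- cbind(t(vapply(p1, function(p) rbinom(30, 2, p), integer(30))),
               t(vapply(p2, function(p) rbinom(30, 2, p), integer(30))))
  g <- toyGenotypes(dos, pops = rep(c("P1", "P2"), each = 30),
                    pos = seq(1000, by = 1000, length.out = 60))
  sw <- slidingPca(g, window_bp = 1e5, step_bp = 1e5, min_snps = 10)
  expect_equal(sw$k, 2L)
  expect_false(any(sw$trimodal))
})

test_that("a planted karyotype window is flagged trimodal", {
  set.seed(63)
  n <- 113
  k_inv <- rep(c(2L, 1L, 0L), times = c(4, 23, 86))
  hapI <- rbinom(50, 1, 0.9); hapS <- rbinom(50, 1, 0.1)
  dos <- vapply(seq_len(n), function(s) {
    a <- if (k_inv[s] >= 1) hapI else hapS
    b <- if (k_inv[s] == 2) hapI else hapS
    as.integer(pmin(a + b + rbinom(50, 1, 0.02), 2))
  }, integer(50))  # variants x samples
  g <- toyGenotypes(dos, pops = rep("A1D", n),
                    pos = seq(1000, by = 1000, length.out = 50))
  sw <- slidingPca(g, window_bp = 1e5, step_bp = 1e5, min_snps = 10)
  expect_equal(sw$k, 3L)
  expect_true(sw$trimodal)
})

test_that("identical blocks have zero local-PCA distance; plants share sign", {
  set.seed(64)
  st <- makeStudy(studyConfig("inversion"))
  g <- st$genotypes
  lp <- localPcaMds(g, block_snps = 100)
  tr <- st$truth$inversion
  inblocks <- lp$start >= tr$start - 1e5 & lp$end <= tr$end + 1e5 &
    lp$chrom == tr$chrom
  expect_gte(sum(lp$outlier[inblocks]), 4)
  s <- sign(lp$mds1[lp$outlier & inblocks] - median(lp$mds1))
  expect_true(all(s == s[1]))
  # duplicated identical blocks are at distance zero: mirror by feeding the
  # same block twice through the internal block summary
  d <- dosages(g)[1:100, ]
  X <- t(d); X[is.na(X)] <- 0
  X <- scale(X, center = TRUE, scale = FALSE)
  C <- tcrossprod(X) / (ncol(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  A <- eg$vectors[, 1:2] %*% (eg$values[1:2] * t(eg$vectors[, 1:2]))
  A <- A / sqrt(sum(A^2))
  expect_equal(sqrt(sum((A - A)^2)), 0)
})

test_that("karyotype assignment matches planted truth and frequencies", {
  set.seed(65)
  st <- makeStudy(studyConfig("inversion"))
  g <- st$genotypes
  tr <- st$truth$inversion
  kc <- assignKaryotypes(g, tr)
  expect_equal(kc$status, "called")
  expect_equal(unname(kc$counts), c(4, 23, 87))
  expect_equal(unname(kc$inv_freq), (2 * 4 + 23) / (2 * 114),
               tolerance = 1e-9)
  expect_gt(kc$hwe$p_value, 0.1)
  expect_equal(mean(as.character(kc$karyotype) == tr$karyotypes), 1.0)
  # an unstructured region cannot be karyotyped
  set.seed(66)
  dos <- matrix(rbinom(30 * 50, 2, 0.4), 30, 50)
  gn <- toyGenotypes(dos, pops = rep("A1D", 50),
                     pos = seq(1000, by = 1000, length.out = 30))
  kc2 <- assignKaryotypes(gn, list(chrom = "chr1", start = 1, end = 1e5))
  expect_equal(kc2$status, "candidate")
  expect_true(all(kc2$karyotype == "unassigned"))
})

test_that("arrangement statistics separate fixed haplotype groups", {
  set.seed(67)
  # region where homozygote groups are fixed for alternative haplotypes
  n_in <- 30; n_out <- 30
  kar <- factor(rep(c("INV/INV", "STD/STD"), each = 10),
                levels = c("INV/INV", "INV/STD", "STD/STD", "unassigned"))
  reg <- rbind(matrix(rep(c(0L, 2L), each = 10), n_in, 20, byrow = TRUE))
  outm <- t(vapply(runif(n_out, .3, .7), function(p) rbinom(20, 2, p),
                   integer(20)))
  g <- toyGenotypes(rbind(reg, outm), pops = rep("A1D", 20),
                    pos = c(seq(1e4, by = 1e3, length.out = n_in),
                            seq(2e5, by = 1e3, length.out = n_out)))
  region <- list(chrom = "chr1", start = 1, end = 1e5)
  st <- arrangementStats(g, region, kar, callable_bp = 1e5)
  expect_gt(st$fst_in, 0.95)
  expect_lt(st$fst_out, 0.2)
  expect_gt(st$dxy, 0)
  # randomly shuffled karyotypes erase the signal
  set.seed(68)
  st2 <- arrangementStats(g, region, sample(kar), callable_bp = 1e5)
  expect_lt(abs(st2$fst_in), 0.2)
})

test_that("inversion dating is linear in Da and 1/mu", {
  d <- dateInversion(0.0044, mu = 1e-8)
  expect_equal(d$age_generations, 220000)
  expect_equal(d$age_years, 506000)
  expect_equal(dateInversion(0)$age_generations, 0)
  expect_equal(dateInversion(0.0020, mu = 1e-8)$age_generations, 100000)
  set.seed(69)
  for (i in 1:20) {
    da <- runif(1, 1e-4, 1e-2); mu <- 10^runif(1, -9, -7); k <- runif(1, .1, 10)
    expect_equal(dateInversion(k * da, mu)$age_generations,
                 k * dateInversion(da, mu)$age_generations,
                 tolerance = 1e-9)
    expect_equal(dateInversion(da, k * mu)$age_generations,
                 dateInversion(da, mu)$age_generations / k,
                 tolerance = 1e-9)
  }
  expect_error(dateInversion(-0.001), "non-negative")
})

test_that("UPGMA reproduces hand agglomerations and is ultrametric", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ut <- upgmaTree(m)
  tr <- ut$phylo
  # ((A:1,B:1):3,C:4): check branch lengths via node depths
  depth <- ape::node.depth.edgelength(tr)
  expect_equal(unname(depth[seq_len(3)]), rep(4, 3))  # ultrametric at 4
  mrca_ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(depth[mrca_ab], 3)  # A and B join at height 1 (depth 4 - 1)
  m2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(sort(upgmaTree(m2)$phylo$edge.length), c(2, 2))
  # equal distances: ultrametric with equal root-tip depths
  m3 <- matrix(6, 4, 4); diag(m3) <- 0
  dimnames(m3) <- list(letters[1:4], letters[1:4])
  d3 <- ape::node.depth.edgelength(upgmaTree(m3)$phylo)
  expect_equal(unname(d3[1:4]), rep(3, 4), tolerance = 1e-9)
  mNA <- m; mNA[1, 2] <- mNA[2, 1] <- NA
  expect_error(upgmaTree(mNA), "NA")
})

test_that("the reported inversion span arithmetic is self-consistent", {
  len <- 14661550 - 11838789 + 1
  expect_equal(round(len / 1e6, 1), 2.8)
})
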