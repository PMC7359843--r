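test_that("model enumeration yields the twenty variants", {
  tab <- enumerateModels()
  expect_equal(nrow(tab), 20L)
  expect_equal(sum(tab$base == "PAN"), 2L)
  expect_equal(sum(tab$base == "SI"), 2L)
  for (b in c("EQ", "IM", "AM", "SC"))
    expect_equal(sum(tab$base == b), 4L)
  expect_false(any(tab$m_hetero & tab$base %in% c("PAN", "SI")))
  expect_false(anyDuplicated(tab$name) > 0)
})

test_that("prior draws respect model structure and prior bounds", {
  set.seed(21)
  si <- samplePriors("SI_Nhomo")
  expect_equal(si$M12, 0); expect_equal(si$M21, 0)
  for (i in 1:50) {
    am <- samplePriors("AM_NhomoMhomo")
    expect_true(am$T_am > 0 && am$T_am < am$T_split)
    sc <- samplePriors("SC_NhomoMhomo")
    expect_true(sc$T_sc > 0 && sc$T_sc < sc$T_split)
  }
  # EQ marginals match the prior (uniform M, log-uniform Ne)
  draws <- replicate(2000, {
    p <- samplePriors("EQ_NhomoMhomo")
    c(p$M12, p$N_pop1)
  })
  pr <- defaultPriors()
  ks_m <- ks.test(draws[1, ], "punif", 0, pr$upper[pr$param == "M12"])
  expect_gt(ks_m$p.value, 0.01)
  ks_n <- ks.test(log(draws[2, ]), "punif", log(1e2), log(1e6))
  expect_gt(ks_n$p.value, 0.01)
  # wide prior option extends the migration bound
  expect_equal(defaultPriors(wide = TRUE)$upper[
    defaultPriors()$param == "M12"][1], 200)
})

test_that("non-viable parameters fail before simulation", {
  p <- samplePriors("AM_NhomoMhomo")
  p$T_am <- p$T_split * 2
  expect_error(simulateDataset("AM_NhomoMhomo", p, n_loci = 1),
               "T_am")
})

test_that("panmixia yields no differentiation; deep isolation fixes alleles", {
  set.seed(22)
  p <- samplePriors("PAN_Nhomo", locus_bp = 850)
  p$N_pop1 <- p$N_pop2 <- 10000
  st <- summarizeDataset(simulateDataset("PAN_Nhomo", p, n_loci = 1000,
                                         n_hap = c(20, 20)))
  expect_lt(abs(st[["fst_mean"]]), 0.02)
  q <- samplePriors("SI_Nhomo", locus_bp = 850)
  q$N_pop1 <- q$N_pop2 <- q$N_anc <- 10000
  q$T_split <- 2e5  # >> 4N generations
  st2 <- summarizeDataset(simulateDataset("SI_Nhomo", q, n_loci = 300,
                                          n_hap = c(20, 20)))
  expect_gt(st2[["sf_mean"]], 0)
  expect_lt(st2[["ss_mean"]], 0.05)
})

test_that("island-model FST decreases monotonically with migration", {
  set.seed(23)
  fst <- vapply(c(0.4, 4, 40), function(M) {
    q <- samplePriors("EQ_NhomoMhomo", locus_bp = 850)
    q$N_pop1 <- q$N_pop2 <- 10000; q$M12 <- q$M21 <- M
    summarizeDataset(simulateDataset("EQ_NhomoMhomo", q, n_loci = 500,
                                     n_hap = c(20, 20)))[["fst_mean"]]
  }, numeric(1))
  expect_true(all(diff(fst) < 0))
})

test_that("summary statistics match hand computations and the oracle", {
  # identical haplotype sets in both populations: dxy equals pi up to the
  # O(1/n) unbiasedness correction of within-group pi, so Da is near zero
  set.seed(20)
  hap <- matrix(rbinom(10 * 6, 1, 0.4), 10, 6)
  loc <- list(geno = rbind(hap, hap), pos = 1:6, pop = rep(1:2, each = 10))
  st <- summarizeDataset(handDataset(list(loc), L = 100))
  expect_lt(abs(st[["da_mean"]]), st[["pi1_mean"]] / 9)
  expect_equal(st[["sf_mean"]], 0)
  # fixed differences at 10 sites, L = 100
  loc2 <- list(geno = rbind(matrix(0, 4, 10), matrix(1, 4, 10)),
               pos = 1:10, pop = rep(1:2, each = 4))
  st2 <- summarizeDataset(handDataset(list(loc2), L = 100))
  expect_equal(st2[["dxy_mean"]], 0.1)
  expect_equal(st2[["pi1_mean"]], 0)
  expect_equal(st2[["pi2_mean"]], 0)
  expect_equal(st2[["da_mean"]], 0.1)
  expect_equal(st2[["sf_mean"]], 10)
  # random locus: pi and thetaW against the brute-force oracle
  set.seed(24)
  hap3 <- matrix(rbinom(20 * 15, 1, 0.3), 20, 15)
  loc3 <- list(geno = hap3, pos = 1:15, pop = rep(1:2, each = 10))
  st3 <- summarizeDataset(handDataset(list(loc3), L = 200))
  or1 <- piThetaOracle(hap3[1:10, , drop = FALSE], 200)
  or2 <- piThetaOracle(hap3[11:20, , drop = FALSE], 200)
  expect_equal(st3[["pi1_mean"]], or1$pi, tolerance = 1e-12)
  expect_equal(st3[["thetaW1_mean"]], or1$thetaW, tolerance = 1e-12)
  expect_equal(st3[["pi2_mean"]], or2$pi, tolerance = 1e-12)
  expect_equal(st3[["thetaW2_mean"]], or2$thetaW, tolerance = 1e-12)
})

test_that("pi and Watterson theta are unbiased under neutral panmixia", {
  set.seed(25)
  p <- samplePriors("PAN_Nhomo", locus_bp = 850)
  p$N_pop1 <- p$N_pop2 <- 10000
  ds <- simulateDataset("PAN_Nhomo", p, n_loci = 2000, n_hap = c(20, 20))
  per <- t(vapply(ds, function(l) DivergeScan:::locusStats(l, 850),
                  numeric(11)))
  theta_true <- 4 * 10000 * 1e-8
  for (col in c(1, 3)) {  # pi1, thetaW1
    m <- mean(per[, col]); se <- sd(per[, col]) / sqrt(nrow(per))
    expect_lt(abs(m - theta_true), 3 * se + 1e-6)
  }
  # E[Da] = 0 under panmixia
  m_da <- mean(per[, 6]); se_da <- sd(per[, 6]) / sqrt(nrow(per))
  expect_lt(abs(m_da), 3 * se_da)
})

test_that("vanishing beta heterogeneity reproduces the homogeneous model", {
  set.seed(26)
  fst_of <- function(model, hetero) {
    replicate(200, {
      p <- samplePriors(model, locus_bp = 850)
      p$N_pop1 <- p$N_pop2 <- 5000; p$M12 <- p$M21 <- 2
      if (hetero) { p$a_N <- p$b_N <- 1000 }  # variance -> 0, mean 1
      summarizeDataset(simulateDataset(model, p, n_loci = 50,
                                       n_hap = c(10, 10)))[["fst_mean"]]
    })
  }
  f_homo <- fst_of("EQ_NhomoMhomo", FALSE)
  f_het <- fst_of("EQ_NheteroMhomo", TRUE)
  expect_gt(suppressWarnings(ks.test(f_homo, f_het))$p.value, 0.01)
})

test_that("ms-like export round-trips locus counts", {
  set.seed(27)
  p <- samplePriors("PAN_Nhomo")
  p$N_pop1 <- p$N_pop2 <- 5000
  ds <- simulateDataset("PAN_Nhomo", p, n_loci = 5, n_hap = c(4, 4))
  f <- withr::local_tempfile()
  writeMsLike(ds, f)
  txt <- readLines(f)
  expect_equal(sum(txt == "//"), 5L)
})
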