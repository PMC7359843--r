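test_that("VCF genotypes map to ALT-allele dosages with missing handling", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t1|1\t0/0",
    "chr1\t300\t.\tG\tC,A\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"), vcf)
  md <- file.path(dir, "meta.tsv")
  writeSampleMeta(data.frame(sample_id = c("s1", "s2", "s3"),
                             population = "A1D"), md)
  expect_warning(g <- readGenotypeVcf(vcf, md), "non-biallelic")
  expect_equal(nrow(g), 2L)  # multi-allelic record skipped
  expect_equal(unname(dosages(g)[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(dosages(g)[2, 1]))
  expect_equal(unname(dosages(g)[2, 2:3]), c(2L, 0L))
  # region/habitat derived from the population code
  expect_equal(unique(sampleMeta(g)$region), "mainland")
  expect_equal(unique(sampleMeta(g)$habitat), "deciduous")
  # a VCF sample absent from the metadata is fatal
  writeSampleMeta(data.frame(sample_id = c("s1", "s2"),
                             population = "A1D"), md)
  expect_error(suppressWarnings(readGenotypeVcf(vcf, md)), "absent")
})

test_that("synthetic VCF round-trips to an identical dosage matrix", {
  dir <- withr::local_tempdir()
  set.seed(11)
  st <- makeStudy(studyConfig("pair", chromosomes = c(chr1 = 5e5)),
                  dir = dir)
  g2 <- readGenotypeVcf(st$paths$vcf, st$paths$metadata)
  expect_identical(dosages(st$genotypes), dosages(g2))
  expect_identical(variantTable(st$genotypes)$pos, variantTable(g2)$pos)
})

test_that("filter chain removes by call rate and reports counts exactly", {
  set.seed(1)
  dos <- matrix(rbinom(10 * 10, 2, 0.4), 10, 10)
  dos[1, 1:3] <- NA  # call rate 0.7
  dos[2, 1:3] <- NA
  g <- toyGenotypes(dos, pops = rep(c("A1D", "A1E"), each = 5))
  cfg <- filterConfig(min_depth = NULL, max_depth = NULL,
                      max_het_region = NULL, min_sample_call_rate = NULL,
                      max_relatedness = NULL, max_per_population = NULL,
                      drop_monomorphic = FALSE)
  res <- applyFilters(g, cfg)
  expect_equal(nrow(res$genotypes), 8L)
  rep_cr <- res$report[res$report$step == "variant_call_rate", ]
  expect_equal(rep_cr$variants_removed, 2L)
  # removal counts always equal the dimension differences
  expect_equal(sum(res$report$variants_removed), nrow(g) - nrow(res$genotypes))
  expect_equal(sum(res$report$samples_removed), ncol(g) - ncol(res$genotypes))
})

test_that("disabled thresholds give the identity and an empty report", {
  set.seed(2)
  g <- toyGenotypes(matrix(rbinom(40, 2, 0.5), 8, 5))
  cfg <- filterConfig(min_depth = NULL, max_depth = NULL,
                      min_variant_call_rate = NULL, max_het_region = NULL,
                      min_sample_call_rate = NULL, max_relatedness = NULL,
                      max_per_population = NULL, drop_monomorphic = FALSE)
  res <- applyFilters(g, cfg)
  expect_identical(dosages(res$genotypes), dosages(g))
  expect_equal(nrow(res$report), 0L)
})

test_that("exactly one member of a duplicated sample pair is removed", {
  set.seed(3)
  dos <- matrix(rbinom(200 * 6, 2, 0.5), 200, 6)
  dos[, 6] <- dos[, 5]  # s006 duplicates s005
  g <- toyGenotypes(dos, pops = rep("A1D", 6))
  cfg <- filterConfig(min_depth = NULL, max_depth = NULL,
                      min_variant_call_rate = NULL, max_het_region = NULL,
                      min_sample_call_rate = NULL, max_per_population = NULL,
                      drop_monomorphic = FALSE)
  res <- applyFilters(g, cfg)
  expect_equal(ncol(res$genotypes), 5L)
  # tie on missingness -> lexicographically larger id removed
  expect_true("s005" %in% colnames(res$genotypes))
  expect_false("s006" %in% colnames(res$genotypes))
  expect_equal(res$report$samples_removed[res$report$step == "relatedness"], 1L)
})

test_that("filtering is idempotent and preserves variant order", {
  set.seed(4)
  dos <- matrix(rbinom(100 * 20, 2, 0.3), 100, 20)
  dos[sample(length(dos), 150)] <- NA
  g <- toyGenotypes(dos, pops = rep(c("A1D", "B1D"), each = 10),
                    depth = runif(100, 5, 120))
  res1 <- applyFilters(g, filterConfig(max_per_population = NULL))
  res2 <- applyFilters(res1$genotypes, filterConfig(max_per_population = NULL))
  expect_identical(dosages(res1$genotypes), dosages(res2$genotypes))
  pos <- variantTable(res1$genotypes)$pos
  expect_true(all(diff(pos) > 0))
  expect_true(all(pos %in% variantTable(g)$pos))
})

test_that("an all-filtering step raises an error naming the step", {
  g <- toyGenotypes(matrix(1L, 4, 4), depth = 2)  # depth below minimum
  expect_error(applyFilters(g, filterConfig()), "depth")
})
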