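#' Configuration for the synthetic study generator
#'
#' Defaults emulate a two-region (mainland "A" / island "B"), paired-habitat
#' (deciduous "D" / evergreen "E") RAD-seq study design: ten populations, a
#' shared ancient-migration history between regions calibrated to moderate
#' between-region differentiation (FST around 0.08), strong within-region
#' gene flow giving weak differentiation (FST around 0.003-0.008), short
#' independent loci tiled along synthetic chromosomes, a planted polymorphic
#' inversion on chr3 present only on the mainland, and planted
#' habitat-associated outlier SNPs.
#'
#' @param preset "full-study", "pair" (two within-region populations, no
#'   plants), "island-mainland" (one population per region, no plants) or
#'   "inversion" (two mainland populations, inversion plant only).
#' @param ... overrides for any configuration element.
#' @return list of class \code{study_config}.
#' @export
studyConfig <- function(preset = c("full-study", "pair", "island-mainland",
                                   "inversion"), ...) {
  preset <- match.arg(preset)
  pops <- data.frame(
    population = c("A1D", "A1E", "A2D", "A2E",
                   "B1D", "B1E", "B2D", "B2E", "B3D", "B3E"),
    latitude = c(43.66, 43.66, 43.93, 43.93,
                 42.38, 42.37, 42.45, 42.44, 42.54, 42.53),
    longitude = c(3.67, 3.68, 3.50, 3.51,
                  8.75, 8.74, 8.91, 8.92, 8.99, 9.02),
    altitude = c(220, 240, 600, 620, 350, 380, 250, 267, 1027, 881),
    stringsAsFactors = FALSE)
  pops <- completeSampleMeta(cbind(sample_id = pops$population, pops))
  pops$sample_id <- NULL
  cfg <- list(
    preset = preset,
    populations = pops,
    n_per_pop = 12,
    chromosomes = c(chr1 = 14e6, chr2 = 12e6, chr3 = 16e6, chr4 = 10e6,
                    chr5 = 8e6, chrZ = 6e6),
    locus_spacing_bp = 20000,
    locus_bp = 300,
    mu = 1e-8,
    # demography (generations / diploid sizes)
    N_mainland = 50000, N_island = 15000, N_anc = 40000,
    T_split = 50000, T_am = 8000,
    M_within = 250,   # total scaled immigration per population, within region
    M_between = 1.5,  # scaled immigration per population, between regions
    # planted inversion
    inversion = list(chrom = "chr3", start = 11800001, end = 14600000,
                     freq_mainland = 0.14, freq_island = 0,
                     da_target = 0.0044, N_inv = 5000, N_std = 50000),
    # planted habitat-associated outliers
    n_outliers = 25, outlier_delta = 0.3,
    missing_rate = 0.02, depth_mean = 50, depth_sd = 12)
  if (preset == "pair") {
    cfg$populations <- pops[pops$population %in% c("A2D", "A2E"), ]
    cfg$chromosomes <- c(chr1 = 10e6)
    cfg$inversion <- NULL; cfg$n_outliers <- 0
  } else if (preset == "island-mainland") {
    cfg$populations <- pops[pops$population %in% c("A1D", "B1D"), ]
    cfg$chromosomes <- c(chr1 = 10e6)
    cfg$inversion <- NULL; cfg$n_outliers <- 0
  } else if (preset == "inversion") {
    # two mainland populations sized to the karyotyped study sample, with
    # fixed karyotype counts at Hardy-Weinberg proportions (freq ~0.14)
    cfg$populations <- pops[pops$population %in% c("A1D", "A2D"), ]
    cfg$chromosomes <- c(chr3 = 16e6)
    cfg$n_outliers <- 0
    cfg$n_per_pop <- 57
    cfg$inversion$karyotype_counts <- c(inv_hom = 4, het = 23, std_hom = 87)
  }
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  structure(cfg, class = "study_config")
}

# Multi-deme epoch structure for the study background: within-region
# migration always; between-region migration only in [T_am, T_split);
# all demes merge into deme 1 (size N_anc) at T_split.
studyEpochs <- function(cfg) {
  pops <- cfg$populations
  D <- nrow(pops)
  sizes <- ifelse(pops$region == "mainland", cfg$N_mainland, cfg$N_island)
  mig_within <- matrix(0, D, D)
  for (r in unique(pops$region)) {
    ix <- which(pops$region == r)
    if (length(ix) < 2) next
    for (i in ix) {
      rate <- cfg$M_within / (4 * sizes[i] * (length(ix) - 1))
      mig_within[i, setdiff(ix, i)] <- rate
    }
  }
  mig_both <- mig_within
  for (i in seq_len(D)) {
    other <- which(pops$region != pops$region[i])
    if (length(other))
      mig_both[i, other] <- cfg$M_between / (4 * sizes[i] * length(other))
  }
  two_regions <- length(unique(pops$region)) == 2
  if (two_regions) {
    list(end = c(cfg$T_am, cfg$T_split, Inf),
         N = rbind(sizes, sizes, c(cfg$N_anc, rep(0, D - 1))),
         mig = list(mig_within, mig_both, matrix(0, D, D)),
         remap = rbind(seq_len(D), seq_len(D), rep(1L, D)))
  } else {
    # single region: island model, no deeper structure
    list(end = Inf, N = matrix(sizes, 1), mig = list(mig_within),
         remap = matrix(seq_len(D), 1))
  }
}

#' Generate a synthetic study: genotypes, metadata, truth
#'
#' Simulates the neutral background under the structured coalescent using
#' the configured multi-population history, tiles the loci along synthetic
#' chromosomes, overlays the planted inversion (two deep-split arrangement
#' haplotype pools; karyotypes drawn at Hardy-Weinberg proportions at the
#' configured regional frequencies; arrangement membership shared across
#' all loci of the region, emulating suppressed recombination) and the
#' planted habitat-associated allele-frequency shifts, sprinkles missing
#' genotypes, and returns the dataset with a machine-readable ground truth.
#'
#' Uses the session RNG: call \code{set.seed()} first for reproducibility.
#'
#' @param cfg a [studyConfig()] list.
#' @param dir output directory; when given, writes \code{genotypes.vcf},
#'   \code{metadata.tsv} and \code{truth.json} there.
#' @return list: genotypes ([GenotypeData-class]), truth (study_truth list),
#'   paths (when \code{dir} is given).
#' @export
makeStudy <- function(cfg = studyConfig(), dir = NULL) {
  pops <- cfg$populations
  n_pop <- nrow(pops)
  n_per <- cfg$n_per_pop
  samples <- data.frame(
    sample_id = unlist(lapply(pops$population, function(p)
      sprintf("%s_%02d", p, seq_len(n_per)))),
    population = rep(pops$population, each = n_per),
    stringsAsFactors = FALSE)
  samples <- completeSampleMeta(merge(samples, pops, by = "population",
                                      sort = FALSE))
  samples <- samples[, c("sample_id", "population", "region", "habitat",
                         "latitude", "longitude", "altitude")]
  n_samples <- nrow(samples)

  inv <- cfg$inversion
  if (!is.null(inv)) {
    if (!inv$chrom %in% names(cfg$chromosomes))
      stop("inversion chromosome absent from chromosome layout")
    if (!is.null(inv$karyotype_counts)) {
      kc <- inv$karyotype_counts
      main <- which(samples$region == "mainland")
      if (sum(kc) != length(main))
        stop("karyotype_counts must sum to the number of mainland samples")
      k_inv <- integer(n_samples)
      k_inv[sample(main)] <- rep(c(2L, 1L, 0L), times = kc)
    } else {
      f <- ifelse(samples$region == "mainland", inv$freq_mainland,
                  inv$freq_island)
      k_inv <- stats::rbinom(n_samples, 2, f)
    }
    names(k_inv) <- samples$sample_id
  }

  ep <- studyEpochs(cfg)
  n_hap_bg <- rep(2L * n_per, n_pop)
  mu_locus <- cfg$mu * cfg$locus_bp

  var_list <- list(); dos_list <- list()
  truth_outliers <- NULL
  L <- cfg$locus_bp
  for (chrom in names(cfg$chromosomes)) {
    clen <- cfg$chromosomes[[chrom]]
    starts <- seq(1, clen - L, by = cfg$locus_spacing_bp)
    for (ls in starts) {
      in_inv <- !is.null(inv) && chrom == inv$chrom &&
        ls >= inv$start && (ls + L - 1) <= inv$end
      if (in_inv) {
        sim <- simulateInversionLocus(k_inv, inv, cfg$mu, L)
      } else {
        raw <- .sim_locus_cpp(n_hap_bg, ep$end, ep$N, ep$mig, ep$remap,
                              mu_locus)
        sim <- raw
      }
      if (ncol(sim$geno) == 0) next
      # haplotypes -> sample dosages (rows 2s-1, 2s belong to sample s)
      gh <- sim$geno
      dos <- gh[seq(1, nrow(gh), by = 2), , drop = FALSE] +
        gh[seq(2, nrow(gh), by = 2), , drop = FALSE]
      off <- pmin(floor(sim$pos * (L - 1)), L - 1)
      keep <- !duplicated(off)
      off <- off[keep]
      dos <- dos[, keep, drop = FALSE]
      o <- order(off)
      dos <- dos[, o, drop = FALSE]
      pos_bp <- ls + off[o]
      var_list[[length(var_list) + 1L]] <-
        data.frame(chrom = chrom, pos = pos_bp, stringsAsFactors = FALSE)
      dos_list[[length(dos_list) + 1L]] <- t(dos)
    }
  }
  variants <- do.call(rbind, var_list)
  dosage <- do.call(rbind, dos_list)
  colnames(dosage) <- samples$sample_id

  # planted habitat-associated outlier SNPs: frequency shift delta between
  # habitats, identical base frequency in both regions
  if (cfg$n_outliers > 0) {
    in_inv_region <- if (!is.null(inv))
      which(variants$chrom == inv$chrom & variants$pos >= inv$start &
              variants$pos <= inv$end)
    else integer(0)
    candidates <- setdiff(seq_len(nrow(variants)), in_inv_region)
    pick <- sort(sample(candidates, cfg$n_outliers))
    hab <- samples$habitat
    for (ix in pick) {
      p0 <- stats::runif(1, 0.35, 0.65)
      p <- ifelse(hab == "evergreen", p0 + cfg$outlier_delta / 2,
                  p0 - cfg$outlier_delta / 2)
      dosage[ix, ] <- stats::rbinom(n_samples, 2, pmin(pmax(p, 0), 1))
    }
    truth_outliers <- data.frame(chrom = variants$chrom[pick],
                                 pos = variants$pos[pick],
                                 delta = cfg$outlier_delta,
                                 stringsAsFactors = FALSE)
  }

  # missingness and depth
  if (cfg$missing_rate > 0) {
    nmiss <- stats::rbinom(1, length(dosage), cfg$missing_rate)
    dosage[sample(length(dosage), nmiss)] <- NA_integer_
  }
  depth <- pmin(pmax(stats::rnorm(nrow(variants), cfg$depth_mean,
                                  cfg$depth_sd), 12), 95)

  # drop monomorphic (after planting)
  n <- rowSums(!is.na(dosage)); s <- rowSums(dosage, na.rm = TRUE)
  poly <- n > 0 & s > 0 & s < 2 * n
  if (!is.null(truth_outliers)) {
    key <- paste(variants$chrom, variants$pos)
    poly[key %in% paste(truth_outliers$chrom, truth_outliers$pos)] <- TRUE
  }
  variants <- variants[poly, , drop = FALSE]
  dosage <- dosage[poly, , drop = FALSE]
  depth <- depth[poly]
  variants$ref <- "A"; variants$alt <- "T"; variants$depth <- depth

  g <- makeGenotypeData(dosage, variants, samples)
  truth <- list(
    schema_version = 1L,
    preset = cfg$preset,
    populations = pops,
    n_per_pop = n_per,
    demography = list(N_mainland = cfg$N_mainland, N_island = cfg$N_island,
                      N_anc = cfg$N_anc, T_split = cfg$T_split,
                      T_am = cfg$T_am, M_within = cfg$M_within,
                      M_between = cfg$M_between, mu = cfg$mu,
                      locus_bp = cfg$locus_bp),
    outliers = truth_outliers,
    inversion = if (!is.null(inv)) list(
      chrom = inv$chrom, start = inv$start, end = inv$end,
      freq_mainland = inv$freq_mainland, freq_island = inv$freq_island,
      da_target = inv$da_target, polarity = "minor",
      karyotypes = stats::setNames(
        c("STD/STD", "INV/STD", "INV/INV")[k_inv + 1L], samples$sample_id))
    else NULL)
  class(truth) <- "study_truth"

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  metadata = file.path(dir, "metadata.tsv"),
                  truth = file.path(dir, "truth.json"))
    writeGenotypeVcf(g, paths$vcf)
    writeSampleMeta(samples, paths$metadata)
    writeTruth(truth, paths$truth)
  }
  list(genotypes = g, truth = truth, paths = paths)
}

# One locus inside the planted inversion: two arrangement haplotype pools
# under strict isolation at depth da_target/(2 mu); each sample's two
# haplotype slots draw from the pools given its karyotype, with slot->pool
# assignment fixed across loci (zero recombination within the region).
simulateInversionLocus <- function(k_inv, inv, mu, L) {
  n_samples <- length(k_inv)
  n_inv_hap <- sum(k_inv)
  n_std_hap <- 2L * n_samples - n_inv_hap
  T_pool <- inv$da_target / (2 * mu)
  N_anc_pool <- (inv$N_inv + inv$N_std) / 2
  if (n_inv_hap >= 2) {
    ep_end <- c(T_pool, Inf)
    Nmat <- rbind(c(inv$N_inv, inv$N_std), c(N_anc_pool, 0))
    migl <- list(matrix(0, 2, 2), matrix(0, 2, 2))
    remap <- rbind(1:2, c(1L, 1L))
    raw <- .sim_locus_cpp(c(n_inv_hap, n_std_hap), ep_end, Nmat, migl, remap,
                          mu * L)
  } else {
    # arrangement effectively absent: single standard pool
    raw <- .sim_locus_cpp(2L * n_samples, Inf, matrix(inv$N_std, 1, 1),
                          list(matrix(0, 1, 1)), matrix(1L, 1, 1), mu * L)
    return(list(geno = raw$geno, pos = raw$pos))
  }
  # slot -> pool-row mapping, deterministic in sample order
  geno <- matrix(0L, 2L * n_samples, ncol(raw$geno))
  inv_next <- 1L; std_next <- n_inv_hap + 1L
  for (s in seq_len(n_samples)) {
    rows <- c(2L * s - 1L, 2L * s)
    k <- k_inv[s]
    take <- integer(0)
    if (k > 0) { take <- seq(inv_next, length.out = k); inv_next <- inv_next + k }
    if (k < 2) { take <- c(take, seq(std_next, length.out = 2L - k))
                 std_next <- std_next + (2L - k) }
    geno[rows, ] <- raw$geno[take, , drop = FALSE]
  }
  list(geno = geno, pos = raw$pos)
}

#' Serialize / read study ground truth
#'
#' Lossless JSON round-trip of the \code{study_truth} object written by
#' [makeStudy()]. Unknown top-level fields in a truth file are rejected.
#'
#' @param truth a \code{study_truth} list.
#' @param path JSON file path.
#' @return \code{writeTruth}: the path, invisibly. \code{readTruth}: the
#'   truth list.
#' @export
writeTruth <- function(truth, path) {
  tr <- unclass(truth)
  if (!is.null(tr$inversion))  # keep sample names: serialize as an object
    tr$inversion$karyotypes <- as.list(tr$inversion$karyotypes)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("schema_version", "preset", "populations", "n_per_pop",
               "demography", "outliers", "inversion")
  extra <- setdiff(names(tr), allowed)
  if (length(extra))
    stop("unknown truth field(s): ", paste(extra, collapse = ", "))
  if (is.null(tr$schema_version) || tr$schema_version != 1L)
    stop("unsupported truth schema version")
  if (!is.null(tr$inversion))
    tr$inversion$karyotypes <- unlist(tr$inversion$karyotypes)
  class(tr) <- "study_truth"
  tr
}
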