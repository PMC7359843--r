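#' Run a pipeline subcommand from a configuration
#'
#' Single programmatic entry point wiring the package modules into the
#' study workflow. Subcommands: \code{simulate-data} (synthetic study to
#' disk), \code{filter} (VCF + metadata through the filter chain),
#' \code{stats} (Ho, MAF spectra, pairwise FST), \code{scan-fst} (windowed
#' FST outliers, both window modes), \code{scan-rda} (partial RDA of
#' habitat conditioned on geography, loading outliers), \code{abc-simulate}
#' (reference table over a model grid), \code{abc-fit} (model choice and
#' parameter estimation for observed statistics), \code{inversion}
#' (sliding-PCA + local-PCA scan, karyotypes, arrangement statistics,
#' dating). Each run writes its artifacts plus a \code{manifest.json}
#' (resolved config, seed, package version, input paths) into the output
#' directory.
#'
#' @param subcommand one of the names above.
#' @param config path to a YAML config file, or an equivalent named list.
#'   Unknown configuration keys are an error. Common keys: \code{out_dir},
#'   \code{seed}; input keys \code{vcf}, \code{metadata}; per-subcommand
#'   settings mirror the corresponding function arguments.
#' @return invisibly, a list of produced artifact paths.
#' @export
runPipeline <- function(subcommand, config) {
  subcommands <- c("simulate-data", "filter", "stats", "scan-fst",
                   "scan-rda", "abc-simulate", "abc-fit", "inversion")
  if (!subcommand %in% subcommands)
    stop("unknown subcommand: ", subcommand)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("out_dir", "seed", "vcf", "metadata", "preset", "filters",
             "window_bp", "block_snps", "step_snps", "models", "n_sims",
             "n_loci", "n_hap", "tolerance", "stats_file", "fit_model",
             "region", "n_perm", "wide_priors", "study")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  out_dir <- cfg$out_dir %||% "divergescan-run"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  set.seed(seed)

  loadInputs <- function() {
    for (k in c("vcf", "metadata"))
      if (is.null(cfg[[k]]) || !file.exists(cfg[[k]]))
        stop("missing input file for '", k, "': ",
             if (is.null(cfg[[k]])) "(not set)" else cfg[[k]])
    readGenotypeVcf(cfg$vcf, cfg$metadata)
  }
  artifacts <- list()
  put <- function(name, writer) {
    p <- file.path(out_dir, name); writer(p); artifacts[[name]] <<- p
  }

  if (subcommand == "simulate-data") {
    sc <- do.call(studyConfig, c(list(preset = cfg$preset %||% "full-study"),
                                 cfg$study %||% list()))
    res <- makeStudy(sc, dir = out_dir)
    artifacts <- res$paths
  } else if (subcommand == "filter") {
    g <- loadInputs()
    fc <- do.call(filterConfig, cfg$filters %||% list())
    fr <- applyFilters(g, fc)
    put("filtered.vcf", function(p) writeGenotypeVcf(fr$genotypes, p))
    put("filter_report.json", function(p) writeFilterReport(fr$report, p))
  } else if (subcommand == "stats") {
    g <- loadInputs()
    put("observed_het.tsv", function(p)
      utils::write.table(observedHet(g), p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    put("maf_spectrum.tsv", function(p)
      utils::write.table(mafSpectrum(g), p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    put("pairwise_fst.tsv", function(p)
      utils::write.table(pairwiseFst(g, n_boot = 200), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
  } else if (subcommand == "scan-fst") {
    g <- loadInputs()
    comp <- wcFstPerSnp(g, grouping = sampleMeta(g)$habitat)
    put("fst_per_snp.tsv", function(p)
      utils::write.table(comp, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    wkb <- windowFst(comp, "kb", window_bp = cfg$window_bp %||% 200000)
    wsnp <- windowFst(comp, "snp", block_snps = cfg$block_snps %||% 50,
                      step_snps = cfg$step_snps %||% 5)
    put("fst_windows_kb.bed", function(p) writeWindowBed(wkb, p))
    put("fst_windows_snp.bed", function(p) writeWindowBed(wsnp, p))
  } else if (subcommand == "scan-rda") {
    g <- loadInputs()
    md <- sampleMeta(g)
    res <- partialRda(g, X = md[, "habitat", drop = FALSE],
                      Z = md[, c("latitude", "longitude", "altitude")],
                      n_perm = cfg$n_perm %||% 1000)
    out <- if (length(res$eig)) loadingOutliers(res, n_axes = 1) else
      data.frame(snp = character(), axis = integer(),
                 loading = numeric(), z = numeric())
    put("rda_outliers.tsv", function(p)
      utils::write.table(out, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    put("rda_summary.json", function(p)
      jsonlite::write_json(list(prop_variance = res$prop_variance,
                                global_p = res$global_p), p,
                           auto_unbox = TRUE, digits = NA))
  } else if (subcommand == "abc-simulate") {
    tab <- simulateReferenceTable(cfg$models %||% "all",
                                  n_sims = cfg$n_sims %||% 1000,
                                  n_loci = cfg$n_loci %||% 1000,
                                  n_hap = cfg$n_hap %||% c(40, 40),
                                  priors = defaultPriors(
                                    isTRUE(cfg$wide_priors)))
    put("reference_table.tsv", function(p)
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  } else if (subcommand == "abc-fit") {
    if (is.null(cfg$stats_file)) stop("missing input file for 'stats_file'")
    tab_file <- file.path(out_dir, "reference_table.tsv")
    if (!file.exists(tab_file)) stop("missing input file: ", tab_file)
    sims <- utils::read.table(tab_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    obs <- unlist(jsonlite::read_json(cfg$stats_file, simplifyVector = TRUE))
    mp <- abcModelChoice(obs, sims, tolerance = cfg$tolerance %||% 0.005)
    put("model_posterior.json", function(p)
      jsonlite::write_json(list(prob = as.list(mp$prob), winner = mp$winner,
                                tolerance = mp$tolerance), p,
                           auto_unbox = TRUE, digits = NA))
    fit_model <- cfg$fit_model %||% mp$winner
    pp <- abcEstimateParams(obs, sims[sims$model == fit_model, ],
                            tolerance = cfg$tolerance %||% 0.005)
    put("param_posterior.json", function(p)
      jsonlite::write_json(pp$estimates, p, auto_unbox = TRUE, digits = NA))
  } else if (subcommand == "inversion") {
    g <- loadInputs()
    sw <- slidingPca(g, window_bp = cfg$window_bp %||% 1e6,
                     step_bp = (cfg$window_bp %||% 1e6) / 10)
    put("sliding_pca.tsv", function(p)
      utils::write.table(sw, p, sep = "\t", quote = FALSE, row.names = FALSE))
    lp <- localPcaMds(g, block_snps = cfg$block_snps %||% 100)
    put("local_pca_mds.tsv", function(p)
      utils::write.table(lp, p, sep = "\t", quote = FALSE, row.names = FALSE))
    region <- cfg$region
    if (is.null(region)) {
      calls <- callInversions(g, block_snps = cfg$block_snps %||% 100)
      called <- Filter(function(x) x$status == "called", calls)
      if (length(called))
        region <- called[[which.max(vapply(called, function(x)
          x$n_blocks, numeric(1)))]]$region
    }
    if (!is.null(region)) {
      kc <- assignKaryotypes(g, region)
      put("karyotypes.tsv", function(p)
        utils::write.table(data.frame(sample_id = colnames(g),
                                      karyotype = as.character(kc$karyotype)),
                           p, sep = "\t", quote = FALSE, row.names = FALSE))
      if (kc$status == "called") {
        st <- arrangementStats(g, region, kc$karyotype)
        dt <- tryCatch(dateInversion(st$da), error = function(e) NULL)
        put("inversion_call.json", function(p)
          jsonlite::write_json(list(
            region = region, counts = as.list(kc$counts),
            inv_freq = kc$inv_freq,
            inv_freq_by_pop = as.list(kc$inv_freq_by_pop),
            hwe_chisq = kc$hwe$chisq, hwe_p = kc$hwe$p_value,
            fst_in = st$fst_in, fst_out = st$fst_out, dxy = st$dxy,
            da = st$da,
            age_generations = dt$age_generations,
            age_years = dt$age_years), p, auto_unbox = TRUE, digits = NA))
      }
    }
  }

  manifest <- list(subcommand = subcommand, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("DivergeScan")),
                   config = cfg, artifacts = artifacts,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(artifacts)
}

writeWindowBed <- function(w, path) {
  utils::write.table(data.frame(w$chrom, w$start - 1L, w$end, w$fst,
                                w$n_snps, w$outlier),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
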