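#' Read a sample metadata sheet
#'
#' Tab-separated file with header columns \code{sample_id}, \code{population},
#' and optionally \code{region}, \code{habitat}, \code{latitude},
#' \code{longitude}, \code{altitude}. Region and habitat are derived from the
#' population code when not given.
#'
#' @param path TSV file path.
#' @return data.frame of sample metadata.
#' @export
readSampleMeta <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  completeSampleMeta(md)
}

#' Read a VCF into a GenotypeData object
#'
#' Parses a VCF v4.x with diploid GT fields into ALT-allele dosages.
#' Non-biallelic records are skipped with a warning reporting the count;
#' genotypes \code{./.} become \code{NA}. Per-variant mean depth is taken
#' from the DP genotype field when present, otherwise from an INFO DP field,
#' otherwise \code{NA}.
#'
#' @param path VCF file (plain text or gzipped).
#' @param metadata_path sample metadata TSV covering every VCF sample; a VCF
#'   sample absent from the metadata is an error.
#' @return a [GenotypeData-class] object.
#' @export
readGenotypeVcf <- function(path, metadata_path) {
  md <- readSampleMeta(metadata_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bi <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!bi))
    warning(sum(!bi), " non-biallelic record(s) skipped")
  v <- v[bi, ]
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt)
  missing_md <- setdiff(vcf_samples, md$sample_id)
  if (length(missing_md))
    stop("samples in VCF absent from metadata: ",
         paste(missing_md, collapse = ", "))
  md <- md[match(vcf_samples, md$sample_id), , drop = FALSE]
  # dosage from GT: count of '1' alleles; any missing allele -> NA
  gtc <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(gtc), ncol(gtc), dimnames = dimnames(gtc))
  dos[gtc == "0/0"] <- 0L
  dos[gtc == "0/1" | gtc == "1/0"] <- 1L
  dos[gtc == "1/1"] <- 2L
  depth <- rep(NA_real_, nrow(gtc))
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- rowMeans(dp, na.rm = TRUE)
  } else {
    info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))
    if (!all(is.na(info_dp))) depth <- info_dp / ncol(gtc)
  }
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         depth = depth, stringsAsFactors = FALSE)
  makeGenotypeData(dos, variants, md)
}

#' Write a GenotypeData object as VCF v4.2
#'
#' Emits one biallelic record per variant with GT (and DP when depth is
#' known) fields; missing dosages become \code{./.}.
#'
#' @param g a [GenotypeData-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGenotypeVcf <- function(g, path) {
  vt <- variantTable(g)
  d <- dosages(g)
  gtxt <- matrix("./.", nrow(d), ncol(d))
  gtxt[!is.na(d) & d == 0L] <- "0/0"
  gtxt[!is.na(d) & d == 1L] <- "0/1"
  gtxt[!is.na(d) & d == 2L] <- "1/1"
  has_dp <- !all(is.na(vt$depth))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=DivergeScan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               if (has_dp)
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
  fmt <- if (has_dp) "GT:DP" else "GT"
  body <- gtxt
  if (has_dp) {
    dp <- ifelse(is.na(vt$depth), ".", as.character(round(vt$depth)))
    body <- matrix(paste(gtxt, rep(dp, ncol(gtxt)), sep = ":"),
                   nrow(gtxt), ncol(gtxt))
  }
  lines <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".",
                 fmt, apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a sample metadata sheet
#' @param samples data.frame as returned by [sampleMeta()].
#' @param path output TSV path.
#' @export
writeSampleMeta <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Post-genotyping filter configuration
#'
#' Defaults reproduce the standard RAD post-genotyping chain: per-variant
#' mean depth within \[10, 100\]; variant call rate >= 0.8; variants with
#' observed heterozygosity >= 0.65 within either region removed (paralog
#' guard); samples below 85\% call rate removed; of each sample pair with
#' genomic relatedness >= 0.35 one member removed; populations capped at 60
#' randomly chosen samples; monomorphic variants dropped. Set any threshold
#' to \code{NULL} to disable that rule.
#'
#' @param min_depth,max_depth per-variant mean read depth bounds.
#' @param min_variant_call_rate minimum fraction of genotyped samples per variant.
#' @param max_het_region maximum within-region observed heterozygosity.
#' @param min_sample_call_rate minimum fraction of genotyped variants per sample.
#' @param max_relatedness GRM threshold above which one of a pair is removed.
#' @param max_per_population random cap on samples per population.
#' @param drop_monomorphic drop variants with no remaining variation.
#' @return a list of class \code{filter_config}.
#' @export
filterConfig <- function(min_depth = 10, max_depth = 100,
                         min_variant_call_rate = 0.8,
                         max_het_region = 0.65,
                         min_sample_call_rate = 0.85,
                         max_relatedness = 0.35,
                         max_per_population = 60,
                         drop_monomorphic = TRUE) {
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 min_variant_call_rate = min_variant_call_rate,
                 max_het_region = max_het_region,
                 min_sample_call_rate = min_sample_call_rate,
                 max_relatedness = max_relatedness,
                 max_per_population = max_per_population,
                 drop_monomorphic = drop_monomorphic),
            class = "filter_config")
}

#' Apply the post-genotyping filter chain
#'
#' Rules are applied in the order listed in [filterConfig()]. The relatedness
#' rule iterates over pairs in decreasing relatedness; the member with more
#' missing genotypes is removed (ties broken by sample id). The population
#' cap samples at random from the session RNG, so set a seed beforehand for
#' reproducibility.
#'
#' @param g a [GenotypeData-class] object.
#' @param cfg a [filterConfig()] list.
#' @return list with elements \code{genotypes} (filtered GenotypeData) and
#'   \code{report} (a \code{FilterReport} data.frame: one row per rule with
#'   counts of variants and samples removed, in application order).
#' @export
applyFilters <- function(g, cfg = filterConfig()) {
  stopifnot(inherits(cfg, "filter_config"))
  steps <- character(); rm_var <- integer(); rm_smp <- integer()
  note <- function(step, dv, ds) {
    steps <<- c(steps, step); rm_var <<- c(rm_var, dv); rm_smp <<- c(rm_smp, ds)
  }
  check_empty <- function(step) {
    if (nrow(g) == 0L || ncol(g) == 0L)
      stop("all data filtered out at step: ", step)
  }

  if (!is.null(cfg$min_depth) || !is.null(cfg$max_depth)) {
    dep <- variantTable(g)$depth
    keep <- rep(TRUE, nrow(g))
    known <- !is.na(dep)
    if (!is.null(cfg$min_depth)) keep[known & dep < cfg$min_depth] <- FALSE
    if (!is.null(cfg$max_depth)) keep[known & dep > cfg$max_depth] <- FALSE
    note("depth", sum(!keep), 0L)
    g <- g[keep, ]; check_empty("depth")
  }

  if (!is.null(cfg$min_variant_call_rate)) {
    cr <- rowMeans(!is.na(dosages(g)))
    keep <- cr >= cfg$min_variant_call_rate
    note("variant_call_rate", sum(!keep), 0L)
    g <- g[keep, ]; check_empty("variant_call_rate")
  }

  if (!is.null(cfg$max_het_region)) {
    d <- dosages(g)
    reg <- sampleMeta(g)$region
    bad <- rep(FALSE, nrow(g))
    for (r in unique(reg[!is.na(reg)])) {
      dr <- d[, reg == r & !is.na(reg), drop = FALSE]
      ho <- rowSums(dr == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(dr)), 1L)
      bad <- bad | (ho >= cfg$max_het_region & rowSums(!is.na(dr)) > 0)
    }
    note("excess_heterozygosity", sum(bad), 0L)
    g <- g[!bad, ]; check_empty("excess_heterozygosity")
  }

  if (!is.null(cfg$min_sample_call_rate)) {
    cr <- colMeans(!is.na(dosages(g)))
    keep <- cr >= cfg$min_sample_call_rate
    note("sample_call_rate", 0L, sum(!keep))
    g <- g[, keep]; check_empty("sample_call_rate")
  }

  if (!is.null(cfg$max_relatedness) && ncol(g) >= 2L) {
    grm <- relatednessMatrix(g)
    nmiss <- colSums(is.na(dosages(g)))
    drop <- character()
    pairs <- which(upper.tri(grm) & grm >= cfg$max_relatedness, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(grm[pairs], decreasing = TRUE)
      pairs <- pairs[ord, , drop = FALSE]
      ids <- colnames(g)
      for (i in seq_len(nrow(pairs))) {
        a <- ids[pairs[i, 1]]; b <- ids[pairs[i, 2]]
        if (a %in% drop || b %in% drop) next
        pick <- if (nmiss[a] > nmiss[b]) a
                else if (nmiss[b] > nmiss[a]) b
                else max(a, b)
        drop <- c(drop, pick)
      }
    }
    note("relatedness", 0L, length(drop))
    g <- g[, !colnames(g) %in% drop]; check_empty("relatedness")
  }

  if (!is.null(cfg$max_per_population)) {
    pop <- populations(g)
    keep <- unlist(lapply(split(seq_len(ncol(g)), pop), function(ix) {
      if (length(ix) > cfg$max_per_population)
        sort(sample(ix, cfg$max_per_population)) else ix
    }), use.names = FALSE)
    note("population_cap", 0L, ncol(g) - length(keep))
    g <- g[, sort(keep)]; check_empty("population_cap")
  }

  if (isTRUE(cfg$drop_monomorphic)) {
    d <- dosages(g)
    n <- rowSums(!is.na(d)); s <- rowSums(d, na.rm = TRUE)
    keep <- n > 0 & s > 0 & s < 2 * n
    note("monomorphic", sum(!keep), 0L)
    g <- g[keep, ]; check_empty("monomorphic")
  }

  report <- data.frame(step = steps, variants_removed = rm_var,
                       samples_removed = rm_smp, stringsAsFactors = FALSE)
  class(report) <- c("FilterReport", class(report))
  list(genotypes = g, report = report)
}

#' Write a filter report as JSON
#' @param report FilterReport from [applyFilters()].
#' @param path output JSON path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
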