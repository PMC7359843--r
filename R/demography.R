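#' Enumerate the twenty two-population divergence model variants
#'
#' Six base scenarios — PAN (panmixia), EQ (two-deme equilibrium island
#' model), SI (strict isolation), IM (isolation with migration), AM (ancient
#' migration: gene flow from the split until it stops), SC (secondary
#' contact: isolation then renewed gene flow) — each optionally with
#' beta-distributed heterogeneity of per-locus effective size (Nhetero)
#' and, for models with migration, of per-locus migration (Mhetero):
#' 4 variants for EQ/IM/AM/SC and 2 for PAN/SI, twenty in total.
#'
#' @return data.frame: base, n_hetero, m_hetero, name.
#' @export
enumerateModels <- function() {
  bases <- c("PAN", "EQ", "SI", "IM", "AM", "SC")
  rows <- list()
  for (b in bases) {
    for (nh in c(FALSE, TRUE)) {
      mh_opts <- if (b %in% c("PAN", "SI")) FALSE else c(FALSE, TRUE)
      for (mh in mh_opts)
        rows[[length(rows) + 1L]] <- data.frame(
          base = b, n_hetero = nh, m_hetero = mh,
          name = paste0(b, "_N", if (nh) "hetero" else "homo",
                        if (!b %in% c("PAN", "SI"))
                          paste0("M", if (mh) "hetero" else "homo") else ""),
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default prior set for the divergence models
#'
#' Effective sizes and split times are log-uniform; epoch fractions, scaled
#' migration and beta hyper-parameters are uniform. These bounds are
#' package defaults, configurable per parameter.
#'
#' @param wide widen the scaled-migration prior from \[0, 40\] to \[0, 200\].
#' @return data.frame: param, dist ("unif"/"logunif"), lower, upper.
#' @export
defaultPriors <- function(wide = FALSE) {
  m_hi <- if (wide) 200 else 40
  pr <- rbind(
    data.frame(param = c("N_anc", "N_pop1", "N_pop2"), dist = "logunif",
               lower = 1e2, upper = 1e6),
    data.frame(param = "T_split", dist = "logunif", lower = 1e3, upper = 3e6),
    data.frame(param = c("frac_T_am", "frac_T_sc"), dist = "unif",
               lower = 0.01, upper = 0.99),
    data.frame(param = c("M12", "M21"), dist = "unif", lower = 0, upper = m_hi),
    data.frame(param = c("a_N", "b_N", "a_M", "b_M"), dist = "unif",
               lower = 0.1, upper = 10))
  pr$dist <- as.character(pr$dist)
  pr
}

drawPrior <- function(priors, param) {
  row <- priors[priors$param == param, ]
  if (nrow(row) != 1L) stop("prior not found for ", param)
  if (row$lower >= row$upper) stop("prior bounds invalid for ", param)
  if (row$dist == "logunif")
    exp(stats::runif(1, log(row$lower), log(row$upper)))
  else stats::runif(1, row$lower, row$upper)
}

#' Draw model parameters from the prior
#'
#' Respects the model structure: PAN has a single size and no times; EQ has
#' no split time; SI/PAN have no migration; AM and SC times are drawn as
#' fractions of the split time so that 0 < T_am, T_sc < T_split always
#' holds. Heterogeneity hyper-parameters are drawn only for hetero variants.
#'
#' @param model one row of [enumerateModels()] (or a model name).
#' @param priors prior table as from [defaultPriors()].
#' @param mu per-bp per-generation mutation rate.
#' @param locus_bp locus length in bp.
#' @param generation_time years per generation.
#' @return named list of class \code{demographic_params}.
#' @export
samplePriors <- function(model, priors = defaultPriors(), mu = 1e-8,
                         locus_bp = 85, generation_time = 2.3) {
  model <- resolveModel(model)
  base <- model$base
  p <- list(base = base, n_hetero = model$n_hetero, m_hetero = model$m_hetero,
            mu = mu, locus_bp = locus_bp, generation_time = generation_time,
            N_anc = NA_real_, N_pop1 = NA_real_, N_pop2 = NA_real_,
            T_split = NA_real_, T_am = NA_real_, T_sc = NA_real_,
            M12 = 0, M21 = 0, a_N = NA_real_, b_N = NA_real_,
            a_M = NA_real_, b_M = NA_real_)
  if (base == "PAN") {
    p$N_pop1 <- p$N_pop2 <- drawPrior(priors, "N_pop1")
  } else {
    p$N_pop1 <- drawPrior(priors, "N_pop1")
    p$N_pop2 <- drawPrior(priors, "N_pop2")
  }
  if (!base %in% c("PAN", "EQ")) {
    p$N_anc <- drawPrior(priors, "N_anc")
    p$T_split <- drawPrior(priors, "T_split")
  }
  if (base == "AM") p$T_am <- drawPrior(priors, "frac_T_am") * p$T_split
  if (base == "SC") p$T_sc <- drawPrior(priors, "frac_T_sc") * p$T_split
  if (!base %in% c("PAN", "SI")) {
    p$M12 <- drawPrior(priors, "M12")
    p$M21 <- drawPrior(priors, "M21")
  }
  if (model$n_hetero) { p$a_N <- drawPrior(priors, "a_N")
                        p$b_N <- drawPrior(priors, "b_N") }
  if (model$m_hetero) { p$a_M <- drawPrior(priors, "a_M")
                        p$b_M <- drawPrior(priors, "b_M") }
  structure(p, class = "demographic_params")
}

resolveModel <- function(model) {
  if (is.character(model)) {
    tab <- enumerateModels()
    hit <- tab[tab$name == model | tab$base == model, ]
    if (!nrow(hit)) stop("unknown model: ", model)
    model <- hit[1, ]
  }
  as.list(model)
}

validateParams <- function(params) {
  with(params, {
    if (any(c(N_pop1, N_pop2) <= 0, na.rm = TRUE)) stop("sizes must be > 0")
    if (base %in% c("SI", "IM", "AM", "SC")) {
      if (is.na(T_split) || T_split <= 0) stop("T_split must be > 0")
      if (is.na(N_anc) || N_anc <= 0) stop("N_anc must be > 0")
    }
    if (base == "AM" && (is.na(T_am) || T_am <= 0 || T_am >= T_split))
      stop("AM requires 0 < T_am < T_split")
    if (base == "SC" && (is.na(T_sc) || T_sc <= 0 || T_sc >= T_split))
      stop("SC requires 0 < T_sc < T_split")
    if (any(c(M12, M21) < 0)) stop("migration must be >= 0")
    if (isTRUE(n_hetero) && any(c(a_N, b_N) <= 0)) stop("beta hyper-params must be > 0")
    if (isTRUE(m_hetero) && any(c(a_M, b_M) <= 0)) stop("beta hyper-params must be > 0")
  })
  invisible(params)
}

# Backward migration rate per lineage per generation from scaled M = 4*N0*m,
# with N0 the recipient deme's size (M12 = migrants into pop1 from pop2).
backwardRates <- function(params) {
  c(m12 = params$M12 / (4 * params$N_pop1),
    m21 = params$M21 / (4 * params$N_pop2))
}

# Epoch structure for the two-population models (generations, backwards).
modelEpochs <- function(params) {
  base <- params$base
  m <- backwardRates(params)
  mig0 <- matrix(0, 2, 2)
  # migM[d, j]: backward rate of a lineage in deme d jumping to deme j
  migM <- matrix(0, 2, 2); migM[1, 2] <- m[["m12"]]; migM[2, 1] <- m[["m21"]]
  merge2to1 <- c(1L, 1L)
  Nrow <- c(params$N_pop1, params$N_pop2)
  anc <- c(params$N_anc, 0)
  ep <- switch(base,
    PAN = list(end = Inf, N = matrix(params$N_pop1, 1, 1),
               mig = list(matrix(0, 1, 1)), remap = matrix(1L, 1, 1),
               n_demes = 1L),
    EQ = list(end = Inf, N = matrix(Nrow, 1, 2),
              mig = list(migM), remap = matrix(1:2, 1, 2), n_demes = 2L),
    SI = list(end = c(params$T_split, Inf),
              N = rbind(Nrow, anc),
              mig = list(mig0, mig0),
              remap = rbind(1:2, merge2to1), n_demes = 2L),
    IM = list(end = c(params$T_split, Inf),
              N = rbind(Nrow, anc),
              mig = list(migM, mig0),
              remap = rbind(1:2, merge2to1), n_demes = 2L),
    AM = list(end = c(params$T_am, params$T_split, Inf),
              N = rbind(Nrow, Nrow, anc),
              mig = list(mig0, migM, mig0),
              remap = rbind(1:2, 1:2, merge2to1), n_demes = 2L),
    SC = list(end = c(params$T_sc, params$T_split, Inf),
              N = rbind(Nrow, Nrow, anc),
              mig = list(migM, mig0, mig0),
              remap = rbind(1:2, 1:2, merge2to1), n_demes = 2L),
    stop("unknown base model: ", base))
  ep
}

#' Simulate a multilocus dataset under a divergence model
#'
#' Backwards-time structured coalescent over independent loci with
#' infinite-sites mutation (no intra-locus recombination). With
#' \code{n_hetero}, each locus's effective sizes are multiplied by an
#' independent Beta(a_N, b_N) draw rescaled to mean 1; with \code{m_hetero},
#' per-locus migration rates are scaled likewise (draws near zero emulate
#' barrier loci). Rescaling keeps the genome-average size and migration at
#' their nominal values.
#'
#' @param model a model name or a row of [enumerateModels()].
#' @param params parameters from [samplePriors()] (validated before use;
#'   non-viable parameters are an error).
#' @param n_loci number of independent loci (default 1000).
#' @param n_hap haplotypes sampled per population (default 40 each, i.e.
#'   20 diploids).
#' @return object of class \code{haplotype_dataset}: list of loci, each with
#'   \code{geno} (haplotypes x segregating sites, 0/1), \code{pos} (bp
#'   positions within the locus), \code{pop} (1/2 per haplotype); attributes
#'   carry the model, parameters and locus length.
#' @export
simulateDataset <- function(model, params, n_loci = 1000, n_hap = c(40, 40)) {
  model <- resolveModel(model)
  stopifnot(identical(model$base, params$base))
  validateParams(params)
  ep <- modelEpochs(params)
  mu_locus <- params$mu * params$locus_bp
  pan <- ep$n_demes == 1L
  n_per_deme <- if (pan) sum(n_hap) else as.integer(n_hap)
  pop <- rep(1:2, times = n_hap)
  mean_N <- if (isTRUE(params$n_hetero)) params$a_N / (params$a_N + params$b_N) else 1
  mean_M <- if (isTRUE(params$m_hetero)) params$a_M / (params$a_M + params$b_M) else 1
  loci <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    Nl <- ep$N
    migl <- ep$mig
    if (isTRUE(params$n_hetero))
      Nl <- Nl * (stats::rbeta(1, params$a_N, params$b_N) / mean_N)
    if (isTRUE(params$m_hetero)) {
      w <- stats::rbeta(1, params$a_M, params$b_M) / mean_M
      migl <- lapply(migl, function(mm) mm * w)
    }
    sim <- .sim_locus_cpp(n_per_deme, ep$end, Nl, migl,
                          ep$remap, mu_locus)
    pos <- 1 + sim$pos * (params$locus_bp - 1)
    o <- order(pos)
    loci[[l]] <- list(geno = sim$geno[, o, drop = FALSE], pos = pos[o],
                      pop = pop)
  }
  structure(loci, class = "haplotype_dataset",
            model = model, params = params, locus_bp = params$locus_bp,
            n_hap = n_hap)
}

#' Summary-statistic vector for ABC
#'
#' Across loci: mean and SD of within-population nucleotide diversity
#' (pi1, pi2), Watterson's theta (thetaW1, thetaW2), between-population
#' diversity dxy, net divergence Da = dxy - (pi1 + pi2)/2, a per-locus FST
#' (1 - mean within-pi / total pi), and the Wakeley-Hey site classes:
#' private polymorphisms sx1 and sx2, shared polymorphisms ss, fixed
#' differences sf. Plus the Pearson correlation of pi1 with pi2 across loci.
#' All diversities are per bp. The vector has fixed length and ordering;
#' the SD of a constant is 0 and an undefined correlation is reported as 0.
#'
#' @param dataset a \code{haplotype_dataset} from [simulateDataset()].
#' @return named numeric vector (23 statistics).
#' @export
summarizeDataset <- function(dataset) {
  L <- attr(dataset, "locus_bp")
  per <- t(vapply(dataset, function(locus) locusStats(locus, L),
                  numeric(11)))
  colnames(per) <- c("pi1", "pi2", "thetaW1", "thetaW2", "dxy", "da",
                     "fst", "sx1", "sx2", "ss", "sf")
  mn <- colMeans(per, na.rm = TRUE)
  sdv <- apply(per, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else stats::sd(v)
  })
  r <- suppressWarnings(stats::cor(per[, "pi1"], per[, "pi2"],
                                   use = "complete.obs"))
  if (is.na(r)) r <- 0
  mn["fst"][is.na(mn["fst"])] <- 0
  out <- c(stats::setNames(mn, paste0(colnames(per), "_mean")),
           stats::setNames(sdv, paste0(colnames(per), "_sd")),
           cor_pi1_pi2 = r)
  out[is.na(out)] <- 0
  out
}

# Per-locus statistics from a 0/1 haplotype matrix with population labels.
locusStats <- function(locus, L) {
  g <- locus$geno; pop <- locus$pop
  i1 <- pop == 1L; i2 <- pop == 2L
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need at least two haplotypes per population")
  S <- ncol(g)
  if (S == 0)
    return(c(0, 0, 0, 0, 0, 0, NA_real_, 0, 0, 0, 0))
  c1 <- colSums(g[i1, , drop = FALSE]); c2 <- colSums(g[i2, , drop = FALSE])
  p1 <- c1 / n1; p2 <- c2 / n2
  pi1 <- sum(2 * c1 * (n1 - c1) / (n1 * (n1 - 1))) / L
  pi2 <- sum(2 * c2 * (n2 - c2) / (n2 * (n2 - 1))) / L
  a1 <- sum(1 / seq_len(n1 - 1)); a2 <- sum(1 / seq_len(n2 - 1))
  S1 <- sum(c1 > 0 & c1 < n1); S2 <- sum(c2 > 0 & c2 < n2)
  thetaW1 <- S1 / (a1 * L); thetaW2 <- S2 / (a2 * L)
  dxy <- sum(p1 * (1 - p2) + p2 * (1 - p1)) / L
  da <- dxy - (pi1 + pi2) / 2
  nT <- n1 + n2; cT <- c1 + c2
  piT <- sum(2 * cT * (nT - cT) / (nT * (nT - 1))) / L
  fst <- if (piT > 0) 1 - ((pi1 + pi2) / 2) / piT else NA_real_
  poly1 <- c1 > 0 & c1 < n1; poly2 <- c2 > 0 & c2 < n2
  mono1 <- !poly1; mono2 <- !poly2
  sx1 <- sum(poly1 & mono2)
  sx2 <- sum(poly2 & mono1)
  ss <- sum(poly1 & poly2)
  sf <- sum(mono1 & mono2 & ((c1 == 0 & c2 == n2) | (c1 == n1 & c2 == 0)))
  c(pi1, pi2, thetaW1, thetaW2, dxy, da, fst, sx1, sx2, ss, sf)
}

#' Build an ABC reference table of simulations
#'
#' Draws parameters from the prior for each listed model, simulates a
#' dataset and records the summary-statistic vector, one row per
#' simulation.
#'
#' @param models character vector of model names (see [enumerateModels()]),
#'   or "all" for the full set of twenty.
#' @param n_sims simulations per model.
#' @param n_loci,n_hap forwarded to [simulateDataset()].
#' @param priors prior table (see [defaultPriors()]).
#' @param mu,locus_bp mutation rate and locus length.
#' @param keep_params record the drawn parameters alongside the statistics.
#' @return data.frame: model, (parameters), statistic columns.
#' @export
simulateReferenceTable <- function(models, n_sims, n_loci = 1000,
                                   n_hap = c(40, 40),
                                   priors = defaultPriors(),
                                   mu = 1e-8, locus_bp = 85,
                                   keep_params = TRUE) {
  if (identical(models, "all")) models <- enumerateModels()$name
  par_cols <- c("N_anc", "N_pop1", "N_pop2", "T_split", "T_am", "T_sc",
                "M12", "M21", "a_N", "b_N", "a_M", "b_M")
  rows <- vector("list", length(models) * n_sims)
  k <- 0L
  for (m in models) {
    for (i in seq_len(n_sims)) {
      pp <- samplePriors(m, priors, mu = mu, locus_bp = locus_bp)
      ds <- simulateDataset(m, pp, n_loci = n_loci, n_hap = n_hap)
      st <- summarizeDataset(ds)
      k <- k + 1L
      row <- data.frame(model = m, stringsAsFactors = FALSE)
      if (keep_params)
        for (pc in par_cols) row[[pc]] <- as.numeric(pp[[pc]])
      rows[[k]] <- cbind(row, as.data.frame(as.list(st)))
    }
  }
  do.call(rbind, rows)
}

#' Export a dataset in an ms-like text format (debugging aid)
#' @param dataset a \code{haplotype_dataset}.
#' @param path output file.
#' @export
writeMsLike <- function(dataset, path) {
  con <- file(path, "w"); on.exit(close(con))
  L <- attr(dataset, "locus_bp")
  for (locus in dataset) {
    writeLines("//", con)
    writeLines(paste("segsites:", ncol(locus$geno)), con)
    writeLines(paste("positions:",
                     paste(sprintf("%.6f", locus$pos / L), collapse = " ")), con)
    writeLines(apply(locus$geno, 1, paste, collapse = ""), con)
  }
  invisible(path)
}
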