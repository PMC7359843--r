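#' ABC model choice by rejection and multinomial logistic regression
#'
#' Summary statistics are standardized by the reference table's median
#' absolute deviation; the tolerance fraction of simulations closest to the
#' observed vector in Euclidean distance is retained. Model posterior
#' probabilities come from a weighted multinomial logistic regression of the
#' model label on the retained statistics, evaluated at the observed point
#' (Epanechnikov weights on distance); plain rejection proportions are the
#' fallback when the regression cannot be fitted or when
#' \code{method = "rejection"}. With \code{hierarchical = TRUE} the base
#' scenario family is chosen first by aggregating variants, then the
#' heterogeneity variant within the winning family.
#'
#' @param observed named numeric summary-statistic vector
#'   (see [summarizeDataset()]).
#' @param sims reference table from [simulateReferenceTable()] (column
#'   \code{model} plus the statistic columns).
#' @param tolerance fraction of simulations retained (default 0.005, with a
#'   floor of 100 rows); fewer than 50 retained rows is an error.
#' @param method "mnlogistic" (default) or "rejection".
#' @param hierarchical choose base family first, then variant.
#' @return list of class \code{model_posterior}: prob (named, sums to 1),
#'   winner, tolerance, n_accepted, method.
#' @export
abcModelChoice <- function(observed, sims, tolerance = 0.005,
                           method = c("mnlogistic", "rejection"),
                           hierarchical = FALSE) {
  method <- match.arg(method)
  if (hierarchical) {
    base_sims <- sims
    base_sims$model <- sub("_.*$", "", sims$model)
    top <- abcModelChoice(observed, base_sims, tolerance, method,
                          hierarchical = FALSE)
    fam <- top$winner
    within <- abcModelChoice(observed, sims[grepl(paste0("^", fam, "_"),
                                                  sims$model) |
                                              sims$model == fam, ],
                             tolerance, method, hierarchical = FALSE)
    prob <- within$prob * top$prob[[fam]]
    other <- top$prob[names(top$prob) != fam]
    res <- structure(list(prob = c(prob, other), winner = within$winner,
                          tolerance = tolerance,
                          n_accepted = within$n_accepted, method = method,
                          family_prob = top$prob),
                     class = "model_posterior")
    return(res)
  }
  std <- standardizeStats(observed, sims)
  acc <- abcReject(std$obs, std$stats, tolerance)
  models <- factor(sims$model[acc$idx])
  if (nlevels(models) == 1L) {
    prob <- stats::setNames(1, levels(models))
  } else if (method == "mnlogistic") {
    prob <- tryCatch({
      dat <- as.data.frame(std$stats[acc$idx, , drop = FALSE])
      dat$.model <- models
      fit <- nnet::multinom(.model ~ ., data = dat, weights = acc$weights,
                            trace = FALSE, maxit = 500, MaxNWts = 5000)
      newd <- as.data.frame(as.list(std$obs))
      pr <- stats::predict(fit, newdata = newd, type = "probs")
      if (is.null(dim(pr))) {
        if (length(pr) == 1)  # binomial case returns P(second level)
          pr <- stats::setNames(c(1 - pr, pr), levels(models))
      }
      pr
    }, error = function(e) {
      warning("multinomial regression failed (", conditionMessage(e),
              "); falling back to rejection proportions")
      NULL
    })
    if (is.null(prob))
      prob <- prop.table(table(models))
  } else {
    prob <- prop.table(table(models))
  }
  prob <- stats::setNames(as.numeric(prob), names(prob))
  # every candidate model appears, even at probability 0
  all_models <- sort(unique(sims$model))
  full <- stats::setNames(numeric(length(all_models)), all_models)
  full[names(prob)] <- pmax(prob, 0)
  full <- full / sum(full)
  structure(list(prob = full, winner = names(full)[which.max(full)],
                 tolerance = tolerance, n_accepted = length(acc$idx),
                 method = method),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("ABC model posterior (tolerance", x$tolerance, ",",
      x$n_accepted, "accepted)\n")
  print(round(sort(x$prob, decreasing = TRUE), 4))
  cat("winner:", x$winner, "\n")
  invisible(x)
}

standardizeStats <- function(observed, sims) {
  stat_cols <- intersect(names(observed), colnames(sims))
  if (length(stat_cols) < 2) stop("observed and sims share too few statistics")
  S <- as.matrix(sims[, stat_cols, drop = FALSE])
  mads <- apply(S, 2, stats::mad)
  mads[mads == 0 | is.na(mads)] <- apply(S, 2, stats::sd)[mads == 0 | is.na(mads)]
  keep <- is.finite(mads) & mads > 0
  S <- sweep(S[, keep, drop = FALSE], 2, mads[keep], "/")
  obs <- observed[stat_cols][keep] / mads[keep]
  list(stats = S, obs = obs)
}

abcReject <- function(obs, stats, tolerance) {
  d2 <- colSums((t(stats) - obs)^2)
  n_keep <- max(ceiling(tolerance * nrow(stats)), min(100, nrow(stats)))
  if (n_keep < 50) stop("tolerance retains fewer than 50 simulations")
  ord <- order(d2)
  idx <- ord[seq_len(n_keep)]
  dmax <- sqrt(d2[idx[n_keep]])
  w <- 1 - (sqrt(d2[idx]) / max(dmax, .Machine$double.eps))^2  # Epanechnikov
  w[w <= 0] <- .Machine$double.eps
  list(idx = idx, dist = sqrt(d2[idx]), weights = w)
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Rejection on MAD-standardized statistics followed by weighted local-linear
#' regression of each parameter on the statistics (Beaumont-style),
#' evaluated at the observed point. Strictly positive parameters are
#' regressed on the log scale and back-transformed. If the regression is
#' rank-deficient the plain rejection sample is used with a warning. The
#' prior-overlap diagnostic is the fraction of (weighted) posterior mass
#' inside the central 50\% interval of the prior sample; a posterior
#' matching the prior sits near 0.5, so values far from 0.5 flag a
#' posterior genuinely updated away from the prior.
#'
#' @param observed named numeric statistic vector.
#' @param sims reference table for a single model, parameters included.
#' @param tolerance retained fraction (floor 100; < 50 is an error).
#' @param params parameter columns to estimate (default: those present with
#'   any variation).
#' @return list of class \code{param_posterior}: per-parameter median,
#'   ci95 low/high, prior-overlap, differentiated flag; plus the adjusted
#'   posterior draws and weights.
#' @export
abcEstimateParams <- function(observed, sims, tolerance = 0.005,
                              params = NULL) {
  par_all <- c("N_anc", "N_pop1", "N_pop2", "T_split", "T_am", "T_sc",
               "M12", "M21", "a_N", "b_N", "a_M", "b_M")
  if (is.null(params)) {
    params <- intersect(par_all, colnames(sims))
    params <- params[vapply(params, function(p) {
      v <- sims[[p]]; length(unique(v[!is.na(v)])) > 1
    }, logical(1))]
  }
  if (!length(params)) stop("no estimable parameters in sims")
  std <- standardizeStats(observed, sims)
  acc <- abcReject(std$obs, std$stats, tolerance)
  X <- std$stats[acc$idx, , drop = FALSE]
  Xc <- sweep(X, 2, std$obs)  # regression at observed point = intercept
  out <- list(); draws <- list()
  for (p in params) {
    v <- sims[[p]][acc$idx]
    pos <- all(v > 0, na.rm = TRUE)
    y <- if (pos) log(v) else v
    adj <- tryCatch({
      fit <- stats::lm.wfit(cbind(1, Xc), y, acc$weights)
      if (fit$rank < ncol(Xc) + 1)
        stop("rank-deficient local-linear regression")
      fit$coefficients[1] + fit$residuals
    }, error = function(e) {
      warning("local-linear adjustment failed for ", p, " (",
              conditionMessage(e), "); using rejection sample")
      y
    })
    post <- if (pos) exp(adj) else adj
    qs <- weightedQuantile(post, acc$weights, c(0.025, 0.5, 0.975))
    prior <- sims[[p]]
    pq <- stats::quantile(prior, c(0.25, 0.75), na.rm = TRUE)
    overlap <- sum(acc$weights * (post >= pq[1] & post <= pq[2])) /
      sum(acc$weights)
    out[[p]] <- data.frame(param = p, median = qs[2], ci_low = qs[1],
                           ci_high = qs[3], prior_overlap = overlap,
                           differentiated = abs(overlap - 0.5) >= 0.2,
                           stringsAsFactors = FALSE)
    draws[[p]] <- post
  }
  structure(list(estimates = do.call(rbind, out), draws = draws,
                 weights = acc$weights, tolerance = tolerance,
                 n_accepted = length(acc$idx)),
            class = "param_posterior")
}

weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' @export
print.param_posterior <- function(x, ...) {
  cat("ABC parameter posterior (", x$n_accepted, "accepted )\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Convert generations to years
#' @param t_generations time in generations (>= 0).
#' @param generation_time years per generation (default 2.3).
#' @return years.
#' @export
gensToYears <- function(t_generations, generation_time = 2.3) {
  stopifnot(all(t_generations >= 0))
  t_generations * generation_time
}

#' Migrants per generation
#' @param Ne effective population size (> 0).
#' @param m per-generation migration rate (>= 0).
#' @return Ne * m, the expected migrants per generation.
#' @export
migrantsPerGeneration <- function(Ne, m) {
  stopifnot(all(Ne > 0), all(m >= 0))
  Ne * m
}

#' Population-scaled migration M = 4 N0 m
#' @param N0 reference effective size (> 0).
#' @param m per-generation migration rate (>= 0).
#' @return 4 * N0 * m.
#' @export
scaledM <- function(N0, m) {
  stopifnot(all(N0 > 0), all(m >= 0))
  4 * N0 * m
}
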