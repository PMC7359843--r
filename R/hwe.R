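#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Classic one-degree-of-freedom Pearson chi-square comparing observed
#' genotype counts to Hardy-Weinberg expectations at the estimated allele
#' frequency \eqn{\hat p = (2 n_{AA} + n_{Aa}) / (2n)}. A fixed allele
#' (\eqn{\hat p} of 0 or 1) yields chi-square 0 and p-value 1.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts, total > 0.
#' @return list: p_hat, expected (named length-3), chisq, df, p_value.
#' @export
hweChisq <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || p == 1)
    return(list(p_hat = p, expected = c(AA = n * p^2, Aa = 2 * n * p * q,
                                        aa = n * q^2),
                chisq = 0, df = 1L, p_value = 1))
  expd <- c(AA = n * p^2, Aa = 2 * n * p * q, aa = n * q^2)
  obs <- c(n_AA, n_Aa, n_aa)
  chisq <- sum((obs - expd)^2 / expd)
  list(p_hat = p, expected = expd, chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
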