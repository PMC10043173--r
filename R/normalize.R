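#' TMM normalization factors
#'
#' Composition-aware between-sample normalization by the weighted trimmed
#' mean of M-values (TMM). The reference sample is the one whose
#' upper-quartile is closest to the mean upper-quartile; per sample, gene-wise
#' log-ratios (M) and average log abundances (A) versus the reference are
#' doubly trimmed and the factor is 2 to the precision-weighted mean of the
#' retained M values. Factors are rescaled to geometric mean 1. Computation
#' is delegated to \code{edgeR::calcNormFactors}.
#'
#' @param counts \code{count_matrix} or integer matrix (features x samples).
#' @param trim_m fraction of M values trimmed from each tail (default 0.3).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @return named numeric vector of scale factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  m <- as_count_mat(counts)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
  zero <- colSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  usable <- rowSums(m > 0) == ncol(m)
  if (sum(usable) < 10L) {
    warning("fewer than 10 features expressed in all samples; returning unit factors")
    return(stats::setNames(rep(1, ncol(m)), colnames(m)))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", logratioTrim = trim_m,
                              sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Log2 counts per million
#'
#' Converts counts to log2 counts-per-million on TMM-adjusted library sizes
#' with a symmetric prior count:
#' \deqn{\log_2\left(\frac{c + p}{L_j f_j + 2p} \cdot 10^6\right)}
#'
#' @param counts \code{count_matrix} or matrix.
#' @param factors normalization factors from [tmm_factors()]; \code{NULL} for
#'   unit factors.
#' @param prior_count prior count \eqn{p > 0} (default 0.5).
#' @return numeric matrix of log2 CPM values, same dimnames as the counts.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  m <- as_count_mat(counts)
  if (prior_count <= 0) stop("prior_count must be > 0")
  lib <- colSums(m)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  if (length(factors) != ncol(m)) stop("one factor per sample required")
  denom <- lib * factors + 2 * prior_count
  log2(sweep(m + prior_count, 2L, denom, "/") * 1e6)
}
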