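#' Per-timepoint priming contrast
#'
#' Estimates, for every gene at one washout timepoint, the priming effect:
#' the difference between the secondary-stimulation (Pam) response of
#' BG-experienced cells and the Pam response of control cells, from the
#' design \code{~ 1 + experiment + primary + Pam:primary}.
#'
#' @param logcpm log-CPM matrix covering the timepoint's samples (all four
#'   condition x secondary groups, >= 2 replicates each).
#' @param meta sample metadata with a \code{secondary} column.
#' @param timepoint division index to analyse.
#' @param moderate moderate variances (default TRUE).
#' @return data.frame with columns \code{feature}, \code{log2FC} (priming
#'   effect), \code{SE}, \code{t}, \code{p}, \code{fdr}.
#' @export
priming_contrast <- function(logcpm, meta, timepoint, moderate = TRUE) {
  meta <- sample_meta(meta)
  if (!"secondary" %in% names(meta))
    stop("metadata lacks a 'secondary' column")
  sel <- meta$division == timepoint
  if (!any(sel)) stop("no samples at timepoint ", timepoint)
  meta_t <- meta[sel, , drop = FALSE]
  groups <- table(meta_t$condition, meta_t$secondary)
  if (any(groups < 2))
    stop("each condition x secondary group needs >= 2 replicates at timepoint ",
         timepoint)
  fit <- fit_model(logcpm[, meta_t$sample, drop = FALSE], meta_t,
                   design = "priming", moderate = moderate)
  fit$tables$priming
}

#' Adaptive shrinkage of effect estimates
#'
#' Empirical-Bayes shrinkage of effect estimates with known standard errors
#' under a unimodal-at-zero prior: a mixture of a point mass at zero and
#' zero-mean normal components on a fixed geometric grid of scales. Mixture
#' weights are fitted by EM on the marginal likelihood
#' \eqn{\hat\beta_j \sim N(0, SE_j^2 + \sigma_k^2)}, with a mild
#' null-favoring Dirichlet penalty so that in the absence of signal all
#' weight lands on the point mass. Per gene the posterior mean and the local
#' false sign rate \eqn{lfsr = \min(P(\beta \le 0 | data), P(\beta \ge 0 |
#' data))} are reported; primed genes are conventionally called at lfsr <
#' 0.01.
#'
#' @param effects estimated effects (length >= 100).
#' @param ses standard errors (same length, all > 0).
#' @param grid optional vector of component standard deviations; default a
#'   geometric grid from \code{min(ses)/10} to \code{2*max(abs(effects))}
#'   with ratio sqrt(2), plus the point mass at 0.
#' @param null_penalty Dirichlet pseudo-count favoring the null component
#'   (default 10, as is conventional for this mixture).
#' @param tol EM convergence tolerance on the penalized log-likelihood
#'   (default 1e-6).
#' @param maxit maximum EM iterations (default 2000).
#' @return object of class \code{epimem_shrink}: list with
#'   \code{posterior_mean}, \code{lfsr}, \code{null_weight} (weight of the
#'   point mass), \code{weights}, \code{grid}, \code{loglik},
#'   \code{iterations}.
#' @export
shrink_effects <- function(effects, ses, grid = NULL, null_penalty = 10,
                           tol = 1e-6, maxit = 2000L) {
  n <- length(effects)
  if (n < 100L) stop("need >= 100 effects to fit the mixture")
  if (length(ses) != n || any(ses <= 0) || any(!is.finite(ses)))
    stop("ses must be positive, finite, and match effects in length")
  if (is.null(grid)) {
    lo <- min(ses) / 10
    hi <- max(2 * max(abs(effects)), lo * 2)
    grid <- lo * sqrt(2)^(0:ceiling(log(hi / lo) / log(sqrt(2))))
  }
  sds <- c(0, grid)
  K <- length(sds)
  # marginal density of effect_j under component k
  marg_sd <- sqrt(outer(ses^2, sds^2, "+"))        # n x K
  lik <- stats::dnorm(matrix(effects, n, K), 0, marg_sd)
  w <- rep(1 / K, K)
  alpha <- c(null_penalty, rep(1, K - 1))          # Dirichlet pseudo-counts
  pen_ll <- function(w) {
    sum(log(lik %*% w)) + sum((alpha - 1) * log(pmax(w, 1e-300)))
  }
  em_step <- function(w) {
    num <- sweep(lik, 2L, w, "*")
    w2 <- colSums(num / rowSums(num)) + alpha - 1
    w2 <- pmax(w2, 0)
    w2 / sum(w2)
  }
  # SQUAREM-accelerated EM on the penalized log-likelihood
  ll_old <- pen_ll(w)
  it <- 0L
  repeat {
    it <- it + 1L
    w1 <- em_step(w)
    w2 <- em_step(w1)
    r <- w1 - w; v <- (w2 - w1) - r
    sr <- sqrt(sum(r^2)); sv <- sqrt(sum(v^2))
    w_new <- if (sv > 0) {
      a <- min(-sr / sv, -1)
      prop <- w - 2 * a * r + a^2 * v
      prop <- pmax(prop, 1e-12); prop <- prop / sum(prop)
      if (pen_ll(prop) >= pen_ll(w2)) prop else w2
    } else {
      w2
    }
    ll <- pen_ll(w_new)
    w <- w_new
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    if (it >= maxit)
      stop(sprintf(
        "EM did not converge after %d iterations (loglik %.6f, change %.2e)",
        maxit, ll, ll - ll_old))
    ll_old <- ll
  }
  # posteriors: component k given data, then beta | k is normal
  num <- sweep(lik, 2L, w, "*")
  resp <- num / rowSums(num)
  shrinkf <- outer(1 / ses^2, 1 / sds^2, function(a, b) b / (a + b))
  shrinkf[, 1] <- 1                                # point mass: full shrink
  # beta|k ~ N(effect * sd_k^2/(sd_k^2+se^2), se^2 sd_k^2/(sd_k^2+se^2))
  pm_k <- matrix(effects, n, K) * (1 - shrinkf)
  pv_k <- matrix(ses^2, n, K) * (1 - shrinkf)
  pv_k[, 1] <- 0
  posterior_mean <- rowSums(resp * pm_k)
  # P(beta <= 0 | data); the point mass contributes fully to both tails
  sd_k <- sqrt(pv_k)
  z <- ifelse(sd_k > 0, -pm_k / sd_k, 0)
  p_le <- stats::pnorm(z)
  p_le[, 1] <- 1
  p_neg <- rowSums(resp * ifelse(sd_k > 0, p_le, as.numeric(pm_k <= 0)))
  p_ge_raw <- 1 - p_neg + resp[, 1]                # add back the atom at 0
  lfsr <- pmin(pmin(p_neg, p_ge_raw), 1)
  out <- list(posterior_mean = posterior_mean, lfsr = lfsr,
              null_weight = w[1], weights = stats::setNames(w, sds),
              grid = sds, loglik = ll, iterations = it)
  class(out) <- "epimem_shrink"
  out
}

#' @export
print.epimem_shrink <- function(x, ...) {
  cat(sprintf(
    "Adaptive shrinkage fit: %d effects, %d mixture components, null weight %.3f (%d EM iterations)\n",
    length(x$posterior_mean), length(x$grid), x$null_weight, x$iterations))
  invisible(x)
}

#' Membership-pattern overlap of primed gene sets
#'
#' Upset-style exact overlap counts: each gene in the union is assigned the
#' pattern of timepoints at which it is primed, and genes are counted per
#' pattern. Patterns with zero genes are omitted.
#'
#' @param primed_sets named list (>= 2 timepoints) of primed gene id vectors.
#' @return data.frame with columns \code{pattern} (timepoints joined by "+"),
#'   \code{n_timepoints}, \code{n_genes}, sorted by descending count.
#' @export
primed_overlap <- function(primed_sets) {
  if (length(primed_sets) < 2L) stop("need >= 2 timepoints")
  if (is.null(names(primed_sets))) stop("primed_sets must be named")
  all_genes <- unique(unlist(primed_sets))
  if (!length(all_genes))
    return(data.frame(pattern = character(), n_timepoints = integer(),
                      n_genes = integer()))
  member <- vapply(primed_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(primed_sets)))
  pat <- apply(member, 1L, function(r)
    paste(names(primed_sets)[r], collapse = "+"))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab),
                    n_timepoints = lengths(strsplit(names(tab), "+",
                                                    fixed = TRUE)),
                    n_genes = as.integer(tab), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$n_genes, out$pattern), , drop = FALSE]
}

#' Enrichment of primed genes among peak-annotated genes
#'
#' Per timepoint, tests whether genes primed at that timepoint are enriched
#' among genes that are the nearest gene of at least one significant peak at
#' the same timepoint (2x2 Fisher's exact test over the background of all
#' tested genes).
#'
#' @param primed_genes character vector of primed gene ids at the timepoint.
#' @param sig_peaks character vector of significant peak ids at the
#'   timepoint.
#' @param links output of [nearest_gene()].
#' @param background character vector of all tested gene ids.
#' @return list with \code{odds_ratio}, \code{p}, \code{table},
#'   \code{degenerate} flag.
#' @export
primed_peak_enrichment <- function(primed_genes, sig_peaks, links,
                                   background) {
  annotated <- unique(links$gene[links$peak %in% sig_peaks & !is.na(links$gene)])
  primed <- background %in% primed_genes
  near_sig <- background %in% annotated
  tab <- matrix(c(sum(primed & near_sig), sum(primed & !near_sig),
                  sum(!primed & near_sig), sum(!primed & !near_sig)),
                nrow = 2, byrow = TRUE,
                dimnames = list(gene = c("primed", "not_primed"),
                                peak = c("near_sig_peak", "not_near")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  or <- if (degenerate) {
    NA_real_
  } else if (any(tab == 0)) {
    ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * dd) / (b * cc)
  }
  list(odds_ratio = or, p = p, table = tab, degenerate = degenerate)
}
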