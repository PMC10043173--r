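# shared fixtures, all generated in code

# small washout simulation config
quick_cfg <- function(...) {
  args <- utils::modifyList(list(n_peaks = 400, n_genes = 300, seed = 1),
                            list(...))
  do.call(sim_config, args)
}

# differential-result tables for the first/last timepoints with known
# trajectory classes: effect delta0 present at the class-defining
# timepoint(s), estimated with N(0, se^2) noise, p from the normal tail
sim_da_tables <- function(n_per_class, delta0 = 2, se = 0.3, seed = 1) {
  set.seed(seed)
  classes <- rep(c("non_persistent", "induced", "retained", "unclassified"),
                 each = n_per_class)
  n <- length(classes)
  ids <- sprintf("f%04d", seq_len(n))
  eff <- function(present) {
    true <- ifelse(present, delta0, 0)
    est <- true + stats::rnorm(n, 0, se)
    p <- 2 * stats::pnorm(-abs(est) / se)
    data.frame(feature = ids, log2FC = est, SE = se, p = p,
               fdr = bh_adjust(p), stringsAsFactors = FALSE)
  }
  list(first = eff(classes %in% c("non_persistent", "retained")),
       last = eff(classes %in% c("induced", "retained")),
       classes = classes, ids = ids)
}

# independent replication of the weighted trimmed-mean-of-M-values
# arithmetic (reference = sample whose upper-quartile/library-size ratio is
# closest to the mean; doubly trimmed, precision-weighted mean of M)
oracle_tmm <- function(m, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(m)
  f75 <- apply(m, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- sapply(seq_len(ncol(m)), function(j) {
    obs <- as.numeric(m[, j]); refv <- as.numeric(m[, ref])
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (refv / nR))
    A <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  })
  unname(fac / exp(mean(log(fac))))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  d <- stats::dhyper(ks, r1, N - r1, c1)
  obs <- stats::dhyper(a, r1, N - r1, c1)
  sum(d[d <= obs * (1 + 1e-7)])
}

# all-pairs brute-force nearest-gene assignment with the package's
# tie-break rules (smaller tss, then lexicographic id)
oracle_nearest <- function(peaks, genes) {
  mid <- (peaks$start + peaks$end) / 2
  out <- data.frame(peak = peaks$peak, gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    dd <- abs(mid[i] - g$tss)
    cand <- g[dd == min(dd), , drop = FALSE]
    cand <- cand[order(cand$tss, cand$gene), , drop = FALSE]
    out$gene[i] <- cand$gene[1]
    out$distance[i] <- if (cand$strand[1] == "-") cand$tss[1] - mid[i] else
      mid[i] - cand$tss[1]
  }
  out
}

# run the washout differential stage and return per-division significant
# feature sets plus the fitted object
washout_sig <- function(sim, alpha = 0.1) {
  f <- tmm_factors(sim$peaks)
  fit <- fit_model(log_cpm(sim$peaks, f), sim$meta, "washout")
  sig <- significant_features(fit, alpha)
  names(sig) <- sub("^d", "", names(sig))
  list(fit = fit, sig = sig)
}
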