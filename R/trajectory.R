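#' Classify features into time-course trajectories
#'
#' Assigns each feature to a trajectory by its significance at the first and
#' last timepoints of the washout: significant only at the first timepoint =
#' non-persistent, only at the last = induced, at both = retained, at
#' neither = unclassified.
#'
#' @param res_first,res_last per-feature results (data.frames with columns
#'   \code{feature} and \code{fdr}) at the first and last timepoints; both
#'   must cover the same feature universe.
#' @param alpha FDR threshold for trajectory membership (default 0.05).
#' @return data.frame with columns \code{feature} and \code{label} (factor
#'   with levels non_persistent, induced, retained, unclassified).
#' @export
classify_trajectories <- function(res_first, res_last, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!setequal(res_first$feature, res_last$feature))
    stop("feature universes differ between the two timepoints")
  res_last <- res_last[match(res_first$feature, res_last$feature), ]
  sig1 <- res_first$fdr < alpha
  sig2 <- res_last$fdr < alpha
  label <- ifelse(sig1 & sig2, "retained",
                  ifelse(sig1, "non_persistent",
                         ifelse(sig2, "induced", "unclassified")))
  data.frame(feature = res_first$feature,
             label = factor(label, levels = c("non_persistent", "induced",
                                              "retained", "unclassified")),
             stringsAsFactors = FALSE)
}

#' Mean absolute log2FC trajectory per label group
#'
#' For every trajectory group, the arithmetic mean of \code{|log2FC|} across
#' its features at each timepoint (absolute values are taken before
#' averaging, so up- and down-regulated features do not cancel).
#'
#' @param labels output of [classify_trajectories()].
#' @param results_all named list (names = divisions) of per-timepoint result
#'   data.frames with columns \code{feature} and \code{log2FC}; every labeled
#'   feature must appear at every timepoint.
#' @return data.frame with columns \code{label}, \code{division},
#'   \code{mean_abs_lfc}, \code{n}. Empty label groups are omitted with a
#'   warning.
#' @export
mean_abs_lfc_curves <- function(labels, results_all) {
  divs <- as.numeric(names(results_all))
  if (any(is.na(divs))) stop("results_all must be named by division")
  out <- list()
  for (lab in levels(labels$label)) {
    feats <- labels$feature[labels$label == lab]
    if (!length(feats)) {
      warning("no features in group '", lab, "'; curve omitted")
      next
    }
    vals <- vapply(results_all, function(tb) {
      idx <- match(feats, tb$feature)
      if (any(is.na(idx)))
        stop("labeled feature(s) missing at a timepoint")
      mean(abs(tb$log2FC[idx]))
    }, numeric(1))
    out[[lab]] <- data.frame(label = lab, division = divs,
                             mean_abs_lfc = unname(vals), n = length(feats),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Assign each peak to its nearest gene TSS
#'
#' Midpoint-to-TSS nearest-gene assignment: each peak is linked to the gene
#' whose TSS minimises the distance to the peak midpoint. Ties are broken by
#' the smaller gene coordinate, then lexicographic gene id. The signed
#' distance is strand-aware: negative means the midpoint lies upstream of the
#' TSS on the gene's strand.
#'
#' @param peaks data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{peak} (id).
#' @param genes data.frame with columns \code{gene}, \code{chrom},
#'   \code{tss}, \code{strand} ("+" or "-").
#' @return data.frame with columns \code{peak}, \code{gene},
#'   \code{distance}. Peaks on chromosomes absent from the gene table get
#'   \code{NA} with a warning.
#' @export
nearest_gene <- function(peaks, genes) {
  stopifnot(all(c("chrom", "start", "end", "peak") %in% names(peaks)),
            all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  if (any(peaks$start >= peaks$end))
    stop("malformed intervals (start >= end)")
  mid <- (peaks$start + peaks$end) / 2
  out <- data.frame(peak = peaks$peak, gene = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  orphan <- !(peaks$chrom %in% genes$chrom)
  if (any(orphan))
    warning("peak(s) on chromosome(s) without genes left unassigned: ",
            paste(unique(peaks$chrom[orphan]), collapse = ", "))
  for (ch in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    # sort by tss then id: findInterval candidates then inherit tie-break
    g <- g[order(g$tss, g$gene), , drop = FALSE]
    pk <- which(peaks$chrom == ch)
    m <- mid[pk]
    lo <- findInterval(m, g$tss)            # last tss <= m (0 if none)
    hi <- pmin(lo + 1L, nrow(g))
    lo <- pmax(lo, 1L)
    d_lo <- abs(m - g$tss[lo])
    d_hi <- abs(m - g$tss[hi])
    # nearer wins; exact ties go to the smaller coordinate (lo); among
    # genes sharing that coordinate, the first in (tss, id) order wins
    pick <- ifelse(d_hi < d_lo, hi, lo)
    gi <- match(g$tss[pick], g$tss)
    out$gene[pk] <- g$gene[gi]
    signed <- ifelse(g$strand[gi] == "-", g$tss[gi] - m, m - g$tss[gi])
    out$distance[pk] <- signed
  }
  out
}

#' Fisher's exact test of peak-gene trajectory concordance
#'
#' Tests whether peaks in a target trajectory are enriched for linkage to
#' genes in the matching trajectory, over the background of all linked
#' peaks. The 2x2 table crosses (peak in target trajectory) with (nearest
#' gene in matching trajectory); the two-sided p-value comes from the exact
#' hypergeometric distribution and the odds ratio is the sample (cross
#' product) odds ratio with a Haldane 0.5 correction when any cell is zero.
#'
#' @param peak_labels,gene_labels outputs of [classify_trajectories()] for
#'   peaks and genes.
#' @param links output of [nearest_gene()].
#' @param target_label the trajectory tested (e.g. \code{"induced"}).
#' @return list with \code{odds_ratio}, \code{p}, \code{table} (2x2) and
#'   \code{degenerate} flag (TRUE when a margin is empty, making the OR
#'   undefined).
#' @export
fisher_concordance <- function(peak_labels, gene_labels, links,
                               target_label) {
  links <- links[!is.na(links$gene), , drop = FALSE]
  pk_lab <- peak_labels$label[match(links$peak, peak_labels$feature)]
  gn_lab <- gene_labels$label[match(links$gene, gene_labels$feature)]
  keep <- !is.na(pk_lab) & !is.na(gn_lab)
  pk_lab <- pk_lab[keep]; gn_lab <- gn_lab[keep]
  if (!length(pk_lab)) stop("no linked peaks with labels")
  in_target <- pk_lab == target_label
  gene_match <- gn_lab == target_label
  tab <- matrix(c(sum(in_target & gene_match), sum(in_target & !gene_match),
                  sum(!in_target & gene_match), sum(!in_target & !gene_match)),
                nrow = 2, byrow = TRUE,
                dimnames = list(peak = c("target", "other"),
                                gene = c("match", "other")))
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

#' PC1xPC2 coupling between expression and histone-PTM levels
#'
#' Measures whether sample-level structure in the transcriptome and the
#' epigenome co-varies: both matrices are feature-centered, sample scores on
#' the top two principal axes are computed for each, the per-sample product
#' PC1 x PC2 is formed, and the Pearson correlation between the two product
#' vectors over paired samples is returned. PC signs are fixed by requiring
#' the largest-magnitude element of each loading vector to be positive.
#'
#' @param logcpm_expr,logcpm_ptm log-CPM matrices (features x samples)
#'   covering the same paired samples (>= 3).
#' @param pairing optional named character vector mapping expression sample
#'   names to PTM sample names; default pairs identical column names.
#' @return list with \code{r} (Pearson correlation), \code{products_expr},
#'   \code{products_ptm} and per-matrix score matrices.
#' @export
pc_product_coupling <- function(logcpm_expr, logcpm_ptm, pairing = NULL) {
  if (is.null(pairing)) {
    common <- intersect(colnames(logcpm_expr), colnames(logcpm_ptm))
    pairing <- stats::setNames(common, common)
  }
  if (length(pairing) < 3L) stop("need >= 3 paired samples")
  e <- logcpm_expr[, names(pairing), drop = FALSE]
  h <- logcpm_ptm[, unname(pairing), drop = FALSE]
  scores <- function(m) {
    mc <- m - rowMeans(m)
    sv <- svd(mc, nu = 2, nv = 2)
    s <- sv$v %*% diag(sv$d[1:2], 2)    # sample scores
    for (k in 1:2) {                    # sign: largest |loading| positive
      load <- sv$u[, k]
      if (load[which.max(abs(load))] < 0) {
        s[, k] <- -s[, k]
      }
    }
    rownames(s) <- colnames(m)
    s
  }
  se <- scores(e); sh <- scores(h)
  pe <- se[, 1] * se[, 2]
  ph <- sh[, 1] * sh[, 2]
  list(r = stats::cor(pe, ph), products_expr = pe, products_ptm = ph,
       scores_expr = se, scores_ptm = sh)
}

#' Row-standardize a matrix
#'
#' Scales each feature (row) to mean 0 and sd 1 across samples. Zero-variance
#' rows are dropped with a warning.
#'
#' @param mat numeric matrix (features x samples).
#' @param sd_type \code{"sample"} (default, divisor n-1) or
#'   \code{"population"} (divisor n).
#' @return the standardized matrix (possibly with fewer rows).
#' @export
scale_rows <- function(mat, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  mu <- rowMeans(mat)
  centered <- mat - mu
  n <- ncol(mat)
  ss <- rowSums(centered^2)
  denom <- if (sd_type == "sample") n - 1 else n
  s <- sqrt(ss / denom)
  zero <- s == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) dropped")
    centered <- centered[!zero, , drop = FALSE]
    s <- s[!zero]
  }
  centered / s
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distances computed from a
#' row-standardized matrix (see [scale_rows()]), with a flat cut at k
#' clusters.
#'
#' @param scaled_matrix features x samples matrix (already row-scaled).
#' @param k number of flat clusters (>= 2 and <= number of samples).
#' @param linkage agglomeration method passed to \code{hclust} (default
#'   \code{"complete"}).
#' @return list with \code{hclust} (the dendrogram object), \code{labels}
#'   (named cluster assignment) and \code{dist} (the distance matrix).
#' @export
hierarchical_clustering <- function(scaled_matrix, k, linkage = "complete") {
  n <- ncol(scaled_matrix)
  if (k < 2L || k > n) stop("k must lie in [2, number of samples]")
  d <- stats::dist(t(scaled_matrix), method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, labels = stats::cutree(hc, k = k), dist = d)
}
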