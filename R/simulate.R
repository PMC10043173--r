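#' Expected marked fraction under passive dilution
#'
#' Closed form for the passive-dilution model: without any copying mechanism,
#' a parental histone mark is transmitted to each daughter cell with
#' probability \eqn{r} per division, so a starting marked fraction \eqn{p_0}
#' decays to \eqn{p_0 r^d} after \eqn{d} divisions (\eqn{r = 0.5} is the 50
#' percent-loss-per-division null).
#'
#' @param p0 initial marked fraction in \[0, 1\].
#' @param r per-division retention probability in \[0, 1\].
#' @param d non-negative integer division index (vectorised).
#' @return \code{p0 * r^d}.
#' @examples
#' expected_marked_fraction(1, 0.5, 0:4)
#' @export
expected_marked_fraction <- function(p0, r, d) {
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1)
    stop("p0 must be a single value in [0, 1]")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("r must be a single value in [0, 1]")
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0) || any(d != round(d)))
    stop("d must be non-negative integer(s)")
  p0 * r^d
}

#' Monte-Carlo nucleosome dilution
#'
#' Tracks marked nucleosome positions through successive rounds of DNA
#' replication in a population of cells. At each division every marked
#' position segregates to the tracked daughter strand with probability 1/2
#' (it is lost otherwise), and every unmarked position is re-marked with
#' probability \code{maintenance_prob} (a write-back activity; 0 means purely
#' passive dilution).
#'
#' @param n_cells number of independent cells.
#' @param n_nucleosomes nucleosome positions tracked per cell.
#' @param p0 initial marked fraction (each position marked independently).
#' @param divisions number of divisions to simulate.
#' @param maintenance_prob probability that an unmarked position is re-marked
#'   after each division.
#' @param seed integer seed.
#' @return numeric vector of population mean marked fractions, named
#'   \code{"0"} (initial state) through \code{as.character(divisions)}.
#' @examples
#' simulate_nucleosome_dilution(1000, 10, 1, 6, 0, seed = 1)
#' @export
simulate_nucleosome_dilution <- function(n_cells, n_nucleosomes, p0,
                                         divisions, maintenance_prob,
                                         seed = 1L) {
  stopifnot(n_cells >= 1L, n_nucleosomes >= 1L, divisions >= 1L)
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (maintenance_prob < 0 || maintenance_prob > 1)
    stop("maintenance_prob must lie in [0, 1]")
  set.seed(seed)
  n <- as.integer(n_cells) * as.integer(n_nucleosomes)
  marked <- stats::runif(n) < p0
  out <- numeric(divisions + 1L)
  out[1L] <- mean(marked)
  for (d in seq_len(divisions)) {
    kept <- marked & (stats::runif(n) < 0.5)
    rewritten <- !kept & (stats::runif(n) < maintenance_prob)
    marked <- kept | rewritten
    out[d + 1L] <- mean(marked)
  }
  names(out) <- as.character(0:divisions)
  out
}

# Per-feature effect magnitudes: truncated Pareto(alpha = 1) on
# [delta0/4, 6*delta0]. Under this scale-free law the fraction of features
# whose diluted effect still crosses a fixed detection threshold decays
# geometrically with the marks themselves, which is what the retention-curve
# analysis measures; typical draws sit near delta0/2-delta0 with a heavy
# tail of strong (latent-enhancer-like) responses.
effect_magnitudes <- function(n, delta0) {
  a <- delta0 / 4; b <- 6 * delta0
  u <- stats::runif(n)
  1 / (1 / a - u * (1 / a - 1 / b))
}

# delta trajectory matrix (features x divisions) from class labels.
# non_persistent: delta0_i * r^d; retained: delta0_i; induced: delta0_i for
# d >= onset; null: 0. 'sign' flips the whole trajectory per feature.
delta_trajectories <- function(classes, sign, mag, cfg) {
  d <- cfg$divisions
  delta <- matrix(0, nrow = length(classes), ncol = length(d),
                  dimnames = list(names(classes), as.character(d)))
  np <- classes == "non_persistent"
  if (any(np)) delta[np, ] <- outer(mag[np], cfg$retention_rate^d)
  re <- classes == "retained"
  if (any(re)) delta[re, ] <- mag[re]
  ind <- classes == "induced"
  if (any(ind))
    delta[ind, ] <- outer(mag[ind],
                          as.numeric(d >= cfg$induction_onset_division))
  delta * sign
}

# Assign dynamics classes deterministically by index blocks (the RNG order
# of feature attributes then stays stable across config changes).
assign_classes <- function(n, cfg) {
  n_resp <- round(cfg$fraction_responsive * n)
  n_maint <- min(round(cfg$fraction_maintained * n), n_resp)
  n_ind <- round(cfg$fraction_induced * n)
  cls <- rep("null", n)
  if (n_resp > 0) cls[seq_len(n_resp)] <- "non_persistent"
  if (n_maint > 0) cls[seq_len(n_maint)] <- "retained"
  if (n_ind > 0) cls[n_resp + seq_len(n_ind)] <- "induced"
  cls
}

# NB draws around means L_j * 2^(eta_ij) / colsum(2^(eta_ij)); phi = 0 is
# the Poisson limit.
nb_counts <- function(log2_intensity, lib_sizes, phi) {
  x <- 2^log2_intensity
  mu <- sweep(x, 2L, lib_sizes / colSums(x), "*")
  n <- length(mu)
  cnt <- if (phi > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / phi)
  } else {
    stats::rpois(n, lambda = mu)
  }
  matrix(cnt, nrow = nrow(mu), dimnames = dimnames(log2_intensity))
}

sim_feature_panel <- function(ids, cfg, genome) {
  n <- length(ids)
  classes <- assign_classes(n, cfg)
  names(classes) <- ids
  sgn <- ifelse(stats::runif(n) < 0.5, 1, -1)
  sgn[classes == "null"] <- 1
  mag <- effect_magnitudes(n, cfg$effect_size_T0)
  mag[classes == "null"] <- 0
  mu <- stats::runif(n, cfg$baseline_log_mean_range[1],
                     cfg$baseline_log_mean_range[2])
  batch <- matrix(stats::rnorm(n * cfg$n_experiments, sd = cfg$batch_sd),
                  nrow = n,
                  dimnames = list(ids, paste0("e", seq_len(cfg$n_experiments))))
  chrom <- sample(names(genome), n, replace = TRUE)
  pos <- floor(stats::runif(n, 1e4, unname(genome[chrom]) - 1e4))
  list(ids = ids, classes = classes, sign = sgn, magnitude = mag, mu = mu,
       batch = batch, chrom = chrom, pos = pos,
       delta = delta_trajectories(classes, sgn, mag, cfg))
}

sim_sample_sheet <- function(cfg, secondary = FALSE) {
  reps <- seq_len(cfg$n_replicates)
  grid <- expand.grid(
    replicate = reps, division = cfg$divisions,
    condition = c("control", "BG"),
    secondary = if (secondary) c("none", "Pam") else "none",
    stringsAsFactors = FALSE)
  # replicates are nested in experiments (paired design)
  grid$experiment <- paste0("e", 1L + (grid$replicate - 1L) %% cfg$n_experiments)
  grid$sample <- paste0(grid$condition,
                        ifelse(grid$secondary == "Pam", "_pam", ""),
                        "_d", grid$division, "_r", grid$replicate)
  grid[, c("sample", "condition", "division", "experiment", "secondary",
           "replicate")]
}

# log2 relative intensity for every feature x sample, given effect matrix
# 'eff' (features x samples, added only to BG samples already baked in).
log2_intensity <- function(panel, meta, eff) {
  base <- matrix(panel$mu, nrow = length(panel$mu), ncol = nrow(meta),
                 dimnames = list(panel$ids, meta$sample))
  base + panel$batch[, meta$experiment, drop = FALSE] + eff
}

#' Simulate peak and gene count matrices for the washout time course
#'
#' Generates negative-binomial count matrices for histone-PTM peaks and genes
#' over a division-indexed washout time course (two conditions, replicates
#' nested in experimental batches), with per-feature dynamics classes
#' (null / non-persistent / retained / induced) and optional peak-gene
#' coupling: a coupled peak inherits the effect trajectory of a gene of the
#' same class and is placed within 10 kb of that gene's TSS.
#'
#' For feature \eqn{i} in sample \eqn{j} (division \eqn{d(j)}), counts are
#' drawn as \deqn{c_{ij} \sim NB(m_{ij}, \phi), \quad m_{ij} = L_j
#' \frac{2^{\mu_i + b_{i,e(j)} + \delta_{i,d(j)} [cond_j = BG]}}{\sum_{i'}
#' 2^{\cdot}}} with variance \eqn{m + \phi m^2}.
#'
#' @param config a [sim_config()].
#' @return list of class \code{epimem_sim} with elements \code{peaks} and
#'   \code{genes} (\code{count_matrix}), \code{meta} (sample sheet),
#'   \code{peak_coords} (BED-style 0-based half-open data.frame),
#'   \code{gene_coords} (TSS table) and \code{truth} (per-feature classes,
#'   signed effect trajectories, peak-gene links, and the config).
#' @export
simulate_counts <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  genome <- c(chr1 = 195e6, chr2 = 182e6, chr3 = 160e6, chr4 = 157e6,
              chr5 = 152e6)
  peak_ids <- sprintf("peak_%05d", seq_len(cfg$n_peaks))
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))

  genes <- sim_feature_panel(gene_ids, cfg, genome)
  peaks <- sim_feature_panel(peak_ids, cfg, genome)

  # couple a fraction of non-null peaks to a same-class non-null gene:
  # shared trajectory (incl. sign) + placement within 10 kb of the TSS
  linked <- rep(NA_character_, cfg$n_peaks)
  for (cls in c("non_persistent", "retained", "induced")) {
    pk <- which(peaks$classes == cls)
    gn <- which(genes$classes == cls)
    if (!length(pk) || !length(gn)) next
    ck <- pk[stats::runif(length(pk)) < cfg$coupling_fraction]
    if (!length(ck)) next
    g <- gn[sample.int(length(gn), length(ck), replace = TRUE)]
    linked[ck] <- gene_ids[g]
    peaks$delta[ck, ] <- genes$delta[g, , drop = FALSE]
    peaks$sign[ck] <- genes$sign[g]
    peaks$magnitude[ck] <- genes$magnitude[g]
    peaks$chrom[ck] <- genes$chrom[g]
    peaks$pos[ck] <- pmax(1L, genes$pos[g] +
                            floor(stats::runif(length(ck), -1e4, 1e4)))
  }
  width <- floor(stats::runif(cfg$n_peaks, 200, 1000))
  peak_coords <- data.frame(
    chrom = peaks$chrom,
    start = as.integer(peaks$pos),                 # 0-based
    end = as.integer(peaks$pos + width),           # half-open
    peak = peak_ids, stringsAsFactors = FALSE)
  gene_coords <- data.frame(
    gene = gene_ids, chrom = genes$chrom, tss = as.integer(genes$pos),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)

  meta <- sim_sample_sheet(cfg)
  lib_peaks <- stats::runif(nrow(meta), cfg$library_size_range[1],
                            cfg$library_size_range[2])
  lib_genes <- stats::runif(nrow(meta), cfg$library_size_range[1],
                            cfg$library_size_range[2])
  is_bg <- as.numeric(meta$condition == "BG")
  dcol <- match(as.character(meta$division), colnames(peaks$delta))
  eff_peaks <- peaks$delta[, dcol, drop = FALSE] *
    rep(is_bg, each = cfg$n_peaks)
  eff_genes <- genes$delta[, dcol, drop = FALSE] *
    rep(is_bg, each = cfg$n_genes)
  colnames(eff_peaks) <- colnames(eff_genes) <- meta$sample

  pk_counts <- nb_counts(log2_intensity(peaks, meta, eff_peaks), lib_peaks,
                         cfg$dispersion)
  gn_counts <- nb_counts(log2_intensity(genes, meta, eff_genes), lib_genes,
                         cfg$dispersion)

  truth <- list(
    peaks = data.frame(feature = peak_ids, class = unname(peaks$classes),
                       sign = peaks$sign, effect_t0 = peaks$magnitude,
                       linked_gene = linked, stringsAsFactors = FALSE),
    genes = data.frame(feature = gene_ids, class = unname(genes$classes),
                       sign = genes$sign, effect_t0 = genes$magnitude,
                       stringsAsFactors = FALSE),
    peak_delta = peaks$delta, gene_delta = genes$delta, config = cfg)

  out <- list(peaks = count_matrix(pk_counts), genes = count_matrix(gn_counts),
              meta = meta[, c("sample", "condition", "division", "experiment")],
              peak_coords = peak_coords, gene_coords = gene_coords,
              truth = truth)
  class(out) <- "epimem_sim"
  out
}

#' @export
print.epimem_sim <- function(x, ...) {
  cat(sprintf("epimem simulation: %d peaks, %d genes, %d samples\n",
              nrow(x$peaks$counts), nrow(x$genes$counts), nrow(x$meta)))
  print(table(x$truth$peaks$class))
  invisible(x)
}

#' Simulate gene counts for a secondary-stimulation (priming) experiment
#'
#' At every timepoint four groups are generated: control and BG-experienced
#' cells, each unstimulated or re-stimulated with a secondary ligand (Pam).
#' Pam adds a response effect \eqn{\rho_i} (log2) to responsive genes in both
#' arms; primed genes additionally gain \eqn{\pi_i} in the BG arm only, so the
#' generative priming effect (difference of Pam responses, BG minus control)
#' is \eqn{\pi_i}.
#'
#' @param config a [sim_config()]; its fractions/dispersion/batch structure are
#'   reused, with \code{fraction_responsive} giving the Pam-responsive genes.
#' @param primed_fraction fraction of genes that are primed (drawn from the
#'   Pam-responsive set).
#' @param priming_effect \eqn{\pi}, the extra log2 Pam response in BG cells.
#' @param pam_response \eqn{\rho}, the log2 Pam response of responsive genes.
#' @return list with \code{genes} (\code{count_matrix}), \code{meta}
#'   (including a \code{secondary} column) and \code{truth} (per-gene rho and
#'   pi).
#' @export
simulate_priming_counts <- function(config, primed_fraction = 0.05,
                                    priming_effect = 2, pam_response = 2) {
  cfg <- validate_sim_config(config)
  if (cfg$n_replicates < 2L)
    stop("priming design needs >= 2 replicates per group")
  if (primed_fraction < 0 || primed_fraction > cfg$fraction_responsive)
    stop("primed_fraction must lie in [0, fraction_responsive]")
  set.seed(cfg$seed + 1L)
  genome <- c(chr1 = 195e6, chr2 = 182e6, chr3 = 160e6, chr4 = 157e6,
              chr5 = 152e6)
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  panel <- sim_feature_panel(gene_ids, cfg, genome)

  responsive <- panel$classes != "null"
  rho <- ifelse(responsive, pam_response, 0)
  n_primed <- round(primed_fraction * cfg$n_genes)
  primed_idx <- which(responsive)[seq_len(min(n_primed, sum(responsive)))]
  pi_eff <- numeric(cfg$n_genes)
  pi_eff[primed_idx] <- priming_effect

  meta <- sim_sample_sheet(cfg, secondary = TRUE)
  lib <- stats::runif(nrow(meta), cfg$library_size_range[1],
                      cfg$library_size_range[2])
  is_pam <- as.numeric(meta$secondary == "Pam")
  is_bg <- as.numeric(meta$condition == "BG")
  eff <- outer(rho, is_pam) + outer(pi_eff, is_pam * is_bg)
  colnames(eff) <- meta$sample
  rownames(eff) <- gene_ids
  counts <- nb_counts(log2_intensity(panel, meta, eff), lib, cfg$dispersion)

  truth <- data.frame(feature = gene_ids, rho = rho, pi = pi_eff,
                      primed = pi_eff != 0, stringsAsFactors = FALSE)
  list(genes = count_matrix(counts),
       meta = meta[, c("sample", "condition", "division", "experiment",
                       "secondary")],
       truth = truth)
}
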