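#' Simulation configuration
#'
#' Bundles the parameters of the count-matrix simulator: the washout time
#' course (division-indexed timepoints), sampling design (replicates nested in
#' experiments), negative-binomial noise model, and the division-indexed
#' effect trajectories that distinguish passively diluted, retained and
#' induced features.
#'
#' The generative log2 fold-change trajectory of a responsive feature at
#' division \eqn{d} is \eqn{\delta_d = \delta_0 r^d} (non-persistent),
#' \eqn{\delta_d = \delta_0} (retained), or \eqn{\delta_d = \delta_0
#' [d \ge d_{on}]} (induced). \code{retention_rate = 0.5} encodes passive
#' dilution: parental nucleosomes are split between daughter strands at each
#' round of DNA replication, halving the marked fraction per division.
#'
#' @param n_peaks,n_genes number of peak / gene features.
#' @param divisions integer divisions post-washout at which samples are taken
#'   (default 0, 2, ..., 14: collection every 24 h with a ~12 h division time).
#' @param n_replicates number of replicates per condition per timepoint.
#' @param n_experiments number of experimental batches; replicate k belongs to
#'   experiment k (paired across conditions and timepoints).
#' @param baseline_log_mean_range range (log2 scale) of baseline relative
#'   abundances, drawn uniformly per feature.
#' @param dispersion negative-binomial dispersion \eqn{\phi} > 0
#'   (variance \eqn{m + \phi m^2}).
#' @param library_size_range range of per-sample sequencing depths.
#' @param batch_sd standard deviation of per-feature, per-experiment log2
#'   offsets.
#' @param effect_size_T0 \eqn{\delta_0}, the log2 fold-change of responsive
#'   features at T0 (division 0); each responsive feature gets a random sign.
#' @param fraction_responsive fraction of features responsive at T0;
#'   \code{fraction_maintained} of all features (a subset of the responsive
#'   ones) keep their full effect at every division ("retained").
#' @param fraction_maintained fraction of features with maintained effects.
#' @param fraction_induced fraction of features with effects appearing only at
#'   division \code{induction_onset_division} and later.
#' @param induction_onset_division first division at which induced effects
#'   appear.
#' @param retention_rate per-division effect retention \eqn{r \in (0, 1]} for
#'   non-persistent features; 0.5 is passive dilution, 1 is full maintenance.
#' @param coupling_fraction fraction of non-null peaks tied to a non-null gene
#'   of the same dynamics class: the peak inherits the gene's effect
#'   trajectory and is placed within 10 kb of its TSS.
#' @param seed integer seed making the simulation deterministic.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso [simulate_counts()], [simulate_priming_counts()]
#' @export
sim_config <- function(n_peaks = 20000L,
                       n_genes = 10000L,
                       divisions = seq(0L, 14L, by = 2L),
                       n_replicates = 3L,
                       n_experiments = 3L,
                       baseline_log_mean_range = c(3, 9),
                       dispersion = 0.01,
                       library_size_range = c(8e6, 1.2e7),
                       batch_sd = 0.3,
                       effect_size_T0 = 2,
                       fraction_responsive = 0.3,
                       fraction_maintained = 0.001,
                       fraction_induced = 0.002,
                       induction_onset_division = 8L,
                       retention_rate = 0.5,
                       coupling_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_peaks = as.integer(n_peaks), n_genes = as.integer(n_genes),
    divisions = as.integer(sort(unique(divisions))),
    n_replicates = as.integer(n_replicates),
    n_experiments = as.integer(n_experiments),
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    dispersion = as.numeric(dispersion),
    library_size_range = as.numeric(library_size_range),
    batch_sd = as.numeric(batch_sd),
    effect_size_T0 = as.numeric(effect_size_T0),
    fraction_responsive = as.numeric(fraction_responsive),
    fraction_maintained = as.numeric(fraction_maintained),
    fraction_induced = as.numeric(fraction_induced),
    induction_onset_division = as.integer(induction_onset_division),
    retention_rate = as.numeric(retention_rate),
    coupling_fraction = as.numeric(coupling_fraction),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_peaks >= 1L, cfg$n_genes >= 1L,
    length(cfg$divisions) >= 1L, all(cfg$divisions >= 0L),
    cfg$n_replicates >= 1L, cfg$n_experiments >= 1L,
    length(cfg$baseline_log_mean_range) == 2L,
    diff(cfg$baseline_log_mean_range) >= 0,
    length(cfg$library_size_range) == 2L,
    all(cfg$library_size_range > 0),
    cfg$batch_sd >= 0
  )
  if (cfg$dispersion < 0)
    stop("dispersion must be >= 0 (0 selects the Poisson limit)")
  if (cfg$retention_rate <= 0 || cfg$retention_rate > 1)
    stop("retention_rate must lie in (0, 1]")
  fr <- cfg$fraction_responsive; fm <- cfg$fraction_maintained
  fi <- cfg$fraction_induced
  if (any(c(fr, fm, fi) < 0) || any(c(fr, fm, fi) > 1))
    stop("class fractions must lie in [0, 1]")
  if (fr + fi > 1)
    stop("fraction_responsive + fraction_induced must be <= 1")
  if (fm > fr)
    stop("fraction_maintained must be <= fraction_responsive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  features: %d peaks, %d genes\n", x$n_peaks, x$n_genes))
  cat(sprintf("  divisions: %s; %d replicates x %d experiments x 2 conditions\n",
              paste(x$divisions, collapse = ","), x$n_replicates,
              x$n_experiments))
  cat(sprintf("  NB dispersion %.3g, batch sd %.2g, library sizes [%.3g, %.3g]\n",
              x$dispersion, x$batch_sd, x$library_size_range[1],
              x$library_size_range[2]))
  cat(sprintf(
    "  delta0 = %.2g, retention r = %.2g, responsive %.0f%% (maintained %.0f%%), induced %.0f%% (onset d=%d)\n",
    x$effect_size_T0, x$retention_rate, 100 * x$fraction_responsive,
    100 * x$fraction_maintained, 100 * x$fraction_induced,
    x$induction_onset_division))
  cat(sprintf("  peak-gene coupling %.0f%%, seed %d\n",
              100 * x$coupling_fraction, x$seed))
  invisible(x)
}

#' Count matrix container
#'
#' A minimal container for a features-by-samples integer count matrix plus the
#' per-sample library sizes (which are, by construction, the column sums).
#'
#' @param counts non-negative integer matrix with feature rownames and sample
#'   colnames.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (matrix) and \code{library_sizes} (named numeric).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # keeps > .Machine$integer.max safe
  out <- list(counts = counts, library_sizes = colSums(counts))
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples, median library size %.3g\n",
              nrow(x$counts), ncol(x$counts),
              stats::median(x$library_sizes)))
  invisible(x)
}

# Accepts a count_matrix or a bare matrix; returns the matrix.
as_count_mat <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Validate sample metadata against a count matrix
#'
#' Checks that metadata has the expected columns and matches the count matrix
#' samples one-to-one.
#'
#' @param meta data.frame with columns \code{sample}, \code{condition},
#'   \code{division}, \code{experiment} and optionally \code{secondary}.
#' @param counts optional \code{count_matrix} or matrix to cross-check
#'   against.
#' @return the metadata, invisibly, with factor levels normalised
#'   (\code{condition} releveled to control first).
#' @export
sample_meta <- function(meta, counts = NULL) {
  need <- c("sample", "condition", "division", "experiment")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stop("duplicated sample ids in metadata: ",
         paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
  if (!all(meta$condition %in% c("control", "BG")))
    stop("condition must be 'control' or 'BG'")
  meta$condition <- factor(meta$condition, levels = c("control", "BG"))
  meta$division <- as.integer(meta$division)
  meta$experiment <- factor(meta$experiment)
  if ("secondary" %in% names(meta)) {
    if (!all(meta$secondary %in% c("none", "Pam")))
      stop("secondary must be 'none' or 'Pam'")
    meta$secondary <- factor(meta$secondary, levels = c("none", "Pam"))
  }
  if (!is.null(counts)) {
    cn <- colnames(as_count_mat(counts))
    extra <- setdiff(cn, meta$sample)
    if (length(extra))
      stop("samples in counts but not metadata: ",
           paste(extra, collapse = ", "))
    extra2 <- setdiff(meta$sample, cn)
    if (length(extra2))
      stop("samples in metadata but not counts: ",
           paste(extra2, collapse = ", "))
    meta <- meta[match(cn, meta$sample), , drop = FALSE]
    rownames(meta) <- NULL
  }
  invisible(meta)
}
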