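#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Input is either a
#' [sim_config()] (the pipeline then simulates its own data) or paths to a
#' peak counts TSV, gene counts TSV, metadata TSV, peaks BED and gene TSS
#' table.
#'
#' @param sim a [sim_config()] or NULL.
#' @param counts_peaks,counts_genes,meta,peaks_bed,genes_tss file paths, used
#'   when \code{sim} is NULL.
#' @param fdr_timepoint per-timepoint significance threshold for
#'   significant-site counting and retention curves (default 0.1).
#' @param fdr_trajectory threshold for trajectory membership (default 0.05).
#' @param lfsr_threshold threshold for calling primed genes (default 0.01).
#' @param include_priming run the priming stage (default TRUE; only possible
#'   with simulated input or metadata carrying a \code{secondary} column).
#' @param seed root seed; each stochastic stage derives its own seed from it.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_peaks = NULL, counts_genes = NULL,
                            meta = NULL, peaks_bed = NULL, genes_tss = NULL,
                            fdr_timepoint = 0.1, fdr_trajectory = 0.05,
                            lfsr_threshold = 0.01, include_priming = TRUE,
                            seed = 1L) {
  thr <- c(fdr_timepoint, fdr_trajectory, lfsr_threshold)
  if (any(thr <= 0) || any(thr >= 1))
    stop("thresholds must lie in (0, 1)")
  if (is.null(sim)) {
    paths <- list(counts_peaks = counts_peaks, counts_genes = counts_genes,
                  meta = meta, peaks_bed = peaks_bed, genes_tss = genes_tss)
    missing <- names(paths)[vapply(paths, is.null, logical(1))]
    if (length(missing))
      stop("file-based config needs: ", paste(missing, collapse = ", "))
  }
  out <- list(sim = sim, counts_peaks = counts_peaks,
              counts_genes = counts_genes, meta = meta,
              peaks_bed = peaks_bed, genes_tss = genes_tss,
              fdr_timepoint = fdr_timepoint,
              fdr_trajectory = fdr_trajectory,
              lfsr_threshold = lfsr_threshold,
              include_priming = include_priming, seed = as.integer(seed))
  class(out) <- "pipeline_config"
  out
}

# normalize + log-CPM + washout fit for one count matrix
fit_washout <- function(cm, meta) {
  f <- tmm_factors(cm)
  lc <- log_cpm(cm, f)
  list(logcpm = lc, fit = fit_model(lc, meta, design = "washout"))
}

#' Run the full washout analysis pipeline
#'
#' Executes every stage on simulated or file-based input: TMM normalization
#' and per-timepoint differential testing of peaks and genes; retention
#' curves of T0-significant features with the Kolmogorov-Smirnov comparison
#' against the 50 percent-per-division dilution null and an exponential
#' retention-rate fit; trajectory classification (first vs last division)
#' with mean |log2FC| curves; nearest-gene linkage and per-trajectory
#' Fisher concordance; PC1xPC2 epigenome-transcriptome coupling; and (for
#' simulated input) the secondary-stimulation priming analysis with adaptive
#' shrinkage. All intermediate artifacts plus a JSON summary and a run log
#' are written to \code{out_dir}.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly; written as \code{summary.json}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = logf)
  logmsg("epimem %s | R %s | seed %d",
         as.character(utils::packageVersion("epimem")),
         paste(R.version$major, R.version$minor, sep = "."), config$seed)

  # ---- input ----
  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- config$seed
    logmsg("stage simulate: %d peaks, %d genes, divisions %s",
           cfg$n_peaks, cfg$n_genes, paste(cfg$divisions, collapse = ","))
    sim <- simulate_counts(cfg)
    peaks_cm <- sim$peaks; genes_cm <- sim$genes; meta <- sim$meta
    peaks_bed <- sim$peak_coords; genes_tss <- sim$gene_coords
    write_counts(peaks_cm, file.path(out_dir, "counts_peaks.tsv"))
    write_counts(genes_cm, file.path(out_dir, "counts_genes.tsv"))
    write_meta(meta, file.path(out_dir, "meta.tsv"))
    write_bed(peaks_bed, file.path(out_dir, "peaks.bed"))
    write_tss(genes_tss, file.path(out_dir, "genes_tss.tsv"))
  } else {
    logmsg("stage read: %s", config$counts_peaks)
    peaks_cm <- read_counts(config$counts_peaks)
    genes_cm <- read_counts(config$counts_genes)
    meta <- read_meta(config$meta, peaks_cm)
    peaks_bed <- read_bed(config$peaks_bed)
    genes_tss <- read_tss(config$genes_tss)
    sim <- NULL
  }
  meta <- sample_meta(meta, peaks_cm)
  divisions <- sort(unique(meta$division))

  # ---- differential ----
  logmsg("stage differential: washout design, %d samples", nrow(meta))
  pk <- fit_washout(peaks_cm, meta)
  gn <- fit_washout(genes_cm, meta)
  for (nm in names(pk$fit$tables))
    utils::write.table(pk$fit$tables[[nm]],
                       file.path(out_dir, paste0("results_peaks_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(gn$fit$tables))
    utils::write.table(gn$fit$tables[[nm]],
                       file.path(out_dir, paste0("results_genes_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sig_pk <- significant_features(pk$fit, config$fdr_timepoint)
  sig_gn <- significant_features(gn$fit, config$fdr_timepoint)
  names(sig_pk) <- names(sig_gn) <- sub("^d", "", names(sig_pk))
  n_sig <- list(peaks = vapply(sig_pk, length, numeric(1)),
                genes = vapply(sig_gn, length, numeric(1)))

  # ---- decay ----
  t0 <- as.character(min(divisions))
  logmsg("stage decay: %d peaks significant at T0 (FDR < %g)",
         length(sig_pk[[t0]]), config$fdr_timepoint)
  decay <- NULL
  if (length(sig_pk[[t0]]) > 0) {
    curve <- retention_fractions(sig_pk[[t0]], sig_pk)
    ks <- ks_compare(curve$observed, curve$null)
    rfit <- tryCatch(fit_retention_rate(curve), error = function(e) NULL)
    utils::write.table(as.data.frame(curve),
                       file.path(out_dir, "retention_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    decay <- list(curve = as.data.frame(curve), ks = ks,
                  rate = if (is.null(rfit)) NULL else
                    rfit[c("rate", "half_life", "r_squared", "unbounded")])
  } else {
    logmsg("stage decay skipped: empty T0 significant set")
  }

  # ---- trajectories & coupling ----
  d_first <- as.character(min(divisions[divisions > min(divisions)]))
  d_last <- as.character(max(divisions))
  logmsg("stage trajectory: first d%s vs last d%s (FDR < %g)",
         d_first, d_last, config$fdr_trajectory)
  lab_pk <- classify_trajectories(pk$fit$tables[[paste0("d", d_first)]],
                                  pk$fit$tables[[paste0("d", d_last)]],
                                  config$fdr_trajectory)
  lab_gn <- classify_trajectories(gn$fit$tables[[paste0("d", d_first)]],
                                  gn$fit$tables[[paste0("d", d_last)]],
                                  config$fdr_trajectory)
  utils::write.table(lab_pk, file.path(out_dir, "trajectory_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lab_gn, file.path(out_dir, "trajectory_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res_by_div <- stats::setNames(pk$fit$tables, sub("^d", "",
                                                   names(pk$fit$tables)))
  curves <- withCallingHandlers(
    mean_abs_lfc_curves(lab_pk, res_by_div),
    warning = function(w) {logmsg("  %s", conditionMessage(w));
      invokeRestart("muffleWarning")})
  utils::write.table(curves, file.path(out_dir, "mean_abs_lfc_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  links <- withCallingHandlers(
    nearest_gene(peaks_bed, genes_tss),
    warning = function(w) {logmsg("  %s", conditionMessage(w));
      invokeRestart("muffleWarning")})
  utils::write.table(links, file.path(out_dir, "peak_gene_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conc <- lapply(stats::setNames(nm = c("non_persistent", "induced",
                                        "retained")),
                 function(lab) {
                   fc <- fisher_concordance(lab_pk, lab_gn, links, lab)
                   list(odds_ratio = fc$odds_ratio, p = fc$p,
                        degenerate = fc$degenerate)
                 })
  pcc <- pc_product_coupling(gn$logcpm, pk$logcpm)

  # ---- priming ----
  priming <- NULL
  if (config$include_priming && !is.null(sim)) {
    logmsg("stage priming: simulated secondary stimulation")
    prc <- config$sim
    prc$seed <- config$seed
    pr <- simulate_priming_counts(prc)
    prf <- tmm_factors(pr$genes)
    prl <- log_cpm(pr$genes, prf)
    prim_divs <- setdiff(sort(unique(pr$meta$division)), min(divisions))
    primed_sets <- list()
    n_primed <- numeric(0)
    for (d in prim_divs) {
      ct <- priming_contrast(prl, pr$meta, d)
      sh <- shrink_effects(ct$log2FC, ct$SE)
      primed_sets[[as.character(d)]] <-
        ct$feature[sh$lfsr < config$lfsr_threshold]
      n_primed[as.character(d)] <- length(primed_sets[[as.character(d)]])
      utils::write.table(
        data.frame(ct, posterior_mean = sh$posterior_mean, lfsr = sh$lfsr),
        file.path(out_dir, paste0("priming_d", d, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    overlap <- primed_overlap(primed_sets)
    utils::write.table(overlap, file.path(out_dir, "primed_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- lapply(stats::setNames(nm = names(primed_sets)), function(d) {
      sp <- sig_pk[[d]]
      if (is.null(sp)) sp <- character()
      pe <- primed_peak_enrichment(primed_sets[[d]], sp, links,
                                   rownames(genes_cm$counts))
      list(odds_ratio = pe$odds_ratio, p = pe$p, degenerate = pe$degenerate)
    })
    priming <- list(n_primed = as.list(n_primed),
                    overlap_patterns = nrow(overlap), enrichment = enr)
  }

  # ---- summary ----
  summary <- list(
    seed = config$seed,
    thresholds = list(fdr_timepoint = config$fdr_timepoint,
                      fdr_trajectory = config$fdr_trajectory,
                      lfsr = config$lfsr_threshold),
    n_significant = n_sig,
    decay = decay,
    trajectory_counts = list(peaks = as.list(table(lab_pk$label)),
                             genes = as.list(table(lab_gn$label))),
    concordance = conc,
    pc_coupling_r = pcc$r,
    priming = priming)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  logmsg("pipeline complete: %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}
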