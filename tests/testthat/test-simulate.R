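test_that("expected marked fraction follows p0 * r^d and rejects bad input", {
  expect_equal(expected_marked_fraction(1.0, 0.5, 1), 0.5)
  expect_equal(expected_marked_fraction(0.8, 0.5, 2), 0.2)
  expect_equal(expected_marked_fraction(0.7, 1.0, 14), 0.7)
  expect_equal(expected_marked_fraction(1, 0.5, 0:3), c(1, 0.5, 0.25, 0.125))
  expect_error(expected_marked_fraction(1.2, 0.5, 1), "p0")
  expect_error(expected_marked_fraction(1, -0.1, 1), "r must")
  expect_error(expected_marked_fraction(1, 0.5, -1), "d must")
  expect_error(expected_marked_fraction(1, 0.5, 1.5), "d must")
})

test_that("Monte-Carlo dilution matches the closed form without maintenance", {
  mc <- simulate_nucleosome_dilution(10000, 10, 1, 8, 0, seed = 1)
  n <- 10000 * 10
  for (d in 1:8) {
    expected <- expected_marked_fraction(1, 0.5, d)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mc[as.character(d)] - expected), 3 * se)
  }
  # population mean is monotone non-increasing under pure dilution
  expect_true(all(diff(mc) <= 0))
})

test_that("full maintenance saturates marks and a single particle absorbs", {
  mc <- simulate_nucleosome_dilution(2000, 10, 0.3, 10, 1, seed = 2)
  expect_true(all(diff(mc) >= -1e-12))
  expect_gt(mc["10"], 0.95)
  # single marked nucleosome, no re-writing: 0/1 path absorbing at 0
  path <- simulate_nucleosome_dilution(1, 1, 1, 12, 0, seed = 3)
  expect_true(all(path %in% c(0, 1)))
  if (any(path == 0)) {
    first0 <- min(which(path == 0))
    expect_true(all(path[first0:length(path)] == 0))
  }
  # same seed reproduces the trajectory exactly
  expect_identical(path, simulate_nucleosome_dilution(1, 1, 1, 12, 0, seed = 3))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(fraction_responsive = 0.7, fraction_induced = 0.5),
               "<= 1")
  expect_error(sim_config(fraction_maintained = 0.5,
                          fraction_responsive = 0.2), "fraction_maintained")
  expect_error(sim_config(retention_rate = 0), "retention_rate")
  expect_error(sim_config(retention_rate = 1.2), "retention_rate")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_silent(print <- format(quick_cfg()))
})

test_that("truth trajectories satisfy the class equations exactly", {
  cfg <- quick_cfg(fraction_responsive = 0.4, fraction_maintained = 0.1,
                   fraction_induced = 0.2, retention_rate = 0.6,
                   coupling_fraction = 0)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  d <- cfg$divisions
  for (i in seq_len(nrow(tr$peaks))) {
    cls <- tr$peaks$class[i]
    d0 <- tr$peaks$effect_t0[i] * tr$peaks$sign[i]
    want <- switch(cls,
      null = rep(0, length(d)),
      non_persistent = d0 * cfg$retention_rate^d,
      retained = rep(d0, length(d)),
      induced = d0 * (d >= cfg$induction_onset_division))
    expect_equal(unname(tr$peak_delta[i, ]), want)
  }
  # class labels partition all features
  expect_equal(sort(unique(tr$peaks$class)),
               sort(c("null", "non_persistent", "retained", "induced")))
})

test_that("simulated counts are reproducible and structurally valid", {
  cfg <- quick_cfg()
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$peaks$counts, s2$peaks$counts)
  expect_identical(s1$genes$counts, s2$genes$counts)
  expect_equal(s1$peaks$library_sizes, colSums(s1$peaks$counts))
  expect_equal(nrow(s1$meta), ncol(s1$peaks$counts))
  expect_true(all(s1$peaks$counts >= 0))
  # different seed gives different data
  s3 <- simulate_counts(quick_cfg(seed = 99))
  expect_false(identical(s1$peaks$counts, s3$peaks$counts))
})

test_that("coupled peaks share the linked gene's trajectory and locus", {
  cfg <- quick_cfg(coupling_fraction = 1, fraction_responsive = 0.5,
                   fraction_maintained = 0.1, fraction_induced = 0.2)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  coupled <- which(!is.na(tr$peaks$linked_gene))
  expect_gt(length(coupled), 0)
  gidx <- match(tr$peaks$linked_gene[coupled], tr$genes$feature)
  expect_equal(tr$peak_delta[coupled, , drop = FALSE],
               tr$gene_delta[gidx, , drop = FALSE],
               ignore_attr = TRUE)
  # within 10 kb of the linked TSS, same chromosome
  pk <- sim$peak_coords[coupled, ]
  gn <- sim$gene_coords[gidx, ]
  expect_true(all(pk$chrom == gn$chrom))
  expect_true(all(abs(pk$start - gn$tss) <= 1e4 + 1))
})

test_that("count noise matches the negative-binomial moment identity", {
  # all features at one baseline, no batch or condition effects, equal
  # depth: every draw shares mean m, so pooled var/mean identifies phi
  phi <- 0.2
  cfg <- sim_config(n_peaks = 250, n_genes = 10, divisions = c(0, 2),
                    n_replicates = 10, batch_sd = 0,
                    baseline_log_mean_range = c(6, 6), dispersion = phi,
                    library_size_range = c(1e6, 1e6),
                    fraction_responsive = 0, fraction_maintained = 0,
                    fraction_induced = 0, seed = 4)
  sim <- simulate_counts(cfg)
  x <- as.numeric(sim$peaks$counts)          # 10^4 draws at equal mean
  m <- mean(x)
  expect_equal(stats::var(x), m + phi * m^2, tolerance = 0.05)
  # Poisson limit: variance tracks the mean
  cfg0 <- sim_config(n_peaks = 250, n_genes = 10, divisions = c(0, 2),
                     n_replicates = 10, batch_sd = 0,
                     baseline_log_mean_range = c(6, 6), dispersion = 0,
                     library_size_range = c(1e6, 1e6),
                     fraction_responsive = 0, fraction_maintained = 0,
                     fraction_induced = 0, seed = 4)
  x0 <- as.numeric(simulate_counts(cfg0)$peaks$counts)
  expect_equal(stats::var(x0) / mean(x0), 1, tolerance = 0.1)
})

test_that("priming simulation encodes Pam response and priming interaction", {
  cfg <- sim_config(n_genes = 600, n_peaks = 10, divisions = 2,
                    n_replicates = 20, batch_sd = 0, dispersion = 0.01,
                    baseline_log_mean_range = c(6, 6),
                    library_size_range = c(1e6, 1e6),
                    fraction_responsive = 0.3, fraction_maintained = 0,
                    fraction_induced = 0, seed = 5)
  pr <- simulate_priming_counts(cfg, primed_fraction = 0.1,
                                priming_effect = 2, pam_response = 1)
  tr <- pr$truth
  expect_true(all(tr$pi[tr$primed] == 2))
  expect_true(all(tr$pi[!tr$primed] == 0))
  expect_true(all(tr$primed | tr$pi == 0))
  # with priming_effect = 0 the generative interaction vanishes
  pr0 <- simulate_priming_counts(cfg, primed_fraction = 0.1,
                                 priming_effect = 0, pam_response = 1)
  expect_true(all(pr0$truth$pi == 0))
  # rho = 1 doubles expected counts under Pam in the control arm
  m <- pr$genes$counts
  meta <- pr$meta
  resp <- tr$rho == 1
  grp <- function(cond, sec)
    rowMeans(m[resp, meta$condition == cond & meta$secondary == sec,
               drop = FALSE])
  # compositional normalization deflates all Pam/none ratios by a common
  # factor, so compare responsive against non-responsive genes: the ratio
  # of ratios isolates rho = 1 (2-fold)
  ratio_resp <- grp("control", "Pam") / grp("control", "none")
  nullg <- tr$rho == 0
  grp0 <- function(cond, sec)
    rowMeans(m[nullg, meta$condition == cond & meta$secondary == sec,
               drop = FALSE])
  ratio_null <- grp0("control", "Pam") / grp0("control", "none")
  expect_equal(median(ratio_resp) / median(ratio_null), 2, tolerance = 0.1)
  # primed genes respond more in the BG arm (pi = 2 on top of rho = 1)
  ratio_bg <- rowMeans(m[tr$primed, meta$condition == "BG" &
                           meta$secondary == "Pam", drop = FALSE]) /
    rowMeans(m[tr$primed, meta$condition == "BG" & meta$secondary == "none",
               drop = FALSE])
  expect_gt(median(ratio_bg) / median(ratio_null), 4)
})
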