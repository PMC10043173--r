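test_that("trajectory classification follows the two-timepoint rule", {
  tb <- function(fdr) data.frame(feature = c("a", "b", "c", "d"),
                                 fdr = fdr, stringsAsFactors = FALSE)
  lab <- classify_trajectories(tb(c(0.01, 0.01, 0.5, 0.5)),
                               tb(c(0.01, 0.5, 0.01, 0.5)), alpha = 0.05)
  expect_equal(as.character(lab$label),
               c("retained", "non_persistent", "induced", "unclassified"))
  # labels partition the universe
  expect_equal(nrow(lab), 4)
  expect_error(classify_trajectories(tb(rep(0.1, 4)),
                                     tb(rep(0.1, 4))[1:3, ]), "universes")
  expect_error(classify_trajectories(tb(rep(0.1, 4)), tb(rep(0.1, 4)),
                                     alpha = 1.5), "alpha")
})

test_that("classification recovers simulated trajectory classes", {
  da <- sim_da_tables(n_per_class = 500, delta0 = 2, se = 0.3, seed = 9)
  lab <- classify_trajectories(da$first, da$last, alpha = 0.05)
  nonnull <- da$classes != "unclassified"
  acc <- mean(as.character(lab$label[nonnull]) == da$classes[nonnull])
  expect_gte(acc, 0.9)
  expect_equal(nrow(lab), length(da$ids))
})

test_that("mean |log2FC| curves average magnitudes, not signed effects", {
  labels <- data.frame(
    feature = c("a", "b", "c"),
    label = factor(c("induced", "induced", "non_persistent"),
                   levels = c("non_persistent", "induced", "retained",
                              "unclassified")))
  res <- list(
    `2` = data.frame(feature = c("a", "b", "c"), log2FC = c(2, -2, 1.5)),
    `4` = data.frame(feature = c("a", "b", "c"), log2FC = c(0.5, 0.5, 1.5)))
  warns <- capture_warnings(curves <- mean_abs_lfc_curves(labels, res))
  expect_match(warns, "retained", all = FALSE)
  ind <- curves[curves$label == "induced", ]
  expect_equal(ind$mean_abs_lfc, c(2, 0.5))   # |2| and |-2| average to 2
  np <- curves[curves$label == "non_persistent", ]
  expect_equal(np$mean_abs_lfc, c(1.5, 1.5))
})

test_that("non-persistent group curves decay at the generative rate", {
  # noiseless tables built from the dilution law itself
  d <- seq(2, 14, 2)
  n <- 40
  ids <- sprintf("p%02d", seq_len(n))
  labels <- data.frame(feature = ids,
                       label = factor(rep("non_persistent", n),
                                      levels = c("non_persistent", "induced",
                                                 "retained", "unclassified")))
  res <- lapply(d, function(dd)
    data.frame(feature = ids, log2FC = 2 * 0.5^dd * rep(c(1, -1), n / 2)))
  names(res) <- d
  curves <- suppressWarnings(mean_abs_lfc_curves(labels, res))
  slope <- coef(lm(log2(curves$mean_abs_lfc) ~ curves$division))[2]
  expect_equal(unname(slope), log2(0.5), tolerance = 1e-10)
})

test_that("nearest-gene assignment follows midpoint distance and conventions", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      tss = c(150L, 300L), strand = c("+", "+"))
  # midpoint of [100, 200) is 150: exact hit
  pk <- data.frame(chrom = "chr1", start = 100L, end = 200L, peak = "pk1")
  hit <- nearest_gene(pk, genes)
  expect_equal(hit$gene, "g1")
  expect_equal(hit$distance, 0)
  # candidates at 100 and 300 from midpoint 150: nearer (100) wins,
  # midpoint downstream of TSS on + strand => positive distance
  genes2 <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                       tss = c(100L, 300L), strand = c("+", "+"))
  hit2 <- nearest_gene(pk, genes2)
  expect_equal(hit2$gene, "gA")
  expect_equal(hit2$distance, 50)
  # minus strand flips the sign convention
  genes3 <- data.frame(gene = "gC", chrom = "chr1", tss = 100L, strand = "-")
  expect_equal(nearest_gene(pk, genes3)$distance, -50)
  # exact distance tie: smaller coordinate, then lexicographic id
  genes4 <- data.frame(gene = c("gZ", "gY"), chrom = "chr1",
                       tss = c(100L, 200L), strand = "+")
  expect_equal(nearest_gene(pk, genes4)$gene, "gZ")
  genes5 <- data.frame(gene = c("gZ", "gA"), chrom = "chr1",
                       tss = c(100L, 100L), strand = "+")
  expect_equal(nearest_gene(pk, genes5)$gene, "gA")
  # orphan chromosome left unassigned with warning
  pk2 <- rbind(pk, data.frame(chrom = "chrX", start = 10L, end = 20L,
                              peak = "pk2"))
  expect_warning(res <- nearest_gene(pk2, genes), "chrX")
  expect_true(is.na(res$gene[res$peak == "pk2"]))
  expect_error(nearest_gene(data.frame(chrom = "chr1", start = 5L, end = 5L,
                                       peak = "bad"), genes), "malformed")
})

test_that("nearest-gene assignment equals the all-pairs brute force", {
  set.seed(10)
  chroms <- paste0("chr", 1:3)
  genes <- data.frame(gene = sprintf("g%03d", 1:60),
                      chrom = sample(chroms, 60, TRUE),
                      tss = sample.int(1e6, 60),
                      strand = sample(c("+", "-"), 60, TRUE))
  start <- sample.int(1e6, 300)
  peaks <- data.frame(chrom = sample(chroms, 300, TRUE), start = start,
                      end = start + sample(100:1000, 300, TRUE),
                      peak = sprintf("p%03d", 1:300))
  expect_equal(nearest_gene(peaks, genes), oracle_nearest(peaks, genes))
})

test_that("concordance test matches hypergeometric enumeration", {
  mk <- function(tab) {
    # realize a 2x2 table as labels + links
    n <- sum(tab)
    pk <- sprintf("p%03d", seq_len(n))
    gn <- sprintf("g%03d", seq_len(n))
    cnt <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    pk_lab <- rep(c("induced", "induced", "unclassified", "unclassified"),
                  cnt)
    gn_lab <- rep(c("induced", "unclassified", "induced", "unclassified"),
                  cnt)
    lv <- c("non_persistent", "induced", "retained", "unclassified")
    list(p = data.frame(feature = pk, label = factor(pk_lab, lv)),
         g = data.frame(feature = gn, label = factor(gn_lab, lv)),
         links = data.frame(peak = pk, gene = gn, distance = 0))
  }
  flat <- matrix(c(10, 10, 10, 10), 2, byrow = TRUE)
  x <- mk(flat)
  fc <- fisher_concordance(x$p, x$g, x$links, "induced")
  expect_equal(fc$odds_ratio, 1)
  expect_equal(fc$p, 1)
  expect_equal(unname(as.vector(fc$table)), c(10, 10, 10, 10))
  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2, byrow = TRUE)
    x <- mk(tab)
    fc <- fisher_concordance(x$p, x$g, x$links, "induced")
    expect_equal(fc$p, oracle_fisher_p(fc$table), tolerance = 1e-10)
  }
  # Haldane correction when a cell is empty
  x0 <- mk(matrix(c(5, 0, 1, 5), 2, byrow = TRUE))
  fc0 <- fisher_concordance(x0$p, x0$g, x0$links, "induced")
  expect_equal(fc0$odds_ratio, (5.5 * 5.5) / (0.5 * 1.5))
})

test_that("row scaling standardizes and drops constant features", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_warning(sc <- scale_rows(m), "zero-variance")
  expect_equal(unname(sc["a", ]), c(-1, 0, 1))
  expect_false("b" %in% rownames(sc))
  scp <- scale_rows(m["a", , drop = FALSE], sd_type = "population")
  expect_equal(unname(scp[1, ]), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  set.seed(12)
  big <- matrix(rnorm(200), 20)
  rownames(big) <- sprintf("f%02d", 1:20)
  sb <- scale_rows(big)
  expect_true(all(abs(rowMeans(sb)) < 1e-12))
  expect_true(all(abs(apply(sb, 1, sd) - 1) < 1e-12))
})

test_that("hierarchical clustering separates distinct sample groups", {
  set.seed(13)
  grp <- rep(1:2, each = 5)
  m <- matrix(rnorm(40 * 10, mean = rep(grp * 4, each = 40)), nrow = 40)
  colnames(m) <- sprintf("s%02d", 1:10)
  rownames(m) <- sprintf("f%02d", 1:40)
  hc <- hierarchical_clustering(scale_rows(m), k = 2)
  expect_equal(length(unique(hc$labels[grp == 1])), 1)
  expect_equal(length(unique(hc$labels[grp == 2])), 1)
  expect_false(hc$labels[1] == hc$labels[10])
  # metric sanity: symmetric, zero diagonal; duplicates merge first
  dm <- as.matrix(hc$dist)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  m2 <- cbind(m, s11 = m[, 1])
  hc2 <- hierarchical_clustering(m2, k = 2)
  expect_equal(hc2$hclust$height[1], 0)
  expect_error(hierarchical_clustering(m, k = 11), "k must")
})

test_that("PC1xPC2 products self-couple and decouple under permutation", {
  set.seed(14)
  m <- matrix(rnorm(60 * 12), 60,
              dimnames = list(sprintf("f%02d", 1:60), sprintf("s%02d", 1:12)))
  self <- pc_product_coupling(m, m)
  expect_equal(abs(self$r), 1, tolerance = 1e-10)
  # independent matrices under random pairing: products uncorrelated
  rs <- replicate(25, {
    a <- matrix(rnorm(60 * 12), 60,
                dimnames = dimnames(m))
    b <- matrix(rnorm(60 * 12), 60, dimnames = dimnames(m))
    pairing <- setNames(sample(colnames(b)), colnames(a))
    pc_product_coupling(a, b, pairing)$r
  })
  expect_lt(mean(abs(rs)), 0.3)
  expect_error(pc_product_coupling(m[, 1:2], m[, 1:2]), ">= 3")
})
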