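test_that("test choice follows per-group Shapiro-Wilk normality", {
  ch <- choose_test(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(ch$shapiro_p_a, 0.9672, tolerance = 1e-3)
  expect_equal(ch$test, "student_t")

  # exactly normal quantiles in both groups stay parametric
  q <- qnorm(ppoints(10))
  expect_equal(choose_test(q, q * 2 + 1)$test, "student_t")

  # a constant group is degenerate: non-parametric branch
  expect_equal(choose_test(rep(3, 5), c(1, 2, 3, 4, 5))$test, "wilcoxon")
  # too small for Shapiro-Wilk: non-parametric with undefined p
  ch2 <- choose_test(c(1, 2), c(3, 4))
  expect_equal(ch2$test, "wilcoxon")
  expect_true(is.na(ch2$shapiro_p_a))
})

test_that("two-group engine: exact Wilcoxon matches enumeration, t handles degeneracy", {
  r <- de_test(c(1, 2, 3), c(4, 5, 6), "wilcoxon")
  expect_equal(r$p, 0.1)
  expect_equal(r$p, oracle_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))

  expect_equal(de_test(c(2, 2, 2), c(2, 2, 2), "wilcoxon")$p, 1)
  # degenerate parametric input reroutes to the rank test
  r2 <- de_test(c(0, 0, 0), c(5, 5, 5), "student_t")
  expect_equal(r2$test, "wilcoxon")
  expect_lt(r2$p, 0.2)

  # exact branch equals brute-force enumeration over labelings (tie-free)
  set.seed(77)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(seq_len(50), na + nb)   # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(de_test(a, b, "wilcoxon")$p, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }

  # swapping groups leaves p unchanged and flips the fold change
  a <- c(3, 7, 9, 12); b <- c(1, 2, 8, 4)
  expect_equal(de_test(a, b, "wilcoxon")$p, de_test(b, a, "wilcoxon")$p)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("Benjamini-Hochberg adjustment is the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.2, 1.4)), "0, 1")

  # monotone (order-preserving) in p
  set.seed(5)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12) && all(q <= 1))
})

test_that("fold changes use the pseudocount ratio of group means", {
  expect_equal(log2_fold_change(c(15, 15), c(3, 3)), 2)
  expect_equal(log2_fold_change(c(4, 8), c(4, 8)), 0)
  expect_equal(log2_fold_change(c(0, 0), c(0, 0)), 0)
})

test_that("run_de tests only above-noise genes and controls stay out", {
  co <- default_cohort()
  de <- co$de
  below <- co$norm$noise_calls$gene[!co$norm$noise_calls$above_noise]
  expect_length(intersect(de$gene, below), 0)
  expect_equal(nrow(de), sum(co$norm$noise_calls$above_noise))
  # sorted by q then |lfc|
  expect_true(all(diff(de$q_fdr) >= -1e-12))
  expect_true(all(de$q_fdr >= de$p_raw - 1e-12))
  expect_equal(de$significant, de$q_fdr <= 0.05)

  ann_bad <- co$ds$annotations
  ann_bad$subtype[ann_bad$subtype == "DRB"] <- "URB"
  expect_error(run_de(co$norm$matrix, ann_bad, co$norm$noise_calls),
               "cohort error")
})

test_that("mean-variance QC flags constructed outliers and little else", {
  set.seed(42)
  n_genes <- 200
  mu <- 2^runif(n_genes, 4, 10)
  vals <- t(vapply(mu, function(m) rnbinom(10, mu = m, size = 10),
                   numeric(10)))
  rownames(vals) <- sprintf("G%03d", seq_len(n_genes))
  cs <- codeset(rep(c("Endogenous", "Positive", "Negative"),
                    c(n_genes, 1, 2)),
                c(rownames(vals), "POS_A", "NEG_A", "NEG_B"),
                expected_concentration = c(rep(NA, n_genes), 128, NA, NA))
  allv <- rbind(vals, POS_A = rep(1000, 10), NEG_A = rep(5, 10),
                NEG_B = rep(6, 10))
  qc <- mean_variance_qc(count_matrix(allv, cs))
  expect_lte(mean(qc$gene_stats$outlier), 0.02)

  # inject a gene with 100x variance at the same mean
  allv["G001", ] <- mean(allv["G001", ]) +
    (allv["G001", ] - mean(allv["G001", ])) * 10
  allv <- pmax(round(allv), 0)
  qc2 <- mean_variance_qc(count_matrix(allv, cs))
  expect_true(qc2$gene_stats$outlier[qc2$gene_stats$gene == "G001"])

  # identical genes: no outliers, degenerate fit handled
  allv[] <- 50
  qc3 <- mean_variance_qc(count_matrix(allv, cs))
  expect_false(any(qc3$gene_stats$outlier))
})

test_that("correlation analysis: Pearson for linearity, Spearman for monotonicity", {
  x <- as.numeric(1:10)
  expect_equal(correlation_analysis(x, x, "pearson")$estimate, 1)
  expect_equal(correlation_analysis(x, x, "spearman")$estimate, 1)

  y <- x^3
  expect_equal(correlation_analysis(x, y, "spearman")$estimate, 1)
  expect_lt(correlation_analysis(x, y, "pearson")$estimate, 1)

  # Pearson p matches the classical t reference implementation
  set.seed(8)
  a <- rnorm(15); b <- a + rnorm(15)
  expect_equal(correlation_analysis(a, b, "pearson")$p,
               cor.test(a, b)$p.value, tolerance = 1e-10)

  expect_error(correlation_analysis(rep(1, 5), 1:5), "zero variance")

  cm <- correlation_matrix(default_cohort()$norm$matrix)
  expect_true(all(diag(cm) == 1))
  expect_true(all(cm >= -1 & cm <= 1 + 1e-12))
})

test_that("PCA separates subtypes when the signal is strong", {
  cs <- tiny_codeset(n_end = 2, n_hk = 1)
  vals <- rbind(G01 = c(10, 20), G02 = c(5, 5), HK01 = c(7, 7),
                matrix(100, 6, 2, dimnames = list(paste0("POS_", LETTERS[1:6]), NULL)),
                matrix(5, 4, 2, dimnames = list(paste0("NEG_", LETTERS[1:4]), NULL)))
  pc <- pca_samples(count_matrix(vals, cs))
  expect_equal(pc$variance_explained[1], 1)

  vals[] <- 50
  pc0 <- pca_samples(count_matrix(vals, cs))
  expect_true(all(abs(pc0$scores) < 1e-10))

  co <- default_cohort()
  pc2 <- pca_samples(co$norm$matrix)
  sub <- co$ds$annotations$subtype[match(rownames(pc2$scores),
                                         co$ds$annotations$sample_id)]
  tumor <- sub %in% c("URB", "DRB")
  r <- abs(cor(pc2$scores[tumor, 1], as.numeric(sub[tumor] == "URB")))
  expect_gt(r, 0.8)
  expect_true(all(pc2$variance_explained >= 0))
  expect_lte(sum(pc2$variance_explained), 1 + 1e-9)
})

test_that("clustering recovers subtypes and supervised mode never interleaves", {
  m <- default_cohort()$norm$matrix
  ann <- default_cohort()$ds$annotations
  cl <- cluster_samples(m)
  expect_setequal(cl$leaf_order, colnames(m$values))
  expect_true(all(diff(cl$merge_heights) >= -1e-9))

  # cutting at 2 clusters recovers the subtypes (controls cluster with one)
  k2 <- cutree(cl$trees$all, k = 2)
  tumor <- ann$sample_id[ann$subtype %in% c("URB", "DRB")]
  truth <- as.character(ann$subtype[match(tumor, ann$sample_id)])
  expect_gt(plain_rand(k2[tumor], truth), 0.8)

  sup <- cluster_samples(m, "supervised", annotations = ann)
  sub_order <- as.character(ann$subtype[match(sup$leaf_order, ann$sample_id)])
  expect_equal(length(rle(sub_order)$lengths), length(unique(sub_order)))

  # duplicated samples merge first at height zero
  vals <- m$values[, c(1, 1, 2)]
  colnames(vals) <- c("A", "B", "C")
  cl2 <- cluster_samples(count_matrix(vals, m$codeset, raw = FALSE))
  expect_equal(min(cl2$merge_heights), 0)
  expect_error(cluster_samples(m, metric = "cosineish"), "unknown distance")
})
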