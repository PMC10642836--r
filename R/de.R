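#' Choose the two-group test for a gene
#'
#' Shapiro-Wilk normality is assessed in each group separately (on the
#' supplied, typically log2-transformed, values); the classical pooled
#' Student's t-test is used only when both groups look normal (p > 0.05),
#' otherwise the Wilcoxon rank-sum test. Groups that are constant, or too
#' small for Shapiro-Wilk (n < 3), fall to the Wilcoxon branch.
#'
#' @param values_a,values_b numeric vectors for the two groups.
#' @return A list: `test` (`"student_t"` or `"wilcoxon"`), `shapiro_p_a`,
#'   `shapiro_p_b` (NA when undefined).
#' @export
choose_test <- function(values_a, values_b) {
  sw <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) {
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(values_a)
  pb <- sw(values_b)
  parametric <- !is.na(pa) && !is.na(pb) && pa > 0.05 && pb > 0.05
  list(test = if (parametric) "student_t" else "wilcoxon",
       shapiro_p_a = pa, shapiro_p_b = pb)
}

#' Two-group test on a chosen branch
#'
#' The parametric branch is the classical pooled-variance two-sided
#' Student's t-test; the non-parametric branch is the Wilcoxon (Mann-Whitney)
#' rank-sum test, exact by enumeration when the combined sample size is at
#' most 12 and tie-free, otherwise the normal approximation with tie and
#' continuity correction. Degenerate parametric input (zero pooled variance)
#' reroutes to the Wilcoxon branch; two identical constant groups give p = 1.
#'
#' @param values_a,values_b numeric vectors.
#' @param choice `"student_t"` or `"wilcoxon"` (from [choose_test()]).
#' @return A list: `test` (branch actually used), `statistic` (t or W),
#'   `p`.
#' @export
de_test <- function(values_a, values_b, choice = c("wilcoxon", "student_t")) {
  choice <- match.arg(choice)
  pooled_sd_zero <- stats::sd(c(values_a - mean(values_a),
                                values_b - mean(values_b))) == 0
  if (choice == "student_t" && pooled_sd_zero) choice <- "wilcoxon"
  if (choice == "student_t") {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    return(list(test = "student_t", statistic = unname(ht$statistic),
                p = ht$p.value))
  }
  if (pooled_sd_zero && mean(values_a) == mean(values_b)) {
    return(list(test = "wilcoxon", statistic = length(values_a) *
                  length(values_b) / 2, p = 1))
  }
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- n <= 12 && !ties
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = exact, correct = TRUE))
  list(test = "wilcoxon", statistic = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1, with
#' the original order restored.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change with a pseudocount
#'
#' `log2((mean_a + 1) / (mean_b + 1))`; positive values mean higher
#' expression in group A (URB).
#'
#' @param values_a,values_b non-negative numeric vectors.
#' @return Signed log2 fold change.
#' @export
log2_fold_change <- function(values_a, values_b) {
  log2((mean(values_a) + 1) / (mean(values_b) + 1))
}

#' Per-gene two-group differential expression
#'
#' Tests every above-noise endogenous gene for a URB-vs-DRB difference on
#' log2(x+1)-transformed normalized counts, choosing the test per gene via
#' [choose_test()]; control samples and below-noise genes never enter, and
#' the FDR adjustment runs over exactly the tested set.
#'
#' @param m a normalized [count_matrix()].
#' @param annotations annotation data frame (see [read_annotations()]).
#' @param noise_calls [noise_filter()] output; `NULL` tests all endogenous
#'   genes.
#' @param alpha significance level on the adjusted q (default 0.05).
#' @return Data frame sorted by `q_fdr` then decreasing `|log2_fc|`:
#'   `gene`, `test_used`, `shapiro_p_a`, `shapiro_p_b`, `statistic`,
#'   `p_raw`, `q_fdr`, `log2_fc`, `significant`.
#' @export
run_de <- function(m, annotations, noise_calls = NULL, alpha = 0.05) {
  stopifnot(inherits(m, "rbdge_count_matrix"))
  annotations <- as.data.frame(annotations)
  annotations <- annotations[match(sample_ids(m), annotations$sample_id), ]
  if (any(is.na(annotations$sample_id))) {
    stop("annotations do not cover every sample in the matrix")
  }
  a_ids <- annotations$sample_id[annotations$subtype == "URB"]
  b_ids <- annotations$sample_id[annotations$subtype == "DRB"]
  if (length(a_ids) < 2 || length(b_ids) < 2) {
    stop("cohort error: need at least 2 samples in each subtype")
  }
  vals <- class_values(m, "Endogenous")
  genes <- rownames(vals)
  if (!is.null(noise_calls)) {
    keep <- noise_calls$gene[noise_calls$above_noise]
    genes <- intersect(genes, keep)
  }
  if (length(genes) == 0) {
    stop("no above-noise endogenous genes to test")
  }
  lv <- log2(vals[genes, , drop = FALSE] + 1)
  res <- lapply(genes, function(g) {
    xa <- lv[g, a_ids]
    xb <- lv[g, b_ids]
    ch <- choose_test(xa, xb)
    tst <- de_test(xa, xb, ch$test)
    data.frame(gene = g, test_used = tst$test,
               shapiro_p_a = ch$shapiro_p_a, shapiro_p_b = ch$shapiro_p_b,
               statistic = tst$statistic, p_raw = tst$p,
               log2_fc = log2_fold_change(vals[g, a_ids], vals[g, b_ids]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_fdr <- bh_adjust(res$p_raw)
  res$significant <- res$q_fdr <= alpha
  res <- res[order(res$q_fdr, -abs(res$log2_fc)), ]
  rownames(res) <- NULL
  res[, c("gene", "test_used", "shapiro_p_a", "shapiro_p_b", "statistic",
          "p_raw", "q_fdr", "log2_fc", "significant")]
}

#' Mean-variance quality control
#'
#' Per-gene log2 mean against log2 variance, fitted by least squares; genes
#' whose residual exceeds 3 median absolute deviations are flagged as
#' outliers. Per-sample totals are screened with the same 3-MAD rule.
#'
#' @param m a [count_matrix()].
#' @return A list: `gene_stats` (gene, log2 mean, log2 variance, residual,
#'   outlier flag), `sample_stats` (sample, total, outlier flag),
#'   `slope`/`intercept` of the fit (NA when degenerate).
#' @export
mean_variance_qc <- function(m) {
  stopifnot(inherits(m, "rbdge_count_matrix"))
  vals <- class_values(m, "Endogenous")
  if (nrow(vals) < 3 || ncol(vals) < 3) {
    stop("mean-variance QC needs at least 3 genes and 3 samples")
  }
  mu <- rowMeans(vals)
  v <- apply(vals, 1, stats::var)
  lmu <- log2(mu + 1)
  lv <- log2(v + 1)
  if (stats::sd(lmu) == 0) {
    gene_stats <- data.frame(gene = rownames(vals), log2_mean = lmu,
                             log2_var = lv, residual = 0, outlier = FALSE,
                             stringsAsFactors = FALSE)
    slope <- NA_real_; intercept <- NA_real_
  } else {
    fit <- stats::lm.fit(cbind(1, lmu), lv)
    resid <- fit$residuals
    madv <- stats::mad(resid)
    out <- if (madv == 0) rep(FALSE, length(resid)) else abs(resid) > 3 * madv
    gene_stats <- data.frame(gene = rownames(vals), log2_mean = lmu,
                             log2_var = lv, residual = unname(resid),
                             outlier = unname(out), stringsAsFactors = FALSE)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  }
  totals <- colSums(vals)
  madt <- stats::mad(totals)
  s_out <- if (madt == 0) rep(FALSE, length(totals)) else {
    abs(totals - stats::median(totals)) > 3 * madt
  }
  list(gene_stats = gene_stats,
       sample_stats = data.frame(sample_id = colnames(vals),
                                 total = unname(totals),
                                 outlier = unname(s_out),
                                 stringsAsFactors = FALSE),
       slope = unname(slope), intercept = unname(intercept))
}

#' Pearson or Spearman correlation with a t-based p-value
#'
#' Pearson's r with its exact t reference distribution (df = n - 2);
#' Spearman's rho is Pearson on average ranks with the same p formula.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `estimate`, `statistic` (t), `p`, `method`.
#' @export
correlation_analysis <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(estimate = r, statistic = tt, p = min(p, 1), method = method)
}

#' Sample-sample correlation matrix
#'
#' @param m a [count_matrix()].
#' @param method `"pearson"` or `"spearman"`.
#' @return Square correlation matrix over samples (endogenous probes,
#'   log2(x+1) scale), with the method recorded as an attribute.
#' @export
correlation_matrix <- function(m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  lv <- log2(class_values(m, "Endogenous") + 1)
  cm <- stats::cor(lv, method = method)
  attr(cm, "method") <- method
  cm
}

#' Principal component analysis of samples
#'
#' Genes are centered; scores come from the singular value decomposition of
#' the centered sample-by-gene matrix, variance fractions from the squared
#' singular values.
#'
#' @param m a [count_matrix()].
#' @param log2_transform analyse log2(x+1) values (default `TRUE`).
#' @return A list: `scores` (samples x components), `variance_explained`.
#' @export
pca_samples <- function(m, log2_transform = TRUE) {
  stopifnot(inherits(m, "rbdge_count_matrix"))
  vals <- class_values(m, "Endogenous")
  if (log2_transform) vals <- log2(vals + 1)
  x <- t(vals)                               # samples x genes
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  scores <- x %*% sv$v[, seq_len(max(k, 1)), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ve <- if (sum(sv$d^2) == 0) rep(0, ncol(scores)) else {
    (sv$d^2 / sum(sv$d^2))[seq_len(ncol(scores))]
  }
  list(scores = scores, variance_explained = ve)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on log2(x+1) endogenous counts
#' (default Euclidean distance, complete linkage). Supervised mode clusters
#' within each subtype separately and concatenates the leaf orders, so
#' subtypes never interleave.
#'
#' @param m a [count_matrix()].
#' @param mode `"unsupervised"` or `"supervised"`.
#' @param annotations required for supervised mode.
#' @param metric distance metric accepted by [stats::dist()].
#' @param linkage agglomeration method accepted by [stats::hclust()].
#' @return A list: `mode`, `leaf_order` (sample ids), `merge_heights`, and
#'   `trees` (the underlying `hclust` object(s)).
#' @export
cluster_samples <- function(m, mode = c("unsupervised", "supervised"),
                            annotations = NULL, metric = "euclidean",
                            linkage = "complete") {
  mode <- match.arg(mode)
  if (!metric %in% c("euclidean", "maximum", "manhattan", "canberra",
                     "binary", "minkowski")) {
    stop("unknown distance metric: ", metric)
  }
  if (!linkage %in% c("ward.D", "ward.D2", "single", "complete", "average",
                      "mcquitty", "median", "centroid")) {
    stop("unknown linkage: ", linkage)
  }
  lv <- t(log2(class_values(m, "Endogenous") + 1))
  one_tree <- function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::hclust(stats::dist(x, method = metric), method = linkage)
  }
  if (mode == "unsupervised") {
    hc <- one_tree(lv)
    return(list(mode = mode, leaf_order = rownames(lv)[hc$order],
                merge_heights = hc$height, trees = list(all = hc)))
  }
  if (is.null(annotations)) stop("supervised clustering needs annotations")
  annotations <- as.data.frame(annotations)
  sub <- annotations$subtype[match(rownames(lv), annotations$sample_id)]
  trees <- list(); leaf_order <- character(0); heights <- numeric(0)
  for (s in unique(as.character(sub))) {
    ids <- rownames(lv)[sub == s]
    x <- lv[ids, , drop = FALSE]
    hc <- one_tree(x)
    trees[[s]] <- hc
    leaf_order <- c(leaf_order, if (is.null(hc)) ids else ids[hc$order])
    if (!is.null(hc)) heights <- c(heights, hc$height)
  }
  list(mode = mode, leaf_order = leaf_order, merge_heights = heights,
       trees = trees)
}
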