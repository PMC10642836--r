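as_event_label <- function(labels, positive = "URB") {
  lab <- as.character(labels)
  if (!any(lab == positive) || all(lab == positive)) {
    stop("both classes must be present (positive class '", positive, "')")
  }
  lab == positive
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity over every distinct threshold: midpoints
#' between adjacent sorted unique values plus the two infinite endpoints.
#' Samples are called positive (URB) when the value exceeds the threshold.
#'
#' @param values numeric marker values, one per sample.
#' @param labels class labels; `positive` marks the event class.
#' @param positive positive-class label (default `"URB"`).
#' @return Data frame: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(values, labels, positive = "URB") {
  y <- as_event_label(labels, positive)
  u <- sort(unique(values))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(values[y] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(values[!y] <= t), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) sample pairs in
#' which the positive sample scores higher, ties counting one half —
#' identical to the trapezoidal area under the empirical curve.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(values, labels, positive = "URB") {
  y <- as_event_label(labels, positive)
  r <- rank(values)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  u <- sum(r[y]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Bootstrap internal validation of the AUC
#'
#' Resamples the full cohort with replacement `B` times (default 1,000
#' iterations, the published internal-validation setting); resamples
#' missing a class are redrawn and the attempts counted. The confidence
#' interval is the 2.5/97.5 percentile of the bootstrap AUC distribution.
#'
#' @inheritParams roc_curve
#' @param B bootstrap iterations (>= 1).
#' @param seed integer RNG seed; same seed, same interval.
#' @return A list: `auc` (point estimate on the original sample),
#'   `ci_low`, `ci_high`, `B`, `seed`, `attempts` (total draws including
#'   redraws), `boot_auc` (the B resample values).
#' @export
bootstrap_auc <- function(values, labels, B = 1000, seed = 20231030,
                          positive = "URB") {
  if (B < 1) stop("B must be at least 1")
  y <- as_event_label(labels, positive)
  n <- length(values)
  point <- auc(values, labels, positive)
  with_seed(seed, {
    boots <- numeric(B)
    attempts <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        attempts <- attempts + 1L
        if (any(y[idx]) && !all(y[idx])) break
      }
      boots[b] <- auc(values[idx], ifelse(y[idx], positive, "other"),
                      positive)
    }
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    list(auc = point, ci_low = ci[1], ci_high = ci[2], B = B, seed = seed,
         attempts = attempts, boot_auc = boots)
  })
}

#' Youden-optimal marker cutoff
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the ROC
#' thresholds; ties are broken toward the cutoff nearest the pooled median
#' of the values. When the marker's AUC is below 0.5 its direction is
#' flipped (reported `down-in-URB`) before the cutoff search, so J is
#' always computed on the informative orientation.
#'
#' @inheritParams roc_curve
#' @return A list of class `rbdge_marker`: `cutoff`, `direction`
#'   (`"up-in-URB"`/`"down-in-URB"`), `j` (Youden's J at the cutoff),
#'   `auc` (on the oriented values).
#' @export
youden_cutoff <- function(values, labels, positive = "URB") {
  a <- auc(values, labels, positive)
  direction <- if (a < 0.5) "down-in-URB" else "up-in-URB"
  v <- if (direction == "down-in-URB") -values else values
  roc <- roc_curve(v, labels, positive)
  finite <- is.finite(roc$threshold)
  if (!any(finite)) stop("cutoff undefined: degenerate ROC (single point)")
  j <- roc$sensitivity + roc$specificity - 1
  best_j <- max(j)
  cand <- which(j == best_j & finite)
  if (length(cand) == 0) cand <- which(j == best_j)
  med <- stats::median(v)
  cutoff <- roc$threshold[cand[which.min(abs(roc$threshold[cand] - med))]]
  structure(list(cutoff = if (direction == "down-in-URB") -cutoff else cutoff,
                 oriented_cutoff = cutoff,
                 direction = direction, j = best_j,
                 auc = max(a, 1 - a)),
            class = "rbdge_marker")
}

#' Binarize marker values at a cutoff
#'
#' `1` marks the event side of the cutoff given the marker's direction
#' ("1 equaling a better chance of an event", i.e. URB).
#'
#' @param marker a [youden_cutoff()] result.
#' @param values numeric marker values.
#' @return Integer 0/1 vector.
#' @export
binarize_marker <- function(marker, values) {
  v <- if (marker$direction == "down-in-URB") -values else values
  as.integer(v > marker$oriented_cutoff)
}

#' Composite marker score
#'
#' Per-sample sum of the binarized marker indicators.
#'
#' @param binarized list (or matrix with markers in columns) of 0/1
#'   per-sample vectors, all over the same samples.
#' @return Integer score vector in `[0, G]` with attribute `n_markers`.
#' @export
composite_score <- function(binarized) {
  if (is.matrix(binarized)) binarized <- asplit(binarized, 2)
  if (length(binarized) == 0) stop("empty marker panel")
  n <- unique(lengths(binarized))
  if (length(n) != 1) stop("markers disagree on the sample set")
  s <- Reduce(`+`, lapply(binarized, as.integer))
  attr(s, "n_markers") <- length(binarized)
  s
}

#' Sensitivity and specificity of the composite score
#'
#' Classifies a sample as URB when its score reaches the threshold and
#' reports the operating point plus the full threshold sweep.
#'
#' @param score integer composite score per sample.
#' @param labels class labels.
#' @param threshold integer decision threshold (classify URB iff
#'   score >= threshold).
#' @param positive positive-class label.
#' @return A list: `sensitivity`, `specificity`, `threshold`, `sweep`
#'   (data frame over all thresholds 0..max+1).
#' @export
score_performance <- function(score, labels, threshold, positive = "URB") {
  y <- as_event_label(labels, positive)
  op <- function(t) {
    call_pos <- score >= t
    c(sensitivity = mean(call_pos[y]), specificity = mean(!call_pos[!y]))
  }
  sweep_t <- 0:(max(score) + 1)
  sw <- t(vapply(sweep_t, op, numeric(2)))
  at <- op(threshold)
  list(sensitivity = unname(at[1]), specificity = unname(at[2]),
       threshold = threshold,
       sweep = data.frame(threshold = sweep_t, sensitivity = sw[, 1],
                          specificity = sw[, 2]))
}

logistic <- function(a, b, s) 1 / (1 + exp(-(a + b * s)))

#' Nonlinear (weighted) least-squares subtype probability model
#'
#' Fits `P(URB | S) = 1 / (1 + exp(-(a + b S)))` to the 0/1 subtype
#' indicator by damped Gauss-Newton (Levenberg-Marquardt) on the weighted
#' least-squares objective — not maximum likelihood. Starts at a = b = 0,
#' relative tolerance 1e-8, at most 500 iterations; on separable data the
#' slope is capped at |b| <= 50 and the fit flagged `"boundary"`.
#'
#' @param scores numeric (typically the composite score), >= 2 distinct
#'   values.
#' @param labels class labels.
#' @param weights per-observation weights (default uniform).
#' @param positive positive-class label.
#' @return A list of class `rbdge_prob_model`: `a`, `b`, `converged`
#'   (`"converged"`, `"boundary"` or `"maxiter"`), `iterations`, `rss`.
#' @export
fit_probability_model <- function(scores, labels, weights = NULL,
                                  positive = "URB") {
  y <- as.numeric(as_event_label(labels, positive))
  if (length(unique(scores)) < 2) {
    stop("need at least 2 distinct score values")
  }
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  if (length(w) != length(y) || any(w < 0)) stop("invalid weights")
  theta <- c(a = 0, b = 0)
  lambda <- 1e-3
  b_cap <- 50
  rss <- function(th) sum(w * (y - logistic(th[1], th[2], scores))^2)
  cur <- rss(theta)
  it <- 0
  status <- "maxiter"
  for (it in seq_len(500)) {
    p <- logistic(theta[1], theta[2], scores)
    r <- y - p
    dp <- p * (1 - p)                       # d p / d eta
    J <- cbind(a = dp, b = dp * scores)
    g <- crossprod(J, w * r)
    H <- crossprod(J, w * J)
    step_ok <- FALSE
    for (k in 1:30) {
      delta <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        cand[2] <- max(min(cand[2], b_cap), -b_cap)
        new <- rss(cand)
        if (new <= cur) {
          step_ok <- TRUE
          lambda <- max(lambda / 3, 1e-12)
          break
        }
      }
      lambda <- lambda * 3
    }
    if (!step_ok) { status <- "converged"; break }
    improvement <- (cur - new) / max(cur, .Machine$double.eps)
    theta <- cand
    cur <- new
    if (improvement < 1e-8) { status <- "converged"; break }
  }
  if (abs(theta[2]) >= b_cap) status <- "boundary"
  structure(list(a = unname(theta[1]), b = unname(theta[2]),
                 converged = status, iterations = it, rss = cur,
                 weights = w),
            class = "rbdge_prob_model")
}

#' Predicted subtype probability
#'
#' @param model a [fit_probability_model()] fit.
#' @param score numeric score(s).
#' @return Probabilities in (0, 1), monotone in the score when `b > 0`.
#' @export
predict_probability <- function(model, score) {
  stopifnot(inherits(model, "rbdge_prob_model"))
  logistic(model$a, model$b, score)
}

#' Select a marker panel from differential-expression results
#'
#' Significant genes ranked by (oriented) AUC; the top `k` become the panel,
#' each binarized at its Youden cutoff.
#'
#' @param de a [run_de()] result.
#' @param m the normalized [count_matrix()].
#' @param annotations annotation data frame.
#' @param k panel size (default 5).
#' @return A list: `genes`, `markers` (per-gene [youden_cutoff()]),
#'   `binarized` (matrix samples x genes), `score` (composite),
#'   `sample_ids`, `labels`.
#' @export
select_markers <- function(de, m, annotations, k = 5) {
  annotations <- as.data.frame(annotations)
  tumor <- annotations$sample_id[annotations$subtype %in% c("URB", "DRB")]
  tumor <- intersect(sample_ids(m), tumor)
  labels <- as.character(
    annotations$subtype[match(tumor, annotations$sample_id)])
  sig <- de$gene[de$significant]
  if (length(sig) == 0) stop("no significant genes to build a panel from")
  vals <- class_values(m, "Endogenous")[, tumor, drop = FALSE]
  aucs <- vapply(sig, function(g) {
    a <- auc(vals[g, ], labels)
    max(a, 1 - a)
  }, numeric(1))
  genes <- sig[order(-aucs)][seq_len(min(k, length(sig)))]
  markers <- lapply(genes, function(g) youden_cutoff(vals[g, ], labels))
  names(markers) <- genes
  bin <- vapply(genes, function(g) binarize_marker(markers[[g]], vals[g, ]),
                integer(length(tumor)))
  rownames(bin) <- tumor
  list(genes = genes, markers = markers, binarized = bin,
       score = composite_score(bin), sample_ids = tumor, labels = labels)
}
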