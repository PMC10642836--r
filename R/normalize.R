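geometric_mean <- function(x) exp(mean(log(x)))

#' Positive-control technical normalization with background subtraction
#'
#' Step 1 scales every lane by `f_l = mean(g) / g_l`, where `g_l` is the
#' lane's geometric mean over positive-control counts and `mean(g)` the
#' cohort arithmetic mean of those geometric means — so lanes with weak
#' overall signal are scaled up. Step 2 estimates the lane's background from
#' its (scaled) negative controls as `tau_l = mu_l + 2 * sd_l` and subtracts
#' it from every endogenous and housekeeping probe, flooring at zero.
#' Control probes are carried through scaled but unsubtracted for audit.
#'
#' @param raw a raw [count_matrix()] with at least one positive and two
#'   negative control probes.
#' @param subtract_first if `TRUE`, background is estimated and subtracted
#'   on the unscaled lane before positive-control scaling (the alternative
#'   operation order; default `FALSE`).
#' @return A list: `matrix` (technically normalized [count_matrix()]),
#'   `factors` (data frame with per-lane `pos_geo_mean` and `factor`),
#'   `backgrounds` (data frame with per-lane `mean`, `sd`, `threshold`).
#' @export
technical_normalize <- function(raw, subtract_first = FALSE) {
  stopifnot(inherits(raw, "rbdge_count_matrix"))
  pos <- class_values(raw, "Positive")
  neg <- class_values(raw, "Negative")
  if (nrow(pos) < 1) stop("technical normalization needs positive controls")
  if (nrow(neg) < 2) {
    stop("background SD undefined: need at least 2 negative controls")
  }
  zero_pos <- colSums(pos == 0) > 0
  if (any(zero_pos)) {
    stop("factor error: zero positive-control count in lane ",
         colnames(pos)[zero_pos][1], " (geometric mean undefined)")
  }
  g <- apply(pos, 2, geometric_mean)
  f <- mean(g) / g

  vals <- raw$values
  if (subtract_first) {
    bg <- background_estimate(neg)
    vals <- subtract_background(vals, raw$codeset, bg$threshold)
    vals <- sweep(vals, 2, f, `*`)
  } else {
    vals <- sweep(vals, 2, f, `*`)
    bg <- background_estimate(sweep(neg, 2, f, `*`))
    vals <- subtract_background(vals, raw$codeset, bg$threshold)
  }
  list(
    matrix = count_matrix(vals, raw$codeset, raw = FALSE),
    factors = data.frame(sample_id = names(f), pos_geo_mean = unname(g),
                         factor = unname(f), stringsAsFactors = FALSE),
    backgrounds = bg
  )
}

# per-lane negative-control mean + 2 SD (n-1 denominator)
background_estimate <- function(neg) {
  mu <- colMeans(neg)
  sdv <- apply(neg, 2, stats::sd)
  data.frame(sample_id = colnames(neg), mean = unname(mu), sd = unname(sdv),
             threshold = unname(mu + 2 * sdv), stringsAsFactors = FALSE)
}

subtract_background <- function(vals, cs, threshold) {
  target <- cs$code_class %in% c("Endogenous", "Housekeeping")
  vals[target, ] <- pmax(sweep(vals[target, , drop = FALSE], 2, threshold,
                               `-`), 0)
  vals
}

#' Reference-gene (housekeeping) biological normalization
#'
#' Each lane is multiplied by `r_l = mean(h) / h_l`, where `h_l` is the
#' geometric mean over the lane's housekeeping probes with count > 0 and
#' `mean(h)` the cohort arithmetic mean of those geometric means.
#'
#' @param m a [count_matrix()] (normally the output of
#'   [technical_normalize()]).
#' @return A list: `matrix` (normalized [count_matrix()]), `factors` (data
#'   frame with per-lane `hk_geo_mean` and `factor`).
#' @export
reference_normalize <- function(m) {
  stopifnot(inherits(m, "rbdge_count_matrix"))
  hk <- class_values(m, "Housekeeping")
  if (nrow(hk) < 1) stop("no housekeeping probes in matrix")
  h <- vapply(seq_len(ncol(hk)), function(j) {
    x <- hk[, j]
    x <- x[x > 0]
    if (length(x) == 0) {
      stop("normalization error: all housekeeping counts are zero in lane ",
           colnames(hk)[j])
    }
    geometric_mean(x)
  }, numeric(1))
  r <- mean(h) / h
  vals <- sweep(m$values, 2, r, `*`)
  list(
    matrix = count_matrix(vals, m$codeset, raw = FALSE),
    factors = data.frame(sample_id = colnames(hk), hk_geo_mean = unname(h),
                         factor = unname(r), stringsAsFactors = FALSE)
  )
}

#' Above-noise decision per endogenous gene
#'
#' One-sample, one-sided t-test of each endogenous gene's per-sample
#' normalized counts against the basal noise level `mu0` — by default the
#' cohort mean of the per-lane negative-control thresholds
#' `tau_l = mu_l + 2 sd_l` recomputed on the normalized scale. Genes with
#' p > 0.05 are interpreted as not sufficiently expressed to overcome basal
#' noise. Zero-variance genes get the limit decision (p = 0 above, 1 below,
#' 0.5 exactly at `mu0`) rather than an error.
#'
#' @param m a normalized [count_matrix()] with >= 2 samples.
#' @param backgrounds data frame with a `threshold` column (per lane), as
#'   produced by [technical_normalize()] but on the normalized scale.
#' @param per_lane if `TRUE`, each sample's count is tested against its own
#'   lane threshold (the count minus `tau_l` against 0) instead of the
#'   pooled mean threshold.
#' @param alpha decision level (default 0.05).
#' @return Data frame, one row per endogenous gene: `gene`, `t`, `p`,
#'   `above_noise`.
#' @export
noise_filter <- function(m, backgrounds, per_lane = FALSE, alpha = 0.05) {
  stopifnot(inherits(m, "rbdge_count_matrix"))
  vals <- class_values(m, "Endogenous")
  if (ncol(vals) < 2) stop("noise filter needs at least 2 samples")
  if (per_lane) {
    vals <- sweep(vals, 2, backgrounds$threshold, `-`)
    mu0 <- 0
  } else {
    mu0 <- mean(backgrounds$threshold)
  }
  n <- ncol(vals)
  mean_g <- rowMeans(vals)
  sd_g <- apply(vals, 1, stats::sd)
  tt <- (mean_g - mu0) / (sd_g / sqrt(n))
  p <- stats::pt(tt, df = n - 1, lower.tail = FALSE)
  degen <- sd_g == 0
  tt[degen] <- 0
  p[degen] <- ifelse(mean_g[degen] > mu0, 0,
                     ifelse(mean_g[degen] < mu0, 1, 0.5))
  data.frame(gene = rownames(vals), t = unname(tt), p = unname(p),
             above_noise = unname(p <= alpha), stringsAsFactors = FALSE)
}

#' Full normalization pipeline
#'
#' Composes [technical_normalize()] (positive-control scaling + background
#' subtraction), [reference_normalize()] (housekeeping scaling) and
#' [noise_filter()] in that order, returning every intermediate for audit.
#' Below-noise genes are flagged, not removed; downstream differential
#' expression excludes them.
#'
#' @param raw a raw [count_matrix()].
#' @inheritParams technical_normalize
#' @inheritParams noise_filter
#' @return A list of class `rbdge_normalized`: `matrix` (final normalized
#'   [count_matrix()]), `technical_factors`, `backgrounds` (on the final
#'   normalized scale), `reference_factors`, `noise_calls`.
#' @export
normalize_pipeline <- function(raw, subtract_first = FALSE,
                               per_lane = FALSE, alpha = 0.05) {
  tech <- technical_normalize(raw, subtract_first = subtract_first)
  ref <- reference_normalize(tech$matrix)
  # thresholds on the final normalized scale: negatives after both scalings
  bg_norm <- background_estimate(class_values(ref$matrix, "Negative"))
  calls <- noise_filter(ref$matrix, bg_norm, per_lane = per_lane,
                        alpha = alpha)
  structure(list(matrix = ref$matrix,
                 technical_factors = tech$factors,
                 backgrounds = bg_norm,
                 reference_factors = ref$factors,
                 noise_calls = calls),
            class = "rbdge_normalized")
}

#' @export
print.rbdge_normalized <- function(x, ...) {
  cat("Normalized nCounter cohort:", ncol(x$matrix$values), "samples;",
      sum(x$noise_calls$above_noise), "of", nrow(x$noise_calls),
      "endogenous genes above noise\n")
  invisible(x)
}
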