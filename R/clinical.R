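#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction: the uncorrected statistic is what reproduces
#' the published clinical-table p-values.
#'
#' @param tab integer matrix, at least 2x2.
#' @return A list: `test`, `statistic` (chi-squared), `df`, `p`.
#' @export
chisq_test <- function(tab) {
  tab <- validate_table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared statistic undefined: zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = "chi-squared", statistic = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided by the point-probability rule: the p-value sums the
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param tab 2x2 integer matrix.
#' @return A list: `test`, `p`, `odds_ratio` (conditional MLE).
#' @export
fisher_exact <- function(tab) {
  tab <- validate_table(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_exact expects a 2x2 table")
  ht <- stats::fisher.test(tab)
  list(test = "fisher", p = ht$p.value, odds_ratio = unname(ht$estimate))
}

validate_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be non-negative integers")
  }
  tab
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic referred to the chi-squared distribution with
#' k - 1 degrees of freedom. A fully tied sample (all values equal) returns
#' H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, parallel to `values`, >= 2 non-empty groups.
#' @return A list: `test`, `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("Kruskal-Wallis needs at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  if (length(unique(values)) == 1) {
    return(list(test = "kruskal-wallis", statistic = 0,
                df = nlevels(groups) - 1, p = 1))
  }
  ht <- stats::kruskal.test(values, groups)
  list(test = "kruskal-wallis", statistic = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Shared engine with the differential-expression module: exact enumeration
#' when the combined n is at most 12 and tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param values_a,values_b numeric vectors (each n >= 1).
#' @return A list: `test`, `statistic` (W), `p`.
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) < 1 || length(values_b) < 1) {
    stop("both groups need at least one observation")
  }
  r <- de_test(values_a, values_b, "wilcoxon")
  list(test = "mann-whitney", statistic = r$statistic, p = r$p)
}

#' Clinical characteristics table by subtype
#'
#' Reproduces the published table's statistical battery on an annotation
#' table: sex and laterality by uncorrected chi-squared, age in months by
#' Mann-Whitney, the three age bins (<18, 18-36, >36 months) by
#' Kruskal-Wallis with the bins as groups, N and C tumor stage by
#' Kruskal-Wallis on ordinal codes, and RB1 germline status by Fisher's
#' exact test. Control samples are excluded.
#'
#' @param annotations annotation data frame (see [read_annotations()]).
#' @return Data frame with one row per characteristic: `characteristic`,
#'   `test`, `statistic`, `p`.
#' @export
build_table1 <- function(annotations) {
  ann <- as.data.frame(annotations)
  required <- c("subtype", "sex", "laterality", "age_months", "n_stage",
                "c_stage", "rb1_germline")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotations lack column(s): ", paste(missing, collapse = ", "))
  }
  ann <- ann[ann$subtype %in% c("URB", "DRB"), ]
  ann$subtype <- factor(as.character(ann$subtype), levels = c("URB", "DRB"))
  if (nlevels(droplevels(ann$subtype)) < 2) {
    stop("cohort error: need both URB and DRB samples")
  }
  row <- function(characteristic, res) {
    data.frame(characteristic = characteristic, test = res$test,
               statistic = if (is.null(res$statistic)) NA_real_
                           else res$statistic,
               p = res$p, stringsAsFactors = FALSE)
  }
  age_bin <- cut(ann$age_months, c(-Inf, 18, 36, Inf),
                 labels = c("<18", "18-36", ">36"), right = FALSE)
  out <- rbind(
    row("sex", chisq_test(table(ann$sex, ann$subtype))),
    row("laterality", chisq_test(table(ann$laterality, ann$subtype))),
    row("age_months", mann_whitney(ann$age_months[ann$subtype == "URB"],
                                   ann$age_months[ann$subtype == "DRB"])),
    row("age_category", kruskal_wallis(as.integer(ann$subtype), age_bin)),
    row("n_stage", kruskal_wallis(as.integer(ordered(ann$n_stage)) - 1,
                                  ann$subtype)),
    row("c_stage", kruskal_wallis(as.integer(ordered(ann$c_stage)) - 1,
                                  ann$subtype)),
    row("rb1_germline",
        fisher_exact(table(factor(ann$rb1_germline, levels = c(TRUE, FALSE)),
                           ann$subtype)))
  )
  rownames(out) <- NULL
  out
}

#' Annotation fixture matching the published cohort's clinical table
#'
#' A deterministic 21-sample annotation table (11 URB, 10 DRB) whose
#' marginal counts per characteristic equal the published clinical table:
#' sex 2/9 vs 6/4, laterality 5/6 vs 6/4, RB1 germline 6/5 vs 2/8, N stage
#' 3/6/2 vs 4/6/0, C stage 7/2/2 vs 7/2/1, and ages with medians 14 and
#' 10.5 months, ranges 4-50 and 2-45, binned 8/1/2 and 6/2/2. The joint
#' assignment of covariates to individual samples is arbitrary (the per-row
#' tests only see margins); the raw per-patient ages are not published, so
#' the age vectors here reproduce the printed summaries only.
#'
#' @return Annotation data frame, validated.
#' @export
table1_annotations <- function() {
  urb <- data.frame(
    sample_id = sprintf("URB%02d", 1:11),
    subtype = "URB",
    sex = rep(c("female", "male"), c(2, 9)),
    laterality = rep(c("unilateral", "bilateral"), c(5, 6)),
    age_months = c(4, 6, 8, 10, 12, 14, 16, 17, 24, 40, 50),
    n_stage = rep(c("N0", "N1", "N2"), c(3, 6, 2)),
    c_stage = rep(c("C0", "C1", "C2"), c(7, 2, 2)),
    rb1_germline = rep(c("yes", "no"), c(6, 5)),
    stringsAsFactors = FALSE
  )
  drb <- data.frame(
    sample_id = sprintf("DRB%02d", 1:10),
    subtype = "DRB",
    sex = rep(c("female", "male"), c(6, 4)),
    laterality = rep(c("unilateral", "bilateral"), c(6, 4)),
    age_months = c(2, 5, 8, 10, 11, 15, 20, 30, 40, 45),
    n_stage = rep(c("N0", "N1", "N2"), c(4, 6, 0)),
    c_stage = rep(c("C0", "C1", "C2"), c(7, 2, 1)),
    rb1_germline = rep(c("yes", "no"), c(2, 8)),
    stringsAsFactors = FALSE
  )
  validate_annotations(rbind(urb, drb))
}
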