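#' Simulation configuration for synthetic nCounter cohorts
#'
#' Defines a two-subtype retinoblastoma-like cohort profiled on a synthetic
#' panel that mirrors the PanCancer layout: 770 endogenous genes, 30
#' housekeeping (reference) genes, a six-step positive-control ladder and
#' eight negative controls. Endogenous counts follow a negative-binomial
#' (gamma-Poisson) model with per-lane log-normal technical scale factors;
#' negative controls are Poisson around `background_mean`.
#'
#' @param n_group_a URB-like samples (default 11, the study cohort size).
#' @param n_group_b DRB-like samples (default 10).
#' @param n_controls non-tumor control samples (default 2).
#' @param n_endogenous,n_reference,n_pos_controls,n_neg_controls panel layout.
#' @param de_fraction fraction of endogenous genes truly differential.
#' @param lfc_magnitude absolute log2 fold change of DE genes; applied as
#'   +/- `lfc_magnitude/2` to each group so library size stays balanced.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param baseline_log_mean_range log2 bounds for expressed-gene baselines.
#' @param lane_factor_sd standard deviation, on the log scale, of the
#'   log-normal per-lane technical factors; 0 means no technical variation.
#' @param background_mean expected negative-control count per lane.
#' @param background_fraction fraction of endogenous genes sitting at the
#'   negative-control background level (not truly expressed).
#' @param up_genes,down_genes optional probe names forced differential
#'   (up / down in group A) on top of the random draw.
#' @param seed integer RNG seed; the seed fully determines the dataset.
#' @return A validated `rbdge_sim_config` list.
#' @export
sim_config <- function(n_group_a = 11, n_group_b = 10, n_controls = 2,
                       n_endogenous = 770, n_reference = 30,
                       n_pos_controls = 6, n_neg_controls = 8,
                       de_fraction = 0.2, lfc_magnitude = 1.5,
                       nb_dispersion = 0.1,
                       baseline_log_mean_range = c(6.5, 12),
                       lane_factor_sd = 0.15,
                       background_mean = 15,
                       background_fraction = 0.06,
                       up_genes = NULL, down_genes = NULL,
                       seed = 20231030) {
  cfg <- list(n_group_a = n_group_a, n_group_b = n_group_b,
              n_controls = n_controls, n_endogenous = n_endogenous,
              n_reference = n_reference, n_pos_controls = n_pos_controls,
              n_neg_controls = n_neg_controls, de_fraction = de_fraction,
              lfc_magnitude = lfc_magnitude, nb_dispersion = nb_dispersion,
              baseline_log_mean_range = baseline_log_mean_range,
              lane_factor_sd = lane_factor_sd,
              background_mean = background_mean,
              background_fraction = background_fraction,
              up_genes = up_genes, down_genes = down_genes,
              seed = as.integer(seed))
  pos_int <- c("n_group_a", "n_group_b", "n_endogenous", "n_reference",
               "n_pos_controls", "n_neg_controls")
  for (f in pos_int) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      stop("configuration error: ", f, " must be a positive count")
    }
  }
  if (cfg$n_controls < 0) stop("configuration error: n_controls < 0")
  if (cfg$n_group_a + cfg$n_group_b < 4) {
    stop("configuration error: need at least 4 tumor samples in total")
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("configuration error: de_fraction outside [0,1]")
  }
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1) {
    stop("configuration error: background_fraction outside [0,1)")
  }
  if (cfg$lfc_magnitude <= 0) stop("configuration error: lfc_magnitude <= 0")
  if (cfg$nb_dispersion <= 0) stop("configuration error: nb_dispersion <= 0")
  if (cfg$lane_factor_sd < 0) stop("configuration error: lane_factor_sd < 0")
  if (cfg$background_mean <= 0) stop("configuration error: background_mean <= 0")
  if (length(cfg$baseline_log_mean_range) != 2 ||
      diff(cfg$baseline_log_mean_range) < 0) {
    stop("configuration error: baseline_log_mean_range must be an ordered pair")
  }
  class(cfg) <- "rbdge_sim_config"
  cfg
}

# standard nCounter positive-control ladder, fM
pos_control_ladder <- function(n) 128 / 4^(seq_len(n) - 1)

# counts per fM at the top of the ladder; gives ~25,000 counts at 128 fM
POS_COUNTS_PER_FM <- 200

#' Build the synthetic CodeSet for a simulation configuration
#'
#' Endogenous probe names start with the curated pathway gene symbols bundled
#' with the package (so pathway overlays work end-to-end on simulated
#' cohorts) and continue as `GENE###`; housekeeping probes are `HK##`,
#' controls `POS_A...`/`NEG_A...` with the concentration ladder attached to
#' the positives.
#'
#' @param config a [sim_config()].
#' @return A [codeset()].
#' @export
make_codeset <- function(config) {
  stopifnot(inherits(config, "rbdge_sim_config"))
  pathway_genes <- tryCatch(pathway_universe_genes(), error = function(e) character(0))
  n_end <- config$n_endogenous
  end_names <- c(utils::head(pathway_genes, n_end),
                 sprintf("GENE%04d", seq_len(max(0, n_end - length(pathway_genes)))))
  hk_names <- sprintf("HK%02d", seq_len(config$n_reference))
  pos_names <- paste0("POS_", LETTERS[seq_len(config$n_pos_controls)])
  neg_names <- paste0("NEG_", LETTERS[seq_len(config$n_neg_controls)])
  codeset(
    code_class = rep(PROBE_CLASSES,
                     c(n_end, config$n_reference,
                       config$n_pos_controls, config$n_neg_controls)),
    name = c(end_names, hk_names, pos_names, neg_names),
    accession = c(paste0("SYN_", end_names, ".1"),
                  paste0("SYN_", hk_names, ".1"),
                  paste0("ERCC_", pos_names), paste0("ERCC_", neg_names)),
    expected_concentration = c(rep(NA_real_, n_end + config$n_reference),
                               pos_control_ladder(config$n_pos_controls),
                               rep(NA_real_, config$n_neg_controls)),
    panel_name = "rbdge synthetic panel"
  )
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a complete synthetic cohort
#'
#' Draws per-lane technical factors, per-gene baselines, a ground-truth set
#' of differential genes (sign split evenly up/down between the two
#' subtypes), a background stratum of unexpressed genes, and the full raw
#' count matrix including control probes. Clinical covariates for the
#' annotation table are drawn to match the observed cohort proportions and
#' are illustrative, not inferential.
#'
#' @param config a [sim_config()].
#' @return A `rbdge_sim_dataset`: `counts` ([count_matrix()]),
#'   `annotations` (data frame), `truth` (per-endogenous-gene data frame
#'   with `is_de`, `true_lfc`, `is_above_noise`), `lane_factors`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "rbdge_sim_config"))
  cs <- make_codeset(config)
  n_a <- config$n_group_a; n_b <- config$n_group_b; n_c <- config$n_controls
  n <- n_a + n_b + n_c
  subtype <- rep(c("URB", "DRB", "control"), c(n_a, n_b, n_c))
  ids <- c(sprintf("URB%02d", seq_len(n_a)), sprintf("DRB%02d", seq_len(n_b)),
           if (n_c > 0) sprintf("CTRL%02d", seq_len(n_c)))
  end <- probe_names(cs, "Endogenous")
  hk <- probe_names(cs, "Housekeeping")

  with_seed(config$seed, {
    lane_factors <- exp(stats::rnorm(n, 0, config$lane_factor_sd))
    names(lane_factors) <- ids

    rng <- config$baseline_log_mean_range
    baseline <- stats::runif(length(end), rng[1], rng[2])
    names(baseline) <- end

    n_bg <- round(config$background_fraction * length(end))
    bg_genes <- if (n_bg > 0) sample(end, n_bg) else character(0)
    baseline[bg_genes] <- log2(config$background_mean)

    eligible <- setdiff(end, bg_genes)
    n_de <- min(round(config$de_fraction * length(end)), length(eligible))
    de_genes <- if (n_de > 0) sample(eligible, n_de) else character(0)
    sign_de <- stats::setNames(sample(c(-1, 1), length(de_genes), replace = TRUE),
                               de_genes)
    for (g in intersect(config$up_genes, eligible)) sign_de[g] <- 1
    for (g in intersect(config$down_genes, eligible)) sign_de[g] <- -1
    de_genes <- names(sign_de)

    true_lfc <- stats::setNames(numeric(length(end)), end)
    true_lfc[de_genes] <- sign_de * config$lfc_magnitude

    half <- config$lfc_magnitude / 2
    eff <- matrix(0, length(end), n, dimnames = list(end, ids))
    eff[de_genes, subtype == "URB"] <- sign_de * half
    eff[de_genes, subtype == "DRB"] <- -sign_de * half

    size <- 1 / config$nb_dispersion
    mu_end <- outer(2^baseline, lane_factors) * 2^eff
    end_counts <- matrix(stats::rnbinom(length(mu_end), mu = mu_end, size = size),
                         nrow(mu_end), dimnames = dimnames(mu_end))

    hk_base <- stats::runif(length(hk), mean(rng), rng[2])
    mu_hk <- outer(2^hk_base, lane_factors)
    hk_counts <- matrix(stats::rnbinom(length(mu_hk), mu = mu_hk, size = size),
                        nrow(mu_hk), dimnames = list(hk, ids))

    ladder <- pos_control_ladder(config$n_pos_controls)
    mu_pos <- outer(POS_COUNTS_PER_FM * ladder, lane_factors)
    pos_counts <- matrix(stats::rpois(length(mu_pos), mu_pos), nrow(mu_pos),
                         dimnames = list(probe_names(cs, "Positive"), ids))
    mu_neg <- outer(rep(config$background_mean, config$n_neg_controls),
                    lane_factors)
    neg_counts <- matrix(stats::rpois(length(mu_neg), mu_neg), nrow(mu_neg),
                         dimnames = list(probe_names(cs, "Negative"), ids))

    vals <- rbind(end_counts, hk_counts, pos_counts, neg_counts)[cs$name, ,
                                                                 drop = FALSE]
    annotations <- simulate_annotations(ids, subtype)
    truth <- data.frame(
      gene = end,
      is_de = end %in% de_genes,
      true_lfc = unname(true_lfc),
      is_above_noise = !(end %in% bg_genes),
      stringsAsFactors = FALSE
    )
    structure(list(counts = count_matrix(vals, cs, raw = TRUE),
                   annotations = annotations, truth = truth,
                   lane_factors = lane_factors, config = config),
              class = "rbdge_sim_dataset")
  })
}

# clinical covariates drawn with the cohort's observed proportions
simulate_annotations <- function(ids, subtype) {
  n <- length(ids)
  p_male <- c(URB = 9 / 11, DRB = 4 / 10, control = 0.5)[subtype]
  p_bilat <- c(URB = 6 / 11, DRB = 4 / 10, control = 0.5)[subtype]
  p_rb1 <- c(URB = 6 / 11, DRB = 2 / 10, control = 0)[subtype]
  age_med <- c(URB = 14, DRB = 10.5, control = 12)[subtype]
  age <- pmin(pmax(round(stats::rlnorm(n, log(age_med), 0.6)), 2), 50)
  n_probs <- list(URB = c(3, 6, 2) / 11, DRB = c(4, 6, 0) / 10,
                  control = c(1, 0, 0))
  c_probs <- list(URB = c(7, 2, 2) / 11, DRB = c(7, 2, 1) / 10,
                  control = c(1, 0, 0))
  n_stage <- vapply(subtype, function(s) {
    sample(N_STAGE_LEVELS, 1, prob = n_probs[[s]])
  }, "")
  c_stage <- vapply(subtype, function(s) {
    sample(C_STAGE_LEVELS, 1, prob = c_probs[[s]])
  }, "")
  df <- data.frame(
    sample_id = ids,
    subtype = subtype,
    sex = ifelse(stats::runif(n) < p_male, "male", "female"),
    laterality = ifelse(stats::runif(n) < p_bilat, "bilateral", "unilateral"),
    age_months = age,
    n_stage = n_stage,
    c_stage = c_stage,
    rb1_germline = ifelse(stats::runif(n) < p_rb1, "yes", "no"),
    stringsAsFactors = FALSE
  )
  validate_annotations(df)
}

#' Write a simulated dataset to disk
#'
#' Emits one RCC file per sample plus `annotations.csv` and `truth.csv`;
#' the files round-trip losslessly through [read_rcc()] /
#' [read_annotations()].
#'
#' @param dataset a [simulate_dataset()] result.
#' @param directory output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "rbdge_sim_dataset"))
  if (!is.character(directory) || length(directory) != 1 ||
      !nzchar(directory)) {
    stop("I/O error: invalid output directory")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", directory)
  }
  cs <- dataset$counts$codeset
  ids <- sample_ids(dataset$counts)
  files <- character(0)
  for (i in seq_along(ids)) {
    lane <- list(sample_id = ids[i],
                 lane_attributes = c(ID = as.character(i), FovCount = "555",
                                     FovCounted = "555"),
                 counts = dataset$counts$values[, i])
    f <- file.path(directory, paste0(ids[i], ".RCC"))
    write_rcc(lane, cs, f)
    files <- c(files, f)
  }
  ann <- dataset$annotations
  ann$rb1_germline <- ifelse(is.na(ann$rb1_germline), "",
                             ifelse(ann$rb1_germline, "yes", "no"))
  af <- file.path(directory, "annotations.csv")
  utils::write.csv(ann, af, row.names = FALSE)
  tf <- file.path(directory, "truth.csv")
  utils::write.csv(dataset$truth, tf, row.names = FALSE)
  invisible(c(files, af, tf))
}
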