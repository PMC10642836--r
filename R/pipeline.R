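#' Pipeline configuration
#'
#' Collects inputs and parameters for a full run: either a directory of RCC
#' files plus an annotation CSV, or an in-memory simulated dataset.
#'
#' @param rcc_dir directory of `.RCC` lane files (ignored when `dataset`
#'   given).
#' @param annotations_file annotation CSV path.
#' @param dataset optional [simulate_dataset()] result used directly.
#' @param gene_sets_file pathway JSON (default the bundled collection).
#' @param alpha significance level used throughout (default 0.05).
#' @param top_k marker panel size (default 5).
#' @param bootstrap_B bootstrap iterations for marker validation
#'   (default 1000).
#' @param ctree control parameters, see [ctree_params()].
#' @param seed global seed; stage seeds are derived by fixed offsets.
#' @param out_dir output directory, or `NULL` to keep results in memory
#'   only.
#' @return A `rbdge_pipeline_config` list.
#' @export
pipeline_config <- function(rcc_dir = NULL, annotations_file = NULL,
                            dataset = NULL,
                            gene_sets_file = system.file(
                              "extdata", "pathway_sets.json",
                              package = "rbdge"),
                            alpha = 0.05, top_k = 5, bootstrap_B = 1000,
                            ctree = ctree_params(), seed = 20231030,
                            out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha outside (0,1)")
  if (is.null(dataset)) {
    if (is.null(rcc_dir) || !dir.exists(rcc_dir)) {
      stop("config error: rcc_dir does not exist")
    }
    if (is.null(annotations_file) || !file.exists(annotations_file)) {
      stop("config error: annotations_file does not exist")
    }
  }
  if (!file.exists(gene_sets_file)) {
    stop("config error: gene_sets_file does not exist")
  }
  structure(list(rcc_dir = rcc_dir, annotations_file = annotations_file,
                 dataset = dataset, gene_sets_file = gene_sets_file,
                 alpha = alpha, top_k = top_k, bootstrap_B = bootstrap_B,
                 ctree = ctree, seed = as.integer(seed), out_dir = out_dir),
            class = "rbdge_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Normalization -> differential expression -> clinical table -> marker
#' scoring -> conditional inference tree (on the marker genes, with LOOCV)
#' -> pathway overlay, with a manifest recording parameters, seed and
#' per-stage record counts. Identical config and seed give identical
#' results.
#'
#' @param config a [pipeline_config()].
#' @return A `rbdge_pipeline_result` list with every stage's output and a
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rbdge_pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[rbdge] %-12s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  input <- stage("input", {
    if (!is.null(config$dataset)) {
      list(counts = config$dataset$counts,
           annotations = config$dataset$annotations)
    } else {
      files <- sort(list.files(config$rcc_dir, pattern = "\\.[Rr][Cc][Cc]$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no RCC files in ", config$rcc_dir)
      lanes <- lapply(files, read_rcc)
      cs0 <- lanes[[1]]
      cs <- codeset(cs0$code_class, names(cs0$counts), cs0$accession,
                    ifelse(cs0$code_class == "Positive",
                           pos_control_ladder(sum(cs0$code_class == "Positive"))[
                             cumsum(cs0$code_class == "Positive")],
                           NA_real_))
      list(counts = assemble_matrix(lanes, cs),
           annotations = read_annotations(config$annotations_file))
    }
  })

  norm <- stage("normalize", normalize_pipeline(input$counts,
                                                alpha = config$alpha))
  de <- stage("de", run_de(norm$matrix, input$annotations, norm$noise_calls,
                           alpha = config$alpha))
  table1 <- stage("table1", build_table1(input$annotations))
  scoring <- stage("score", {
    panel <- select_markers(de, norm$matrix, input$annotations,
                            k = config$top_k)
    boot <- lapply(seq_along(panel$genes), function(i) {
      g <- panel$genes[i]
      vals <- class_values(norm$matrix, "Endogenous")[g, panel$sample_ids]
      est <- bootstrap_auc(vals, panel$labels, B = config$bootstrap_B,
                           seed = config$seed + 1000L + i)
      est$boot_auc <- NULL
      est$gene <- g
      est
    })
    model <- fit_probability_model(panel$score, panel$labels)
    perf <- score_performance(panel$score, panel$labels,
                              threshold = ceiling(length(panel$genes) / 2))
    list(panel = panel, bootstrap = boot, model = model, performance = perf)
  })
  tree <- stage("ctree", {
    X <- t(class_values(norm$matrix, "Endogenous")[
      scoring$panel$genes, scoring$panel$sample_ids, drop = FALSE])
    fit <- grow_ctree(X, scoring$panel$labels, config$ctree)
    cv <- loocv_ctree(X, scoring$panel$labels, config$ctree)
    list(tree = fit, loocv = cv)
  })
  pathways <- stage("pathway", {
    sets <- load_gene_sets(config$gene_sets_file)
    pathway_overlay(de, sets)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rbdge")),
    seed = config$seed,
    alpha = config$alpha,
    top_k = config$top_k,
    bootstrap_B = config$bootstrap_B,
    n_samples = ncol(input$counts$values),
    n_probes = nrow(input$counts$values),
    stages = list(
      normalize = list(above_noise = sum(norm$noise_calls$above_noise),
                       genes = nrow(norm$noise_calls)),
      de = list(tested = nrow(de), significant = sum(de$significant)),
      table1 = list(rows = nrow(table1)),
      score = list(panel = length(scoring$panel$genes)),
      ctree = list(loocv_accuracy = tree$loocv$accuracy),
      pathway = list(nodes = nrow(pathways),
                     nonzero = sum(pathways$state != 0))
    )
  )
  result <- structure(list(input = input, normalized = norm, de = de,
                           table1 = table1, scoring = scoring, tree = tree,
                           pathways = pathways, manifest = manifest),
                      class = "rbdge_pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write_matrix_csv(result$normalized$matrix, out("normalized.csv"))
  utils::write.csv(result$normalized$noise_calls, out("noise_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(result$de, out("de.csv"), row.names = FALSE)
  utils::write.csv(result$table1, out("table1.csv"), row.names = FALSE)
  utils::write.csv(result$pathways, out("pathway_states.csv"),
                   row.names = FALSE)
  score <- result$scoring
  jsonlite::write_json(
    list(genes = score$panel$genes,
         cutoffs = lapply(score$panel$markers, function(mk) {
           mk[c("cutoff", "direction", "j", "auc")]
         }),
         bootstrap = score$bootstrap,
         score = stats::setNames(as.list(as.integer(score$panel$score)),
                                 score$panel$sample_ids),
         model = list(a = score$model$a, b = score$model$b,
                      converged = score$model$converged)),
    out("score.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
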