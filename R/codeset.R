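#' @keywords internal
"_PACKAGE"

PROBE_CLASSES <- c("Endogenous", "Housekeeping", "Positive", "Negative")

#' Construct a CodeSet probe table
#'
#' A CodeSet describes the probe content of an nCounter panel: endogenous
#' targets, housekeeping (reference) genes, and the spiked positive and
#' negative control probes. Positive controls carry the standard synthetic
#' concentration ladder (128, 32, 8, 2, 0.5, 0.125 fM) as metadata.
#'
#' @param code_class character vector, one of `"Endogenous"`,
#'   `"Housekeeping"`, `"Positive"`, `"Negative"` per probe.
#' @param name unique probe names.
#' @param accession accession strings (defaults to the probe name).
#' @param expected_concentration numeric fM values, `NA` except for
#'   positive-control probes.
#' @param panel_name label for the panel.
#' @return A `data.frame` of class `rbdge_codeset` with one row per probe.
#' @export
codeset <- function(code_class, name, accession = name,
                    expected_concentration = NA_real_,
                    panel_name = "synthetic") {
  code_class <- as.character(code_class)
  bad <- setdiff(unique(code_class), PROBE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown probe code class: ", paste(bad, collapse = ", "))
  }
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("duplicate probe names in codeset: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  expected_concentration <- rep_len(as.numeric(expected_concentration),
                                    length(name))
  if (any(!is.na(expected_concentration) & code_class != "Positive")) {
    stop("expected_concentration is only meaningful for Positive probes")
  }
  if (any(is.na(expected_concentration) & code_class == "Positive")) {
    stop("every Positive probe needs an expected_concentration (fM)")
  }
  cs <- data.frame(
    code_class = code_class,
    name = name,
    accession = as.character(accession),
    expected_concentration = expected_concentration,
    stringsAsFactors = FALSE
  )
  attr(cs, "panel_name") <- panel_name
  class(cs) <- c("rbdge_codeset", "data.frame")
  cs
}

#' @export
print.rbdge_codeset <- function(x, ...) {
  cat("CodeSet '", attr(x, "panel_name"), "': ", nrow(x), " probes (",
      paste(sprintf("%s=%d", names(table(x$code_class)),
                    as.integer(table(x$code_class))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

probe_names <- function(cs, class = NULL) {
  if (is.null(class)) cs$name else cs$name[cs$code_class %in% class]
}

#' Construct a probe-by-sample count matrix
#'
#' The central container of the pipeline: a probes x samples grid of
#' non-negative values together with its CodeSet. Raw instrument counts are
#' integer-valued; normalized matrices reuse the same container with
#' `raw = FALSE`.
#'
#' @param values numeric matrix, probes in rows (rownames = probe names),
#'   samples in columns.
#' @param codeset the matching [codeset()].
#' @param raw logical; if `TRUE` the values are validated as integers.
#' @return An object of class `rbdge_count_matrix`.
#' @export
count_matrix <- function(values, codeset, raw = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("count matrix needs probe names as rownames")
  }
  if (!identical(rownames(values), codeset$name)) {
    if (!setequal(rownames(values), codeset$name)) {
      stop("probe names of the matrix do not match the codeset")
    }
    values <- values[codeset$name, , drop = FALSE]
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("count matrix contains negative entries")
  if (raw && any(values != round(values))) {
    stop("raw counts must be integer-valued")
  }
  structure(list(values = values, codeset = codeset, raw = raw),
            class = "rbdge_count_matrix")
}

#' @export
print.rbdge_count_matrix <- function(x, ...) {
  cat(if (x$raw) "Raw" else "Normalized", "count matrix:",
      nrow(x$values), "probes x", ncol(x$values), "samples\n")
  invisible(x)
}

#' @export
dim.rbdge_count_matrix <- function(x) dim(x$values)

sample_ids <- function(m) colnames(m$values)

# values restricted to one probe class
class_values <- function(m, class) {
  m$values[m$codeset$code_class %in% class, , drop = FALSE]
}
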