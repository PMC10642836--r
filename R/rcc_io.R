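#' Read an nCounter RCC lane file
#'
#' Parses the plain-text RCC export: sections delimited by `<Header>`,
#' `<Sample_Attributes>`, `<Lane_Attributes>` and `<Code_Summary>`; the
#' `Code_Summary` body is CSV with columns `CodeClass,Name,Accession,Count`.
#' Unknown sections are preserved verbatim so that a read/write cycle
#' round-trips the file.
#'
#' @param file path to an RCC file.
#' @return A `rbdge_lane` object: `sample_id`, `lane_attributes` (named
#'   character vector), `counts` (named non-negative integer vector),
#'   `code_class`/`accession` per probe, and the raw extra sections.
#' @export
read_rcc <- function(file) {
  if (!file.exists(file)) stop("RCC file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  # locate <Tag> ... </Tag> blocks
  opens <- grep("^<[A-Za-z_]+>\\s*$", lines)
  sections <- list()
  for (i in opens) {
    tag <- sub("^<([A-Za-z_]+)>\\s*$", "\\1", lines[i])
    close_pat <- paste0("^</", tag, ">\\s*$")
    j <- grep(close_pat, lines)
    j <- j[j > i][1]
    if (is.na(j)) stop("RCC parse error: unclosed section <", tag,
                       "> opened at line ", i)
    sections[[tag]] <- list(body = lines[seq(i + 1, length.out = j - i - 1)],
                            start = i)
  }
  if (is.null(sections$Code_Summary)) {
    stop("RCC parse error: missing <Code_Summary> section in ", file)
  }
  if (is.null(sections$Lane_Attributes)) {
    stop("RCC parse error: missing <Lane_Attributes> section in ", file)
  }

  parse_kv <- function(body) {
    parts <- strsplit(body, ",", fixed = TRUE)
    keys <- vapply(parts, `[`, "", 1)
    vals <- vapply(parts, function(p) {
      if (length(p) >= 2) paste(p[-1], collapse = ",") else ""
    }, "")
    stats::setNames(vals, keys)
  }
  lane_attr <- parse_kv(sections$Lane_Attributes$body)
  sample_attr <- if (!is.null(sections$Sample_Attributes)) {
    parse_kv(sections$Sample_Attributes$body)
  } else character(0)

  cs <- sections$Code_Summary
  body <- cs$body
  if (length(body) < 2 || !grepl("^CodeClass,Name,Accession,Count", body[1])) {
    stop("RCC parse error: Code_Summary header missing at line ", cs$start + 1)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != 4)) {
    stop("RCC parse error: malformed Code_Summary row at line ",
         cs$start + 1 + which(nfield != 4)[1])
  }
  tab <- do.call(rbind, rows)
  counts_chr <- tab[, 4]
  counts <- suppressWarnings(as.numeric(counts_chr))
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
  if (length(bad) > 0) {
    stop("RCC parse error: negative or non-integer count at line ",
         cs$start + 1 + bad[1])
  }
  if (anyDuplicated(tab[, 2])) {
    dup <- which(duplicated(tab[, 2]))[1]
    stop("RCC parse error: duplicate probe name '", tab[dup, 2],
         "' at line ", cs$start + 1 + dup)
  }

  sid <- if (length(sample_attr) && nzchar(sample_attr["ID"])) {
    unname(sample_attr["ID"])
  } else {
    sub("\\.[Rr][Cc][Cc]$", "", basename(file))
  }
  extra <- sections[setdiff(names(sections),
                            c("Sample_Attributes", "Lane_Attributes",
                              "Code_Summary"))]
  structure(list(
    sample_id = sid,
    sample_attributes = sample_attr,
    lane_attributes = lane_attr,
    code_class = stats::setNames(tab[, 1], tab[, 2]),
    accession = stats::setNames(tab[, 3], tab[, 2]),
    counts = stats::setNames(as.integer(counts), tab[, 2]),
    extra_sections = lapply(extra, `[[`, "body")
  ), class = "rbdge_lane")
}

#' Write an nCounter RCC lane file
#'
#' @param lane a `rbdge_lane` (or a list with `sample_id`, `counts`, and
#'   optionally `lane_attributes`).
#' @param codeset the [codeset()] defining probe order and classes.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_rcc <- function(lane, codeset, file) {
  missing <- setdiff(codeset$name, names(lane$counts))
  if (length(missing) > 0) {
    stop("lane '", lane$sample_id, "' lacks counts for probe(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  la <- lane$lane_attributes
  if (is.null(la) || !length(la)) la <- c(ID = "1", FovCount = "555")
  sa <- lane$sample_attributes
  if (is.null(sa) || !length(sa)) sa <- c(ID = lane$sample_id)
  sa["ID"] <- lane$sample_id
  kv <- function(x) paste0(names(x), ",", unname(x))
  out <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,rbdge", "</Header>",
    "<Sample_Attributes>", kv(sa), "</Sample_Attributes>",
    "<Lane_Attributes>", kv(la), "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    paste(codeset$code_class, codeset$name, codeset$accession,
          format(lane$counts[codeset$name], scientific = FALSE, trim = TRUE),
          sep = ","),
    "</Code_Summary>"
  )
  extra <- lane$extra_sections
  if (!is.null(extra) && length(extra)) {
    for (tag in names(extra)) {
      out <- c(out, paste0("<", tag, ">"), extra[[tag]], paste0("</", tag, ">"))
    }
  }
  writeLines(out, file)
  invisible(file)
}

#' Assemble lane records into a count matrix
#'
#' @param lanes list of lanes from [read_rcc()].
#' @param codeset the shared [codeset()].
#' @return A raw [count_matrix()] whose column order follows the lane order.
#' @export
assemble_matrix <- function(lanes, codeset) {
  if (length(lanes) < 1) stop("need at least one lane")
  ids <- vapply(lanes, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample id across lanes: ", ids[duplicated(ids)][1])
  }
  vals <- vapply(lanes, function(ln) {
    missing <- setdiff(codeset$name, names(ln$counts))
    if (length(missing) > 0) {
      stop("lane '", ln$sample_id, "' does not cover the codeset (missing ",
           missing[1], ")")
    }
    extra <- setdiff(names(ln$counts), codeset$name)
    if (length(extra) > 0) {
      stop("lane '", ln$sample_id, "' has probes absent from the codeset (",
           extra[1], ")")
    }
    as.numeric(ln$counts[codeset$name])
  }, numeric(nrow(codeset)))
  vals <- matrix(vals, nrow = nrow(codeset),
                 dimnames = list(codeset$name, ids))
  count_matrix(vals, codeset, raw = TRUE)
}

SUBTYPE_LEVELS <- c("URB", "DRB", "control")
N_STAGE_LEVELS <- c("N0", "N1", "N2")
C_STAGE_LEVELS <- c("C0", "C1", "C2")

#' Read a sample annotation table
#'
#' Expects a CSV with columns `sample_id, subtype, sex, laterality,
#' age_months, n_stage, c_stage, rb1_germline`. Subtype is one of
#' `URB`/`DRB`/`control`; tumor stages are the ordinal scales `N0<N1<N2` and
#' `C0<C1<C2`; `rb1_germline` is `yes`/`no` (empty for controls).
#'
#' @param file CSV path.
#' @return A `data.frame` with validated, typed columns; ordinal stages are
#'   ordered factors.
#' @export
read_annotations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  required <- c("sample_id", "subtype", "sex", "laterality", "age_months",
                "n_stage", "c_stage", "rb1_germline")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in annotations")
  bad <- setdiff(unique(df$subtype), SUBTYPE_LEVELS)
  if (length(bad) > 0) stop("unknown subtype token: ", bad[1])
  df$subtype <- factor(df$subtype, levels = SUBTYPE_LEVELS)
  df$age_months <- as.numeric(df$age_months)
  if (any(!is.na(df$age_months) & df$age_months < 0)) {
    stop("negative age_months in annotations")
  }
  tum <- df$subtype != "control"
  chk_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[tum & !is.na(x) & nzchar(x)]), levels)
    if (length(bad) > 0) stop("unknown ", what, " token: ", bad[1])
  }
  chk_levels(df$n_stage, N_STAGE_LEVELS, "n_stage")
  chk_levels(df$c_stage, C_STAGE_LEVELS, "c_stage")
  chk_levels(df$laterality, c("unilateral", "bilateral"), "laterality")
  chk_levels(tolower(df$rb1_germline), c("yes", "no", "true", "false"),
             "rb1_germline")
  df$n_stage <- factor(df$n_stage, levels = N_STAGE_LEVELS, ordered = TRUE)
  df$c_stage <- factor(df$c_stage, levels = C_STAGE_LEVELS, ordered = TRUE)
  df$rb1_germline <- tolower(df$rb1_germline) %in% c("yes", "true")
  df$rb1_germline[df$subtype == "control"] <- NA
  df
}

#' Read a bare count-matrix CSV
#'
#' Alternative input to RCC files: probes as rows, first column the probe
#' name, second the code class, remaining columns one sample each.
#'
#' @param file CSV path.
#' @param housekeeping optional probe names to re-label as `Housekeeping`
#'   when the file carries no usable code classes.
#' @return A raw [count_matrix()].
#' @export
read_matrix_csv <- function(file, housekeeping = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3) stop("matrix CSV needs name, code class and >=1 sample")
  cls <- df[[2]]
  if (!is.null(housekeeping)) cls[df[[1]] %in% housekeeping] <- "Housekeeping"
  cs <- codeset(cls, df[[1]])
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df[[1]]
  count_matrix(vals, cs, raw = all(vals == round(vals)))
}

#' Write a count matrix as CSV
#' @param m a [count_matrix()].
#' @param file output path.
#' @export
write_matrix_csv <- function(m, file) {
  df <- data.frame(name = m$codeset$name, code_class = m$codeset$code_class,
                   m$values, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
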