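# Flat-file input/output.
#
# The evidence template is a plain table with a label column first, a
# Weight column, then one column per proposition:
#
#   Evidence,Weight,Cold,Common pneumonia,COVID-19
#   Expert 1,10,90%,0,0
#   Expert 2,8,0,90%,0
#   Expert 3,5,0,0,90%
#
# Belief cells may be decimals (0.9) or percent strings ("90%"); blank
# cells are read as 0. A reference template ships in
# inst/extdata/template.csv and is the normative definition of the format.
# CSV files are RFC-4180-style UTF-8 (LF or CRLF); XLSX files are read
# from the first worksheet and must contain the same layout.

# Read a raw character table from CSV or XLSX.
read_raw_table <- function(path) {
  if (!file.exists(path))
    er_abort("io", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- tryCatch(
      utils::read.csv(path, check.names = FALSE, colClasses = "character",
                      fileEncoding = "UTF-8", strip.white = TRUE),
      error = function(e) er_abort("io", sprintf("cannot parse %s: %s",
                                                 path, conditionMessage(e))))
  } else if (ext %in% c("xlsx", "xls")) {
    df <- tryCatch(
      as.data.frame(readxl::read_excel(path, sheet = 1, col_types = "text"),
                    check.names = FALSE),
      error = function(e) er_abort("io", sprintf("cannot parse %s: %s",
                                                 path, conditionMessage(e))))
    df[] <- lapply(df, function(x) ifelse(is.na(x), "", x))
  } else {
    er_abort("io", sprintf("unsupported file extension '%s' (need csv/xlsx)",
                           ext))
  }
  if (nrow(df) == 0L)
    er_abort("validation", sprintf("empty table: %s", path))
  df
}

# Parse one belief/weight cell: decimal, percent string, or blank (= 0).
# Comma-decimal locales are rejected, not silently misparsed.
parse_cell <- function(cell, path, row, col) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(0)
  pct <- grepl("%$", cell)
  if (pct) cell <- sub("%$", "", cell)
  val <- suppressWarnings(as.numeric(cell))
  if (is.na(val))
    er_abort("validation",
             sprintf(paste0("non-numeric cell '%s' at row %d, column '%s'",
                            " in %s (use '.' as the decimal separator)"),
                     cell, row, col, path))
  if (pct) val / 100 else val
}

# Shared core: character data.frame -> labels, raw weights, belief matrix.
parse_belief_table <- function(df, path) {
  cols <- names(df)
  wcol <- which(tolower(cols) == "weight")
  if (length(wcol) != 1L)
    er_abort("validation",
             sprintf("expected exactly one 'Weight' column in %s", path))
  props <- cols[-c(1L, wcol)]
  if (length(props) < 1L)
    er_abort("validation", sprintf("no proposition columns in %s", path))
  if (anyDuplicated(props))
    er_abort("validation",
             sprintf("duplicate proposition headers in %s: %s", path,
                     paste(unique(props[duplicated(props)]),
                           collapse = ", ")))
  labels <- trimws(df[[1L]])
  weights <- vapply(seq_len(nrow(df)), function(i)
    parse_cell(df[[wcol]][i], path, i, "Weight"), 0)
  mat <- matrix(0, nrow(df), length(props),
                dimnames = list(labels, props))
  for (j in seq_along(props))
    mat[, j] <- vapply(seq_len(nrow(df)), function(i)
      parse_cell(df[[props[j]]][i], path, i, props[j]), 0)
  list(labels = labels, weights = weights, beliefs = mat, props = props)
}

#' Read a flat evidence table from CSV or XLSX
#'
#' Reads a degrees-of-belief table following the package template (see
#' `system.file("extdata", "template.csv", package = "erfusion")`): a
#' label column, a `Weight` column, then one column per proposition.
#' Belief cells are accepted as decimals (`0.9`) or percent strings
#' (`"90%"`); blank cells count as 0.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param tol Belief-sum tolerance passed to [evidence_body()].
#' @return An object of class `evidence_table`: a list with `frame`,
#'   `evidence` (list of [evidence_body]), `weights` (raw, un-normalized),
#'   `labels` and `source`.
#' @export
read_evidence_table <- function(path, tol = 1e-3) {
  parsed <- parse_belief_table(read_raw_table(path), path)
  frame <- er_frame(parsed$props)
  bodies <- lapply(seq_along(parsed$labels), function(i)
    evidence_body(parsed$beliefs[i, ], frame, label = parsed$labels[i],
                  tol = tol))
  structure(list(frame = frame, evidence = bodies,
                 weights = parsed$weights, labels = parsed$labels,
                 source = path),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("<evidence_table: %d bodies x %d propositions (%s)>\n",
              length(x$evidence), x$frame$N, x$source))
  df <- do.call(rbind, lapply(x$evidence, function(e) e$beliefs))
  rownames(df) <- x$labels
  print(cbind(Weight = x$weights, df))
  invisible(x)
}

# Canonical algorithm tags and their aliases (case-insensitive).
.algorithms <- c(er = "ER", demp = "Dempster", dempster = "Dempster",
                 yager = "Yager", murphy = "Murphy")

match_algorithm <- function(algorithm) {
  key <- tolower(trimws(algorithm))
  if (!key %in% names(.algorithms))
    er_abort("dispatch",
             sprintf("unknown algorithm '%s'; valid tags: %s", algorithm,
                     paste(unique(.algorithms), collapse = ", ")))
  unname(.algorithms[key])
}

#' Fuse an evidence file with a chosen combination rule
#'
#' Reads a flat evidence table and dispatches to the requested rule:
#' `"ER"` (the default, weight-aware), or the weight-free `"Demp"`
#' (alias `"Dempster"`), `"Yager"` and `"Murphy"`, in which case the
#' file's weight column is discarded with a warning.
#'
#' @param path Path to a `.csv` or `.xlsx` evidence table.
#' @param algorithm Algorithm tag, case-insensitive.
#' @param plot Optional path of a PNG/SVG bar chart to render via
#'   [render_result_chart()].
#' @param tol Belief-sum tolerance.
#' @return A [fusion_result].
#' @examples
#' f <- system.file("extdata", "diagnosis.csv", package = "erfusion")
#' run_from_file(f)
#' @export
run_from_file <- function(path, algorithm = "ER", plot = NULL, tol = 1e-3) {
  algorithm <- match_algorithm(algorithm)
  tab <- read_evidence_table(path, tol = tol)
  result <- switch(algorithm,
    ER = er_fuse(tab$evidence, tab$weights, tab$frame, tol = tol),
    Dempster = dempster_fuse(tab$evidence, tab$frame, weights = tab$weights,
                             tol = tol),
    Yager = yager_fuse(tab$evidence, tab$frame, weights = tab$weights,
                       tol = tol),
    Murphy = murphy_fuse(tab$evidence, tab$frame, weights = tab$weights,
                         tol = tol))
  if (!is.null(plot)) render_result_chart(result, out = plot)
  result
}

#' Write fused results to CSV
#'
#' Writes one row per fused result with proposition columns plus an
#' `Uncertainty` column. Values are written at full double precision by
#' default so that a write/read round trip is lossless; pass `digits = 4`
#' for the conventional 4-decimal presentation.
#'
#' @param result A [fusion_result], or a named list of them (one output
#'   row each, names in an `Object` column).
#' @param path Output CSV path.
#' @param digits Optional presentation rounding (half-even), e.g. `4`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, digits = NULL) {
  if (inherits(result, "fusion_result")) {
    rows <- list(result)
    labels <- NULL
  } else if (is.list(result) &&
             all(vapply(result, inherits, TRUE, "fusion_result"))) {
    rows <- result
    labels <- names(result)
  } else {
    er_abort("validation",
             "write_result expects a fusion_result or a list of them")
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (!is.null(digits)) df <- round(df, digits)
  if (!is.null(labels)) df <- cbind(Object = labels, df)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    er_abort("io", sprintf("cannot write %s: %s", path,
                           conditionMessage(ok)))
  invisible(path)
}
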