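# Tabular data model: replicate measurement tables and paired per-patient
# comparison tables, with strict validation so malformed instrument exports
# fail loudly instead of propagating.

#' Allowed sample matrices
#'
#' Replicate measurements must come from one of these matrices: assay buffer,
#' human urine, or distilled water (blanks).
#'
#' @export
XYL_MATRICES <- c("buffer", "urine", "water")

.replicate_columns <- c(
  "analyzer", "matrix", "level_id", "nominal_conc",
  "run_id", "replicate_index", "value", "raw_response"
)

# Delimiter sniffing restricted to comma / tab / semicolon.
.sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) {
    stop("no data rows: file '", path, "' is empty", call. = FALSE)
  }
  counts <- c(
    "," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
    "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
    ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))
  )
  if (all(counts == 0L)) {
    stop("could not detect a comma/tab/semicolon delimiter in '", path, "'",
         call. = FALSE)
  }
  names(counts)[which.max(counts)]
}

# Decimal commas ("1,5") are a common European export artefact; they corrupt
# silently if coerced, so they are rejected with the offending rows named.
.check_decimal_commas <- function(x, column) {
  bad <- grepl("^\\s*-?[0-9]+,[0-9]+\\s*$", x)
  if (any(bad)) {
    stop("column '", column, "' uses ',' as decimal separator (rows ",
         paste(which(bad), collapse = ", "),
         "); re-export with '.' decimals", call. = FALSE)
  }
}

.as_numeric_col <- function(x, column) {
  x <- trimws(x)
  .check_decimal_commas(x, column)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("column '", column, "' is not numeric (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  out
}

.read_delimited <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (is.null(delimiter)) delimiter <- .sniff_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE, fill = FALSE,
                          strip.white = TRUE, comment.char = "")
  if (nrow(df) == 0L) stop("no data rows in '", path, "'", call. = FALSE)
  df
}

#' Validate a replicate measurement table
#'
#' Checks the invariants of the long-format replicate table: known matrix,
#' exactly one of `value` / `raw_response` per row, non-negative measured
#' concentrations, and replicate indices unique within each
#' (analyzer, level_id, run_id) cell. Diagnostics name the offending rows.
#'
#' @param tbl a data frame with the replicate-table columns.
#' @return the validated table as a [tibble::tibble()] (invisibly identical
#'   content, standardized column order).
#' @export
validate_replicates <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0L) stop("replicate table is empty", call. = FALSE)
  mandatory <- c("analyzer", "matrix", "level_id", "run_id", "replicate_index")
  missing_cols <- setdiff(mandatory, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!any(c("value", "raw_response") %in% names(tbl))) {
    stop("missing mandatory column(s): one of value/raw_response",
         call. = FALSE)
  }
  for (col in setdiff(.replicate_columns, names(tbl))) tbl[[col]] <- NA_real_

  bad_matrix <- !(tbl$matrix %in% XYL_MATRICES)
  if (any(bad_matrix)) {
    stop("unknown matrix (rows ", paste(which(bad_matrix), collapse = ", "),
         "); allowed: ", paste(XYL_MATRICES, collapse = ", "), call. = FALSE)
  }

  has_value <- !is.na(tbl$value)
  has_raw <- !is.na(tbl$raw_response)
  both <- has_value & has_raw
  neither <- !has_value & !has_raw
  if (any(both)) {
    stop("rows with both value and raw_response present: ",
         paste(which(both), collapse = ", "), call. = FALSE)
  }
  if (any(neither)) {
    stop("rows with neither value nor raw_response: ",
         paste(which(neither), collapse = ", "), call. = FALSE)
  }

  neg <- has_value & tbl$value < 0
  if (any(neg)) {
    stop("negative measured value (rows ",
         paste(which(neg), collapse = ", "), ")", call. = FALSE)
  }

  ri <- tbl$replicate_index
  if (any(is.na(ri)) || any(ri <= 0) || any(ri != round(ri))) {
    stop("replicate_index must be a positive integer for every row",
         call. = FALSE)
  }
  key <- paste(tbl$analyzer, tbl$level_id, tbl$run_id, ri, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate replicate_index within (analyzer, level_id, run_id): rows ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  tbl[, .replicate_columns]
}

#' Read a replicate measurement table
#'
#' Reads a delimited (comma, tab, or semicolon) UTF-8 file of replicate
#' measurements in mg/dL and validates it with [validate_replicates()].
#' Column names may be remapped with `col_map`
#' (e.g. `c(instrument = "analyzer")` renames `instrument` on input).
#'
#' @param path path to the file.
#' @param delimiter single delimiter character, or `NULL` to auto-detect
#'   among comma, tab and semicolon.
#' @param col_map optional named character vector `c(file_name = field_name)`
#'   mapping file headers to replicate-table fields.
#' @return a validated replicate table (tibble).
#' @export
read_replicates <- function(path, delimiter = NULL, col_map = NULL) {
  df <- .read_delimited(path, delimiter)
  if (!is.null(col_map)) {
    hit <- match(names(df), names(col_map))
    names(df)[!is.na(hit)] <- unname(col_map[hit[!is.na(hit)]])
  }
  for (col in c("nominal_conc", "replicate_index", "value", "raw_response")) {
    if (col %in% names(df)) df[[col]] <- .as_numeric_col(df[[col]], col)
  }
  validate_replicates(df)
}

#' Validate a paired method-comparison table
#'
#' One row per patient: total urinary xylose (mg) by the reference
#' phloroglucinol method (`method_a_total`) and by the enzymatic method
#' (`method_b_total`). Patient ids must be unique; totals non-negative.
#' Optional `reference_label` / `adjudicated_label` columns carry the
#' hypolactasic/normolactasic classification; an adjudicated label, when
#' present, overrides the reference label downstream.
#'
#' @param tbl a data frame of paired totals.
#' @return the validated tibble.
#' @export
validate_comparison <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0L) stop("no data rows", call. = FALSE)
  mandatory <- c("patient_id", "method_a_total", "method_b_total")
  missing_cols <- setdiff(mandatory, names(tbl))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(tbl$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id: ",
         paste(unique(tbl$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (col in c("method_a_total", "method_b_total")) {
    if (!is.numeric(tbl[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (any(is.na(tbl[[col]]))) {
      stop("column '", col, "' has missing totals (rows ",
           paste(which(is.na(tbl[[col]])), collapse = ", "), ")",
           call. = FALSE)
    }
    if (any(tbl[[col]] < 0)) {
      stop("negative totals in '", col, "' (rows ",
           paste(which(tbl[[col]] < 0), collapse = ", "), ")", call. = FALSE)
    }
  }
  labels <- c("hypolactasic", "normolactasic")
  for (col in c("reference_label", "adjudicated_label")) {
    if (col %in% names(tbl)) {
      bad <- !is.na(tbl[[col]]) & !(tbl[[col]] %in% labels)
      if (any(bad)) {
        stop("column '", col, "' has labels outside {",
             paste(labels, collapse = ", "), "} (rows ",
             paste(which(bad), collapse = ", "), ")", call. = FALSE)
      }
    } else {
      tbl[[col]] <- NA_character_
    }
  }
  tbl$patient_id <- as.character(tbl$patient_id)
  tbl[, c("patient_id", "method_a_total", "method_b_total",
          "reference_label", "adjudicated_label")]
}

#' Read a paired method-comparison table
#'
#' @inheritParams read_replicates
#' @return a validated paired-comparison tibble; see [validate_comparison()].
#' @export
read_comparison <- function(path, delimiter = NULL) {
  df <- .read_delimited(path, delimiter)
  for (col in c("method_a_total", "method_b_total")) {
    if (col %in% names(df)) df[[col]] <- .as_numeric_col(df[[col]], col)
  }
  for (col in c("reference_label", "adjudicated_label")) {
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA_character_
  }
  validate_comparison(df)
}

# Numeric columns are serialized at 17 significant digits so a write/read
# round trip is bit-exact for doubles.
.write_table <- function(tbl, path) {
  out <- as.data.frame(tbl)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      x <- sprintf("%.17g", out[[col]])
      x[is.na(out[[col]])] <- ""
      out[[col]] <- x
      attr(out[[col]], "xyl_numeric") <- TRUE
    }
  }
  quote_cols <- which(!vapply(out, function(x)
    isTRUE(attr(x, "xyl_numeric")), logical(1)))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double",
                     quote = quote_cols, na = "")
  invisible(path)
}

#' Write a replicate table to CSV
#'
#' RFC-4180-style quoting; numeric fields at full double precision so a
#' read-back reproduces the table exactly.
#'
#' @param tbl a validated replicate table.
#' @param path output path.
#' @export
write_replicates <- function(tbl, path) {
  .write_table(validate_replicates(tbl), path)
}

#' Write a paired-comparison table to CSV
#'
#' @param tbl a validated paired-comparison table.
#' @param path output path.
#' @export
write_comparison <- function(tbl, path) {
  .write_table(validate_comparison(tbl), path)
}

#' Total excreted xylose from concentration and urine volume
#'
#' Convenience only: patient totals are normally taken as given. Converts a
#' measured concentration (mg/dL) and a collected urine volume (dL) into a
#' total amount (mg).
#'
#' @param conc_mg_dl concentration in mg/dL.
#' @param volume_dl urine volume in dL.
#' @return total xylose in mg.
#' @export
total_from_concentration <- function(conc_mg_dl, volume_dl) {
  stopifnot(all(volume_dl >= 0))
  conc_mg_dl * volume_dl
}
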