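#' Cohort CSV column schema
#'
#' Column names of the patient-level cohort table, in canonical order.
#' Units are fixed by the schema and never auto-converted: percentages are
#' percent of white cells, lymphocyte counts are x10^2/uL, platelet counts
#' are x10^4/uL, and all times are days.  Missing values are empty cells.
#' The six tumor-infiltrating-lymphocyte (TIL) columns are optional as a
#' block; every other column must be present in the header.
#'
#' @param include_tils logical; append the six TIL/sTIL columns.
#' @return Character vector of column names.
#' @export
cohort_columns <- function(include_tils = TRUE) {
  core <- c(
    "patient_id", "age", "bmi", "parity", "figo_stage", "subtype",
    "surgical_outcome", "days_first_treatment_to_ids",
    "pre_neutrophil_pct", "pre_lymphocyte_pct", "pre_lymphocyte_count",
    "pre_platelet_count",
    "post_neutrophil_pct", "post_lymphocyte_pct", "post_lymphocyte_count",
    "post_platelet_count",
    "death", "os_days", "recurrence", "pfs_days"
  )
  if (include_tils) c(core, til_columns()) else core
}

til_columns <- function() {
  c("cd3_tils", "cd3_stils", "cd8_tils", "cd8_stils",
    "cd56_tils", "cd56_stils")
}

marker_columns <- function() {
  c("pre_neutrophil_pct", "pre_lymphocyte_pct", "pre_lymphocyte_count",
    "pre_platelet_count",
    "post_neutrophil_pct", "post_lymphocyte_pct", "post_lymphocyte_count",
    "post_platelet_count")
}

numeric_cohort_columns <- function() {
  c("age", "bmi", "parity", "figo_stage", "days_first_treatment_to_ids",
    marker_columns(), "os_days", "pfs_days", til_columns())
}

subtype_levels <- function() {
  c("serous", "endometrioid", "clear_cell", "mucinous", "mixed", "other")
}

#' Construct a cohort object
#'
#' A cohort is a validated data frame following [cohort_columns()], one row
#' per patient, with a provenance tag.  Validation enforces the schema
#' invariants: unique patient ids, FIGO stage in \{2, 3, 4\}, percentages in
#' \[0, 100\] with neutrophil + lymphocyte <= 100 at each timepoint, counts
#' and times non-negative, and `os_days >= pfs_days` where both are present.
#'
#' @param data data frame with the cohort schema columns.
#' @param provenance free-text source tag stored as an attribute.
#' @return An object of class `ppsn_cohort` (a data frame).
#' @export
as_cohort <- function(data, provenance = "unspecified") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(cohort_columns(include_tils = FALSE), names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in intersect(numeric_cohort_columns(), names(data))) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data$death <- as_flag(data$death, "death")
  data$recurrence <- as_flag(data$recurrence, "recurrence")
  validate_cohort(data)
  structure(data, class = c("ppsn_cohort", "data.frame"),
            provenance = provenance)
}

# Coerce 0/1/TRUE/FALSE (possibly as text) to logical; anything else errors.
as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  x_chr <- trimws(as.character(x))
  x_chr[x_chr == ""] <- NA_character_
  out <- rep(NA, length(x_chr))
  out[x_chr %in% c("1", "TRUE", "true")] <- TRUE
  out[x_chr %in% c("0", "FALSE", "false")] <- FALSE
  bad <- !is.na(x_chr) & is.na(out)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s) at row(s) %s: must be 0/1 or TRUE/FALSE",
                 what, paste(which(bad), collapse = ", ")))
  }
  out
}

validate_cohort <- function(data) {
  if (nrow(data) == 0L) stop("cohort is empty")
  id <- as.character(data$patient_id)
  if (anyNA(id) || any(id == "")) stop("patient_id must be non-missing")
  if (anyDuplicated(id)) {
    stop("duplicated patient_id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  fs <- data$figo_stage
  if (any(!is.na(fs) & !fs %in% c(2, 3, 4))) {
    stop("figo_stage must be 2, 3 or 4")
  }
  for (tp in c("pre", "post")) {
    np <- data[[paste0(tp, "_neutrophil_pct")]]
    lp <- data[[paste0(tp, "_lymphocyte_pct")]]
    check_range(np, 0, 100, paste0(tp, "_neutrophil_pct"))
    check_range(lp, 0, 100, paste0(tp, "_lymphocyte_pct"))
    both <- !is.na(np) & !is.na(lp)
    if (any(both & np + lp > 100 + 1e-9)) {
      stop(tp, ": neutrophil_pct + lymphocyte_pct exceeds 100")
    }
    check_range(data[[paste0(tp, "_lymphocyte_count")]], 0, Inf,
                paste0(tp, "_lymphocyte_count"))
    check_range(data[[paste0(tp, "_platelet_count")]], 0, Inf,
                paste0(tp, "_platelet_count"))
  }
  check_range(data$os_days, 0, Inf, "os_days", open_lower = TRUE)
  check_range(data$pfs_days, 0, Inf, "pfs_days", open_lower = TRUE)
  both <- !is.na(data$os_days) & !is.na(data$pfs_days)
  if (any(both & data$os_days < data$pfs_days - 1e-9)) {
    stop("os_days must be >= pfs_days where both are present")
  }
  if (any(!is.na(data$parity) & data$parity < 0)) stop("parity must be >= 0")
  for (col in intersect(til_columns(), names(data))) {
    check_range(data[[col]], 0, Inf, col)
  }
  invisible(data)
}

check_range <- function(x, lo, hi, what, open_lower = FALSE) {
  if (is.null(x)) return(invisible(NULL))
  ok <- is.na(x) | (if (open_lower) x > lo else x >= lo) & x <= hi
  if (!all(ok)) {
    stop(sprintf("%s out of range at row(s) %s", what,
                 paste(which(!ok), collapse = ", ")))
  }
  invisible(NULL)
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8 cohort table whose header matches
#' [cohort_columns()] (TIL columns optional).  Empty cells become missing
#' values, never zeros.  In strict mode a non-numeric entry in a numeric
#' column is an error naming the offending row; otherwise it is coerced to
#' missing with a warning.
#'
#' @param path path to a CSV file.
#' @param strict logical; fail on unparseable numeric cells.
#' @return A `ppsn_cohort`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(include_tils = FALSE), names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: header lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in intersect(numeric_cohort_columns(), names(raw))) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(num)
    if (any(bad)) {
      msg <- sprintf("non-numeric value in column '%s' at row(s) %s",
                     col, paste(which(bad), collapse = ", "))
      if (strict) stop("parse error: ", msg) else warning(msg)
    }
    raw[[col]] <- num
  }
  as_cohort(raw, provenance = path)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells and the
#' output round-trips every field value exactly (numbers at full precision
#' via decimal serialization with 17 significant digits).
#'
#' @param cohort a `ppsn_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ppsn_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           formatC(out[[col]], digits = 17, format = "g"))
    } else if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           ifelse(out[[col]], "1", "0"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Complete-case subset of a cohort
#'
#' Keeps only records with every required field present, preserving order.
#' Shorthands expand to field groups: `"pre"` (the three pre-treatment
#' scoring markers), `"post"` (the four post-NACT scoring markers),
#' `"tils"` (the six TIL columns), `"pfs"` (`recurrence` + `pfs_days`).
#' The operation is idempotent and monotone: requiring more fields never
#' grows the subset.
#'
#' @param cohort a `ppsn_cohort`.
#' @param required_fields character vector of column names or shorthands.
#' @return The subset `ppsn_cohort` (possibly with zero rows, with a
#'   warning).
#' @export
complete_case_subset <- function(cohort, required_fields) {
  stopifnot(inherits(cohort, "ppsn_cohort"))
  fields <- expand_field_shorthand(required_fields)
  unknown <- setdiff(fields, names(cohort))
  if (length(unknown) > 0L) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(cohort))
  for (f in fields) keep <- keep & !is.na(cohort[[f]])
  if (!any(keep)) {
    warning("complete_case_subset: no records have all required fields")
  }
  out <- cohort[keep, , drop = FALSE]
  structure(out, class = class(cohort),
            provenance = attr(cohort, "provenance"))
}

expand_field_shorthand <- function(fields) {
  out <- character(0)
  for (f in fields) {
    out <- c(out, switch(f,
      pre  = c("pre_neutrophil_pct", "pre_lymphocyte_pct",
               "pre_lymphocyte_count"),
      post = c("post_neutrophil_pct", "post_lymphocyte_pct",
               "post_lymphocyte_count", "post_platelet_count"),
      tils = til_columns(),
      pfs  = c("recurrence", "pfs_days"),
      f))
  }
  unique(out)
}

#' @export
print.ppsn_cohort <- function(x, ...) {
  cat(sprintf("PPSN cohort: %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  cat(sprintf("  deaths: %d/%d\n", sum(x$death, na.rm = TRUE), nrow(x)))
  invisible(x)
}

#' Serialize analysis results
#'
#' Writes pipeline outputs to disk deterministically.  JSON keeps full
#' numeric precision (`digits = NA`); TSV expects a data frame and writes
#' full-precision numbers (display-rounded twins are the caller's concern,
#' see [truncate2()]).  Writing the same object twice yields byte-identical
#' files.
#'
#' @param results a list (for JSON) or data frame (for TSV).
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write report: no such directory: ", dirname(path))
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null",
                         force = TRUE)
  } else {
    if (!is.data.frame(results)) {
      results <- as.data.frame(results, stringsAsFactors = FALSE)
    }
    out <- results
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), "",
                             formatC(out[[col]], digits = 17, format = "g"))
      }
    }
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
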