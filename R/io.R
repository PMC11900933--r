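# Cohort CSV/TSV reading and writing.

# Columns with fixed units in the canonical cohort schema.
.numeric_cols <- c(
  "age_years", "bmi_kgm2", "wc_cm", "sbp_mmhg", "dbp_mmhg", "hr_bpm",
  "glucose_mgdl", "glucose_mmol", "insulin_uiu_ml", "tc_mgdl", "hdl_mgdl",
  "ldl_mgdl", "tg_mgdl", "hscrp_mgdl", "hba1c_pct", "igf1_ngml",
  "rhgh_duration_years", "ffm_kg", "ffm_pct", "fm_kg", "fm_pct"
)
.binary_cols <- c("htn_treated", "smoker", "diabetes", "rhgh_treated")

#' Read a cohort table from CSV or TSV
#'
#' Delimiter (comma or tab) is sniffed from the header line. Known schema
#' columns are typed and validated (numeric columns must parse; binary flags
#' must be 0/1; `sex` must be F/M; `sample_id` must be unique); unknown
#' columns are passed through with guessed types. Methylation columns given
#' under recognised aliases are renamed to the canonical site names. Errors
#' report 1-based file line numbers (header = line 1).
#'
#' @param path Path to a delimited text file with a header row.
#' @param strict_percent Passed through to downstream methylation checks via
#'   attribute only; reading itself does not rescale values.
#' @return A tibble, one row per subject.
#' @export
read_cohort <- function(path, strict_percent = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) abort("Empty file or missing header.")
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), trim_ws = TRUE, show_col_types = FALSE
  )
  if (!nrow(raw)) abort("No data rows found.")

  # canonicalise methylation column names
  canon <- resolve_site_names(names(raw))
  dup <- canon[duplicated(unname(canon))]
  if (length(dup)) abort("Multiple columns resolve to the same methylation site.")
  names(raw)[match(names(canon), names(raw))] <- unname(canon)

  line_of <- function(i) i + 1L  # header occupies line 1

  if (!"sample_id" %in% names(raw)) abort("Missing required column `sample_id`.")
  if (anyNA(raw$sample_id)) {
    abort(paste0("Empty sample_id at line ",
                 line_of(which(is.na(raw$sample_id))[1]), "."))
  }
  if (anyDuplicated(raw$sample_id)) {
    i <- which(duplicated(raw$sample_id))[1]
    abort(paste0("Duplicate sample_id `", raw$sample_id[i],
                 "` at line ", line_of(i), "."))
  }

  out <- raw
  to_number <- function(col) {
    v <- out[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad)) {
      abort(paste0("Cannot parse `", v[bad[1]], "` in column `", col,
                   "` as a number (line ", line_of(bad[1]), ")."))
    }
    parsed
  }
  for (col in intersect(c(clock_sites(), .numeric_cols), names(out))) {
    out[[col]] <- to_number(col)
  }
  for (col in intersect(.binary_cols, names(out))) {
    v <- to_number(col)
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad)) {
      abort(paste0("Column `", col, "` must be 0/1 (line ", line_of(bad[1]), ")."))
    }
    out[[col]] <- as.integer(v)
  }
  if ("sex" %in% names(out)) {
    s <- toupper(substr(out$sex, 1, 1))
    bad <- which(!is.na(out$sex) & !s %in% c("F", "M"))
    if (length(bad)) {
      abort(paste0("Unknown sex code `", out$sex[bad[1]], "` at line ",
                   line_of(bad[1]), " (expected F or M)."))
    }
    out$sex <- ifelse(is.na(out$sex), NA_character_, s)
  }
  # guess types of remaining pass-through columns
  known <- c("sample_id", "group", "sex", clock_sites(), .numeric_cols, .binary_cols)
  for (col in setdiff(names(out), known)) {
    out[[col]] <- utils::type.convert(out[[col]], as.is = TRUE)
  }
  attr(out, "strict_percent") <- strict_percent
  out
}

#' Write a cohort (or any result) table to CSV or TSV
#'
#' Format follows the file extension: `.tsv`/`.txt` write tab-separated,
#' anything else comma-separated.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  stopifnot(is.data.frame(data))
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(data)
}
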