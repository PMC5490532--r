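# Cohort CSV reader/writer. Comma-delimited, UTF-8, dot decimal, mandatory
# header; sex stored as literal "F"/"M". The latent-truth sidecar shares the
# file stem with a .truth extension and the same delimiter.

.cohort_columns <- c("patient_id", "sex", "age_y", "height_cm", "weight_kg",
                     "bcm_kg", "fat_kg", "ecw_kg", "resistance_ohm",
                     "reactance_ohm", "scr_mg_dl", "ucr_conc_mg_dl",
                     "uvol_24h_ml", "gfr_ml_min_173")
.mandatory_columns <- c("patient_id", "sex", "age_y", "height_cm",
                        "weight_kg", "scr_mg_dl")

#' Cohort schema column names
#' @return character vector of the versioned cohort CSV header.
#' @export
cohort_schema <- function() .cohort_columns

#' Read a cohort CSV
#'
#' Validates the header (the mandatory columns `patient_id, sex, age_y,
#' height_cm, weight_kg, scr_mg_dl` must be present; optional columns may be
#' absent or hold empty cells) and every row. Rows failing validation
#' (non-positive serum creatinine or weight, implausible height outside
#' `height_window`, age <= 0, negative urine volume, non-positive BCM or
#' electrical values where present, sex not F/M) are dropped with a warning
#' naming the row numbers; valid rows are returned.
#'
#' @param path CSV file path.
#' @param height_window plausible height range in cm (default 100-230).
#' @return data frame in the cohort schema (missing optional columns filled
#'   with NA).
#' @export
read_cohort <- function(path, height_window = c(100, 230)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("cannot parse cohort file: ",
                             conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(.mandatory_columns, names(x))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(x) == 0) stop("cohort file contains no data rows", call. = FALSE)
  for (col in setdiff(.cohort_columns, names(x))) x[[col]] <- NA_real_
  x <- x[.cohort_columns]

  num_cols <- setdiff(.cohort_columns, c("patient_id", "sex"))
  for (col in num_cols) x[[col]] <- suppressWarnings(as.numeric(x[[col]]))

  bad_if <- function(v, test) !is.na(v) & test(v)
  present_bad <- function(v) bad_if(v, function(z) z <= 0)
  bad <- !(x$sex %in% c("F", "M")) |
    is.na(x$age_y) | x$age_y <= 0 |
    is.na(x$height_cm) | x$height_cm < height_window[1] |
    x$height_cm > height_window[2] |
    is.na(x$weight_kg) | x$weight_kg <= 0 |
    is.na(x$scr_mg_dl) | x$scr_mg_dl <= 0 |
    present_bad(x$bcm_kg) | present_bad(x$resistance_ohm) |
    present_bad(x$reactance_ohm) |
    bad_if(x$uvol_24h_ml, function(z) z < 0) |
    bad_if(x$ucr_conc_mg_dl, function(z) z < 0)
  if (any(bad)) {
    warning("dropped ", sum(bad), " invalid row(s): ",
            paste(which(bad), collapse = ", "), call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no valid rows after validation", call. = FALSE)
  rownames(x) <- NULL
  x
}

#' Write a cohort CSV (and its latent-truth sidecar)
#'
#' Writes the cohort schema columns as comma-delimited UTF-8. When the cohort
#' carries a `"truth"` attribute (as produced by [generate_cohort()]) and
#' `truth = TRUE`, the latent values go to a sidecar file with the same stem
#' and a `.truth` extension, same delimiter.
#'
#' @param cohort cohort data frame.
#' @param path output CSV path.
#' @param truth also write the sidecar when latent values are attached.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth = TRUE) {
  write.csv(cohort[intersect(.cohort_columns, names(cohort))], path,
            row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  tr <- attr(cohort, "truth")
  if (truth && !is.null(tr)) {
    tpath <- paste0(sub("\\.csv$", "", path), ".truth")
    write.csv(tr, tpath, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a latent-truth sidecar
#' @param path path to the `.truth` file (or the cohort CSV whose stem it
#'   shares).
#' @return data frame of latent values.
#' @export
read_truth <- function(path) {
  if (grepl("\\.csv$", path)) path <- paste0(sub("\\.csv$", "", path), ".truth")
  if (!file.exists(path)) stop("truth sidecar not found: ", path,
                               call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
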