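## Assay table schema shared by the generator, the fitting workflow and file
## I/O. Concentrations are uM, rates nmol/min/mg; no unit inference anywhere.

DATASET_COLS <- c("acceptor_uM", "donor_uM", "effector_name", "effector_uM",
                  "replicate", "rate_nmol_min_mg")

#' Construct and validate a kinetic dataset
#'
#' One row per steady-state rate observation. Required columns:
#' `acceptor_uM`, `donor_uM`, `effector_name` (may be empty strings),
#' `effector_uM`, `replicate` (integer >= 1), `rate_nmol_min_mg`.
#'
#' @param df a data.frame with the schema columns.
#' @return the validated data.frame with class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(df) {
  stop_if(!is.data.frame(df), "df must be a data.frame")
  missing_cols <- setdiff(DATASET_COLS, names(df))
  stop_if(length(missing_cols) > 0, "missing column(s): ",
          paste(missing_cols, collapse = ", "))
  df <- df[, DATASET_COLS]
  df$effector_name <- as.character(df$effector_name)
  df$effector_name[is.na(df$effector_name)] <- ""
  for (col in c("acceptor_uM", "donor_uM", "effector_uM",
                "rate_nmol_min_mg")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0)
    stop_if(length(bad) > 0, "column ", col,
            ": negative or malformed value(s) in row(s) ",
            paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.finite(df$replicate) | df$replicate < 1 |
                 df$replicate != round(df$replicate))
  stop_if(length(bad) > 0, "column replicate: invalid value(s) in row(s) ",
          paste(head(bad, 5), collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("kinetic_dataset", "data.frame")
  df
}

#' Read an assay CSV file
#'
#' Reads the UTF-8, decimal-point CSV schema (see [kinetic_dataset()]) with
#' row-addressed validation errors.
#'
#' @param path path to a CSV file.
#' @return a `kinetic_dataset`.
#' @export
read_dataset <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = NA)
  for (col in intersect(c("acceptor_uM", "donor_uM", "effector_uM",
                          "rate_nmol_min_mg"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    stop_if(length(bad) > 0, "column ", col, ": malformed number(s) in ",
            "row(s) ", paste(head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  kinetic_dataset(df)
}

#' Write an assay dataset as CSV
#'
#' Numeric fields are written with 17 significant digits, so write-then-read
#' round trips reproduce the doubles exactly.
#'
#' @param dataset a `kinetic_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  out <- as.data.frame(dataset)
  for (col in c("acceptor_uM", "donor_uM", "effector_uM",
                "rate_nmol_min_mg")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

## evaluate code under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}
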