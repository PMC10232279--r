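#' Paired ECG-parameter / echocardiography dataset
#'
#' Container pairing one row of automatic ECG measurements with the
#' echocardiographic left ventricular ejection fraction (LVEF) measured
#' within a few weeks of the ECG.  The label of interest is *reduced* LVEF,
#' defined as LVEF < 40%.
#'
#' @param params numeric matrix (n x p), columns named by schema parameter
#'   names.
#' @param lvef numeric vector of LVEF percentages in \[0, 100\].
#' @param record_id,patient_id character vectors; several records may share a
#'   patient.
#' @param paced logical; whether the ECG shows a paced rhythm.
#' @param days_to_echo non-negative integers; days between ECG and echo.
#' @param schema an [ecg_schema()].
#' @param split one of `"unsplit"`, `"train"`, `"test"`, `"external"`.
#' @return An object of class `ecg_dataset`.
#' @export
ecg_dataset <- function(params, lvef, record_id = NULL, patient_id = NULL,
                        paced = NULL, days_to_echo = NULL,
                        schema = ecg_schema(), split = "unsplit") {
  params <- as.matrix(params)
  n <- nrow(params)
  record_id <- as.character(record_id %||% sprintf("rec%06d", seq_len(n)))
  patient_id <- as.character(patient_id %||% record_id)
  paced <- as.logical(paced %||% rep(FALSE, n))
  days_to_echo <- as.integer(days_to_echo %||% rep(0L, n))
  lvef <- as.numeric(lvef)

  if (!identical(colnames(params), schema$name)) {
    missing <- setdiff(schema$name, colnames(params))
    if (length(missing))
      stop("missing schema column(s): ", paste(head(missing, 5), collapse = ", "))
    params <- params[, schema$name, drop = FALSE]  # name-driven alignment
  }
  if (length(lvef) != n || length(record_id) != n || length(patient_id) != n ||
      length(paced) != n || length(days_to_echo) != n)
    stop("all per-record fields must have length nrow(params)")
  if (anyNA(params)) stop("missing parameter values; impute or drop before construction")
  if (any(lvef < 0 | lvef > 100, na.rm = TRUE) || anyNA(lvef))
    stop("lvef must lie in [0, 100]")
  if (any(days_to_echo < 0)) stop("days_to_echo must be >= 0")
  split <- match.arg(split, c("unsplit", "train", "test", "external"))

  structure(list(params = params, lvef = lvef, reduced = lvef < 40,
                 record_id = record_id, patient_id = patient_id,
                 paced = paced, days_to_echo = days_to_echo,
                 schema = schema, split = split),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d records, %d patients, %d parameters [%s]\n",
              nrow(x$params), length(unique(x$patient_id)),
              ncol(x$params), x$split))
  cat(sprintf("  reduced LVEF: %d (%.1f%%); paced: %d\n",
              sum(x$reduced), 100 * mean(x$reduced), sum(x$paced)))
  invisible(x)
}

#' @export
length.ecg_dataset <- function(x) nrow(x$params)

#' Subset an ecg_dataset by record index
#' @param x an `ecg_dataset`.
#' @param i integer or logical index over records.
#' @param ... unused.
#' @export
`[.ecg_dataset` <- function(x, i, ...) {
  out <- x
  out$params <- x$params[i, , drop = FALSE]
  for (f in c("lvef", "reduced", "record_id", "patient_id", "paced",
              "days_to_echo"))
    out[[f]] <- x[[f]][i]
  out
}

#' Read / write a paired dataset as a delimited table
#'
#' The table must contain `record_id`, `patient_id`, `lvef`, `paced` and one
#' column per schema parameter (`days_to_echo` optional).  Column order is
#' irrelevant: loading is name-driven.
#'
#' @param path CSV/TSV file with header.
#' @param schema an [ecg_schema()].
#' @param sep field separator; `","` default.
#' @param impute if `TRUE`, missing parameter cells are median-imputed
#'   (column medians); default `FALSE` rejects missing values.
#' @return An `ecg_dataset`.
#' @export
read_ecg_dataset <- function(path, schema = ecg_schema(), sep = ",",
                             impute = FALSE) {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("record_id", "patient_id", "lvef", "paced", schema$name)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(head(missing, 5), collapse = ", "))
  params <- as.matrix(df[, schema$name, drop = FALSE])
  if (!is.numeric(params)) {
    bad <- which(!apply(df[, schema$name, drop = FALSE], 2, is.numeric))[1]
    badrow <- which(is.na(suppressWarnings(
      as.numeric(df[[schema$name[bad]]]))))[1]
    stop(sprintf("non-numeric value in column '%s' (row %d)",
                 schema$name[bad], badrow %||% NA))
  }
  if (anyNA(params)) {
    if (!impute) {
      bad <- which(is.na(params), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at row %d, column '%s' (use impute = TRUE to median-impute)",
                   bad[1], colnames(params)[bad[2]]))
    }
    for (j in seq_len(ncol(params))) {
      nas <- is.na(params[, j])
      if (any(nas)) params[nas, j] <- stats::median(params[, j], na.rm = TRUE)
    }
  }
  ecg_dataset(params, lvef = df$lvef, record_id = df$record_id,
              patient_id = df$patient_id, paced = as.logical(df$paced),
              days_to_echo = df$days_to_echo %||% NULL, schema = schema)
}

#' @rdname read_ecg_dataset
#' @param ds an `ecg_dataset`.
#' @export
write_ecg_dataset <- function(ds, path, sep = ",") {
  df <- data.frame(record_id = ds$record_id, patient_id = ds$patient_id,
                   lvef = ds$lvef, paced = ds$paced,
                   days_to_echo = ds$days_to_echo,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ds$params, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Patient-grouped train/test split
#'
#' Randomly divides a dataset so that all records of a patient land on the
#' same side (no patient-level leakage between training and test data).
#' Patients are shuffled and assigned to the test side until the realized
#' record fraction best matches `test_fraction`.
#'
#' @param ds an unsplit `ecg_dataset`.
#' @param test_fraction target fraction of *records* in the test side.
#' @param seed integer RNG seed; the partition is deterministic given it.
#' @return A list with elements `train` and `test`, both `ecg_dataset`s.
#' @export
split_by_patient <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "ecg_dataset"), test_fraction > 0, test_fraction < 1)
  patients <- unique(ds$patient_id)
  if (length(patients) < 2) stop("need at least 2 patients to split")
  counts <- table(ds$patient_id)[patients]
  ord <- with_seed(seed, sample(length(patients)))
  cum <- cumsum(as.numeric(counts[ord]))
  target <- test_fraction * length(ds$patient_id)
  k <- which.min(abs(cum - target))
  test_patients <- patients[ord[seq_len(k)]]
  in_test <- ds$patient_id %in% test_patients
  train <- ds[!in_test]; train$split <- "train"
  test <- ds[in_test]; test$split <- "test"
  list(train = train, test = test)
}

#' Prevalence of reduced LVEF, in percent
#'
#' @param x an `ecg_dataset` or a logical vector of reduced-LVEF labels.
#' @param digits decimals to round to (tables conventionally print one).
#' @return Percentage of records with reduced LVEF.
#' @export
prevalence <- function(x, digits = 1) UseMethod("prevalence")

#' @export
prevalence.ecg_dataset <- function(x, digits = 1) {
  prevalence(x$reduced, digits = digits)
}

#' @export
prevalence.logical <- function(x, digits = 1) {
  if (!length(x)) stop("empty dataset")
  round(100 * mean(x), digits)
}
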