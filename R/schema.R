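ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

LEAD_KINDS <- c(R_amp = "mV", S_amp = "mV", Q_amp = "mV", T_amp = "mV",
                P_amp = "mV", ST_level = "mV",
                R_dur = "ms", S_dur = "ms", Q_dur = "ms", P_dur = "ms",
                T_dur = "ms", VAT = "ms", QTc_lead = "ms", RR_lead = "ms")

GLOBAL_KINDS <- c(HR = "bpm", PR_interval = "ms", QRS_duration = "ms",
                  QT_interval = "ms", QTc = "ms", RR_interval = "ms",
                  QRS_axis = "degrees", P_axis = "degrees",
                  age = "years", sex = "binary")

lead_param_name <- function(kind, lead) {
  switch(kind,
         QTc_lead = paste0("QTc_", lead),
         RR_lead  = paste0("RR_", lead),
         paste0(kind, "_", lead))
}

#' Default 178-entry ECG parameter schema
#'
#' The measurement vocabulary of an automatic 12-lead ECG analyser: for each
#' of the 12 leads, five wave amplitudes, the ST level, five wave durations,
#' the ventricular activation time (VAT), and per-lead corrected QT and RR
#' intervals (12 x 14 = 168 entries); plus ten global entries (heart rate,
#' PR/QRS/QT/QTc/RR, QRS and P axes, age, sex).  Amplitudes are in mV,
#' durations and intervals in ms, axes in degrees.
#'
#' Each entry also carries the direction vocabulary used when attribution
#' analysis turns a parameter into an ECG finding (see
#' [interpret_criteria()]): e.g. a low R amplitude reads as "low voltage",
#' a low T amplitude as "negative T-wave inversion", a high duration as a
#' prolongation.  Lead aVR is excluded from T-amplitude findings because its
#' normal T wave is inverted.
#'
#' @param extra ignored; reserved.
#' @return A data frame of class `ecg_schema` with columns `name`, `lead`,
#'   `kind`, `unit`.
#' @export
ecg_schema <- function(extra = NULL) {
  lead_rows <- do.call(rbind, lapply(ECG_LEADS, function(ld) {
    data.frame(name = vapply(names(LEAD_KINDS), lead_param_name, "", lead = ld),
               lead = ld, kind = names(LEAD_KINDS),
               unit = unname(LEAD_KINDS),
               stringsAsFactors = FALSE)
  }))
  global_rows <- data.frame(name = names(GLOBAL_KINDS), lead = "GLOBAL",
                            kind = names(GLOBAL_KINDS),
                            unit = unname(GLOBAL_KINDS),
                            stringsAsFactors = FALSE)
  schema <- rbind(lead_rows, global_rows)
  rownames(schema) <- NULL
  stopifnot(!anyDuplicated(schema$name))
  class(schema) <- c("ecg_schema", "data.frame")
  schema
}

#' @export
print.ecg_schema <- function(x, ...) {
  cat("ECG parameter schema:", nrow(x), "parameters (",
      sum(x$lead != "GLOBAL"), "per-lead,", sum(x$lead == "GLOBAL"),
      "global )\n")
  invisible(x)
}

#' Read or write a parameter schema as JSON
#'
#' @param path file path.
#' @param schema an `ecg_schema`.
#' @return `read_schema` returns an `ecg_schema`; `write_schema` its path,
#'   invisibly.
#' @export
read_schema <- function(path) {
  df <- jsonlite::fromJSON(path)
  need <- c("name", "lead", "kind", "unit")
  if (!all(need %in% names(df)))
    stop("schema file must provide columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$name)) stop("duplicate parameter names in schema file")
  class(df) <- c("ecg_schema", "data.frame")
  df
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(as.data.frame(schema), path, auto_unbox = FALSE)
  invisible(path)
}

# Direction vocabulary: which ECG finding a decision factor on a given
# parameter expresses, given the direction (low/high) of the cluster's values
# relative to the reference population.  NA means the factor yields no
# finding (age, axes, rates, aVR T amplitude, ...).
finding_word <- function(kind, lead, direction) {
  if (direction == "none") return(NA_character_)
  low <- direction == "low"
  switch(kind,
    R_amp    = if (low) "low voltage" else "high voltage",
    T_amp    = {
      if (lead == "aVR") return(NA_character_)  # inverted lead: low T is normal
      if (low) "negative T-wave inversion" else "tall T wave"
    },
    Q_amp    = if (!low) "Q wave" else NA_character_,
    Q_dur    = if (!low) "Q wave" else NA_character_,
    S_amp    = if (!low) "deep S wave" else NA_character_,
    P_amp    = if (low) "low P-wave voltage" else NA_character_,
    ST_level = if (low) "ST depression" else "ST elevation",
    R_dur    = if (!low) "R-wave prolongation" else NA_character_,
    S_dur    = if (!low) "S-wave prolongation" else NA_character_,
    P_dur    = if (!low) "P-wave prolongation" else NA_character_,
    T_dur    = if (!low) "T-wave prolongation" else NA_character_,
    VAT      = if (!low) "VAT prolongation" else NA_character_,
    QTc_lead = if (!low) "QTc prolongation" else NA_character_,
    QTc      = if (!low) "QTc prolongation" else NA_character_,
    QT_interval  = if (!low) "QT prolongation" else NA_character_,
    QRS_duration = if (!low) "QRS prolongation" else NA_character_,
    NA_character_  # HR, PR, RR, axes, age, sex: no finding vocabulary
  )
}
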