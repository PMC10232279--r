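# Non-waveform parameters: decision factors on these never yield an ECG
# finding (they may still rank among a cluster's factors, e.g. age).
NON_WAVEFORM_KINDS <- c("age", "sex", "HR", "PR_interval", "RR_interval",
                        "RR_lead", "QRS_axis", "P_axis")

#' The six canonical ECG finding categories
#'
#' Reduced-LVEF decision criteria extracted from attribution clusters
#' decompose into six recurring ECG findings, each tied to a canonical lead
#' group: negative T-wave inversion (I/V5-6), low voltage (I/II/V4-6),
#' Q wave (V3-6), VAT prolongation (I/V5-6), S-wave prolongation (V2-3),
#' and QTc prolongation (any lead or the global interval).  VAT and S-wave
#' prolongation both express intraventricular conduction delay and are
#' reported as one super-group.
#'
#' @return Data frame: `code`, `finding`, `leads` ("/"-joined canonical
#'   group; empty for QTc), `supergroup`.
#' @export
finding_categories <- function() {
  data.frame(
    code = c("NEG_T_INVERSION_I_V56", "LOW_VOLTAGE_I_II_V46", "Q_WAVE_V36",
             "VAT_PROLONG_I_V56", "S_PROLONG_V23", "QTC_PROLONG"),
    finding = c("negative T-wave inversion", "low voltage", "Q wave",
                "VAT prolongation", "S-wave prolongation",
                "QTc prolongation"),
    leads = c("I/V5/V6", "I/II/V4/V5/V6", "V3/V4/V5/V6", "I/V5/V6",
              "V2/V3", ""),
    supergroup = c("", "", "", "intraventricular conduction delay",
                   "intraventricular conduction delay", ""),
    stringsAsFactors = FALSE)
}

#' Extract per-cluster decision factors from attribution values
#'
#' A parameter is a decision factor of a cluster when its median SHAP value
#' over the cluster's records strictly exceeds the mean + 1 SD of the SHAP
#' values over all parameters.  By default the mean and SD are taken over
#' the p per-parameter cluster medians (population-SD convention), making
#' the threshold commensurable with the quantity tested; `over = "entries"`
#' instead pools all n x p attribution entries of the cluster.
#'
#' @param sm a [shap_matrix()] covering the clustered records (rows aligned
#'   with `clusters$labels`).
#' @param clusters a [cluster_embedding()] result, or an integer label
#'   vector.
#' @param over `"medians"` (default) or `"entries"`: the population over
#'   which the mean + SD threshold is computed.
#' @param include_unexplained also extract factors for clusters flagged too
#'   small (default `FALSE`).
#' @return A data frame of class `decision_factors`: `cluster`, `parameter`,
#'   `median_shap`, `threshold`, sorted by decreasing median within cluster.
#' @export
decision_factors <- function(sm, clusters, over = c("medians", "entries"),
                             include_unexplained = FALSE) {
  over <- match.arg(over)
  labels <- if (inherits(clusters, "shap_clusters")) clusters$labels else
    as.integer(clusters)
  if (length(labels) != nrow(sm$values))
    stop("attribution rows do not cover all clustered records")
  unexplained <- if (inherits(clusters, "shap_clusters"))
    clusters$unexplained else integer()
  out <- list()
  for (k in sort(unique(labels))) {
    rows <- which(labels == k)
    if (!length(rows)) { warning("empty cluster ", k, " skipped"); next }
    if (!include_unexplained && k %in% unexplained) next
    med <- apply(sm$values[rows, , drop = FALSE], 2, stats::median)
    thr <- switch(over,
                  medians = mean(med) + pop_sd(med),
                  entries = mean(sm$values[rows, ]) + pop_sd(sm$values[rows, ]))
    hit <- which(med > thr)
    if (!length(hit)) next
    ord <- hit[order(-med[hit])]
    out[[length(out) + 1]] <- data.frame(
      cluster = k, parameter = sm$feature_names[ord],
      median_shap = unname(med[ord]), threshold = unname(thr),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster = integer(), parameter = character(),
               median_shap = numeric(), threshold = numeric())
  class(res) <- c("decision_factors", "data.frame")
  res
}

#' Interpret decision factors as signed ECG findings
#'
#' Each decision factor on a waveform parameter is read against the actual
#' parameter distributions: the cluster's median parameter value is compared
#' with the reference (whole test set) median, and when they differ by at
#' least `min_effect_sd` reference SDs the schema's direction vocabulary
#' supplies the finding word (low R amplitude -> "low voltage", low T
#' amplitude -> "negative T-wave inversion", high duration/VAT/QTc ->
#' prolongation, elevated Q duration/amplitude -> "Q wave").  Non-waveform
#' factors (age, axes, rates) yield no criterion.  Leads sharing a finding
#' within a cluster are merged into one criterion.
#'
#' @param factors a [decision_factors()] data frame.
#' @param values parameter matrix of the clustered records (rows aligned
#'   with `labels`).
#' @param labels cluster labels aligned with `values`.
#' @param reference parameter matrix of the reference population (whole
#'   test set).
#' @param schema the [ecg_schema()] in use.
#' @param min_effect_sd minimum |cluster median - reference median| in
#'   reference SDs for a direction call (default 0.2).
#' @return Data frame of class `decision_criteria`: `cluster`, `finding`,
#'   `leads` ("/"-joined), `direction`.
#' @export
interpret_criteria <- function(factors, values, labels, reference,
                               schema = ecg_schema(), min_effect_sd = 0.2) {
  if (!nrow(reference)) stop("reference table is empty")
  values <- as.matrix(values); reference <- as.matrix(reference)
  rows <- list()
  for (i in seq_len(nrow(factors))) {
    par <- factors$parameter[i]
    k <- factors$cluster[i]
    j <- match(par, schema$name)
    if (is.na(j)) stop("decision factor on unknown parameter: ", par)
    kind <- schema$kind[j]; lead <- schema$lead[j]
    if (kind %in% NON_WAVEFORM_KINDS) next
    cl_med <- stats::median(values[labels == k, par])
    ref_med <- stats::median(reference[, par])
    ref_sd <- pop_sd(reference[, par])
    if (abs(cl_med - ref_med) < min_effect_sd * ref_sd) next
    direction <- if (cl_med < ref_med) "low" else "high"
    finding <- finding_word(kind, lead, direction)
    if (is.na(finding)) next
    rows[[length(rows) + 1]] <- data.frame(
      cluster = k, finding = finding, lead = lead, direction = direction,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    res <- data.frame(cluster = integer(), finding = character(),
                      leads = character(), direction = character())
    class(res) <- c("decision_criteria", "data.frame")
    return(res)
  }
  df <- do.call(rbind, rows)
  lead_order <- c(ECG_LEADS, "GLOBAL")
  agg <- lapply(split(df, list(df$cluster, df$finding), drop = TRUE),
                function(g) {
    leads <- unique(g$lead)
    leads <- leads[order(match(leads, lead_order))]
    data.frame(cluster = g$cluster[1], finding = g$finding[1],
               leads = paste(leads, collapse = "/"),
               direction = g$direction[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  res <- res[order(res$cluster, res$finding), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("decision_criteria", "data.frame")
  res
}

# A criterion matches a canonical category when enough of its leads fall in
# the category's lead group: at least min(2, ceil(group/2)) leads, so broad
# categories (low voltage across I/II/V4-6) need two supporting leads while
# the two-lead S-prolongation group accepts a single lead; QTc prolongation
# matches regardless of leads.
match_category <- function(finding, leads_str) {
  cats <- finding_categories()
  row <- cats[cats$finding == finding, ]
  if (!nrow(row)) return(NA_character_)
  if (row$code == "QTC_PROLONG") return(row$code)
  group <- strsplit(row$leads, "/")[[1]]
  leads <- strsplit(leads_str, "/")[[1]]
  need <- min(2, ceiling(length(group) / 2))
  if (sum(leads %in% group) >= need) row$code else NA_character_
}

#' Map decision criteria to the six canonical categories
#'
#' @param criteria a [interpret_criteria()] data frame.
#' @return Named list: per cluster (as character key), the sorted vector of
#'   matched category codes.  Criteria outside the six categories are kept
#'   in the `"outside"` attribute (finding + leads per cluster), never
#'   dropped silently.  Clusters whose categories include both VAT and
#'   S-wave prolongation carry the `"supergroup"` attribute entry
#'   "intraventricular conduction delay".
#' @export
categorize_criteria <- function(criteria) {
  out <- list(); outside <- list()
  for (k in sort(unique(criteria$cluster))) {
    sub <- criteria[criteria$cluster == k, , drop = FALSE]
    codes <- character(); miss <- character()
    for (i in seq_len(nrow(sub))) {
      code <- match_category(sub$finding[i], sub$leads[i])
      if (is.na(code)) miss <- c(miss, paste0(sub$finding[i], " [", sub$leads[i], "]"))
      else codes <- c(codes, code)
    }
    out[[as.character(k)]] <- sort(unique(codes))
    if (length(miss)) outside[[as.character(k)]] <- sort(unique(miss))
  }
  attr(out, "outside") <- outside
  attr(out, "supergroup") <- vapply(out, function(v)
    if (all(c("VAT_PROLONG_I_V56", "S_PROLONG_V23") %in% v))
      "intraventricular conduction delay" else "", "")
  out
}

#' Write per-cluster factor and criteria reports
#'
#' @param factors,criteria,categories the three stage outputs.
#' @param dir output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_criteria_report <- function(factors, criteria, categories, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "decision_factors.csv")
  f2 <- file.path(dir, "decision_criteria.json")
  utils::write.csv(as.data.frame(factors), f1, row.names = FALSE)
  jsonlite::write_json(
    list(criteria = as.data.frame(criteria),
         categories = lapply(categories, identity),
         outside = attr(categories, "outside"),
         supergroup = as.list(attr(categories, "supergroup"))),
    f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2))
}
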