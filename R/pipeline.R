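#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end decision-criteria pipeline with
#' its default.  All randomness derives from `seed`.
#'
#' @param family classifier family (see [fit_lvef_model()]).
#' @param hyper classifier hyperparameters.
#' @param test_fraction patient-grouped test split fraction.
#' @param background_size interventional SHAP background rows.
#' @param pca_dims,n_neighbors,min_dist embedding parameters.
#' @param K_max,min_cluster_size clustering parameters.
#' @param factor_over population for the decision-factor threshold
#'   (`"medians"` or `"entries"`).
#' @param min_effect_sd direction-call threshold in reference SDs.
#' @param cutoff probability cut-off for positive calls.
#' @param bootstrap_B bootstrap replicates for metric CIs.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(family = "random_forest", hyper = list(),
                            test_fraction = 0.3, background_size = 64,
                            pca_dims = 20, n_neighbors = 8, min_dist = 0.05,
                            K_max = 10, min_cluster_size = 10,
                            factor_over = "medians", min_effect_sd = 0.2,
                            cutoff = 0.5, bootstrap_B = 1000, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the decision-criteria pipeline end to end
#'
#' Train -> score -> attribute -> embed -> cluster -> extract factors ->
#' interpret criteria -> categorize, on a given train/test pair.  When
#' `model` is supplied, training is skipped and the fitted model is reused
#' (the external-replay mode: the same explanations on a second dataset,
#' with the embedding and clustering refitted on the new cohort).
#'
#' @param train,test [ecg_dataset()]s; `train` may be `NULL` when `model`
#'   is given.
#' @param cfg a [pipeline_config()].
#' @param model optional pre-fitted `ecg_model` to reuse.
#' @param background optional explicit background matrix; defaults to a
#'   seed-fixed subsample of the training data.
#' @param out_dir if non-`NULL`, artifacts (CSV/JSON tables and a manifest
#'   with content hashes) are written there.
#' @return A `lvef_pipeline` list with every stage's output.
#' @export
run_lvef_pipeline <- function(train, test, cfg = pipeline_config(),
                              model = NULL, background = NULL,
                              out_dir = NULL) {
  if (is.null(model)) {
    model <- fit_lvef_model(train, family = cfg$family, hyper = cfg$hyper,
                            seed = derive_seed(cfg$seed, "fit"))
  }
  probs <- predict_proba(model, test)
  metrics <- metric_report(probs, test$reduced, cutoff = cfg$cutoff,
                           B = cfg$bootstrap_B,
                           seed = derive_seed(cfg$seed, "boot"))

  cohort_idx <- select_explanation_cohort(test, probs, cutoff = cfg$cutoff)
  cohort <- test[cohort_idx]
  if (is.null(background)) {
    if (is.null(train)) stop("need train data or an explicit background")
    background <- draw_background(
      train, background_spec(size = cfg$background_size,
                             seed = derive_seed(cfg$seed, "bg")))
  }
  sm <- shap_values(model, cohort, background,
                    bg = background_spec(size = nrow(background),
                                         seed = derive_seed(cfg$seed, "bg")))
  emb <- embed_attributions(sm, pca_dims = cfg$pca_dims,
                            n_neighbors = cfg$n_neighbors,
                            min_dist = cfg$min_dist,
                            seed = derive_seed(cfg$seed, "umap"))
  clusters <- cluster_embedding(emb, K_max = cfg$K_max,
                                min_cluster_size = cfg$min_cluster_size,
                                seed = derive_seed(cfg$seed, "vbgmm"))
  factors <- decision_factors(sm, clusters, over = cfg$factor_over)
  criteria <- interpret_criteria(factors, cohort$params, clusters$labels,
                                 reference = test$params,
                                 schema = test$schema,
                                 min_effect_sd = cfg$min_effect_sd)
  categories <- categorize_criteria(criteria)

  res <- structure(list(model = model, probs = probs, metrics = metrics,
                        cohort_idx = cohort_idx, cohort = cohort,
                        background = background, shap = sm,
                        embedding = emb, clusters = clusters,
                        factors = factors, criteria = criteria,
                        categories = categories, config = cfg),
                   class = "lvef_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.lvef_pipeline <- function(x, ...) {
  cat("<lvef_pipeline>\n")
  cat(sprintf("  model: %s; test records: %d; explanation cohort: %d\n",
              x$model$family, length(x$probs), length(x$cohort_idx)))
  cat(sprintf("  clusters: %d (unexplained: %s)\n", x$clusters$effective_K,
              if (length(x$clusters$unexplained))
                paste(x$clusters$unexplained, collapse = ",") else "none"))
  cat(sprintf("  decision factors: %d rows over %d clusters\n",
              nrow(x$factors), length(unique(x$factors$cluster))))
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(out_dir, "metrics.csv")
  utils::write.csv(res$metrics, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(out_dir, "predictions.csv")
  utils::write.csv(data.frame(record_id = res$cohort$record_id,
                              prob = res$probs[res$cohort_idx]),
                   p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(out_dir, "attributions.csv")
  write_shap_matrix(res$shap, p)
  paths <- c(paths, p, sub("\\.csv$", ".json", p))
  p <- file.path(out_dir, "embedding.csv")
  utils::write.csv(data.frame(record_id = res$cohort$record_id,
                              x = res$embedding$coords[, 1],
                              y = res$embedding$coords[, 2],
                              cluster = res$clusters$labels),
                   p, row.names = FALSE); paths <- c(paths, p)
  paths <- c(paths, write_criteria_report(res$factors, res$criteria,
                                          res$categories, out_dir))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = res$config$seed, files = manifest),
                       mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}

#' Explain a single record against a fitted pipeline
#'
#' The clinical-use view: predicted probability and call for one ECG, its
#' attribution vector, its projection into the fitted 2-D attribution map,
#' the nearest cluster and that cluster's decision criteria.  Predicted-
#' negative records are reported without cohort membership; paced records
#' are flagged excluded from clustering but still scored.
#'
#' @param res a [run_lvef_pipeline()] result.
#' @param record one-row parameter matrix (or single-record
#'   [ecg_dataset()]).
#' @param paced whether the record shows a paced rhythm.
#' @return List with `prob`, `call`, `shap`, and (for cohort-eligible
#'   calls) `coords`, `cluster`, `responsibility`, `criteria`.
#' @export
explain_record <- function(res, record, paced = FALSE) {
  if (inherits(record, "ecg_dataset")) {
    paced <- record$paced[1]
    record <- record$params[1, , drop = FALSE]
  }
  prob <- predict_proba(res$model, record)
  call <- classify(prob, res$config$cutoff)
  sm <- shap_values(res$model, record, res$background,
                    bg = background_spec(size = nrow(res$background)))
  out <- list(prob = prob, call = call, shap = sm$values[1, ],
              base_value = sm$base_value, paced = paced)
  if (!call) {
    out$note <- "predicted negative: no explanation cohort membership"
    return(out)
  }
  if (paced) out$note <- "paced rhythm: excluded from clustering"
  proj <- project_attribution(res$embedding, res$clusters, sm$values[1, ])
  out$coords <- proj$coords
  out$cluster <- proj$cluster
  out$responsibility <- proj$responsibility
  out$criteria <- res$criteria[res$criteria$cluster == proj$cluster, ,
                               drop = FALSE]
  out
}
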