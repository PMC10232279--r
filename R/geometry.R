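#' Select the explanation cohort
#'
#' The records whose attribution patterns are clustered and explained:
#' those the model calls reduced-LVEF (probability strictly above the
#' cut-off) that do not show a paced rhythm.  Paced ECGs are excluded
#' because pacing dominates the waveform and their attribution patterns
#' reflect the pacemaker, not intrinsic conduction.
#'
#' @param ds an [ecg_dataset()].
#' @param probs predicted probabilities aligned with `ds`.
#' @param cutoff decision threshold (default 0.5, strict).
#' @return Integer vector of record indices into `ds`.
#' @export
select_explanation_cohort <- function(ds, probs, cutoff = 0.5) {
  if (length(probs) != length(ds$paced))
    stop("probs and dataset lengths differ")
  which(probs > cutoff & !ds$paced)
}

#' Embed an attribution matrix to two dimensions (PCA then UMAP)
#'
#' High-dimensional per-record attribution vectors are first reduced
#' linearly to `pca_dims` principal components and then to two dimensions
#' with UMAP.  The fitted transform (PCA basis + UMAP model) is retained so
#' new records can be projected into the same space.
#'
#' @param sm a [shap_matrix()].
#' @param pca_dims number of principal components before UMAP (default 20).
#' @param n_neighbors,min_dist UMAP hyperparameters; the defaults (8, 0.05)
#'   favor local structure at explanation-cohort sizes of a few hundred
#'   records and compact blobs for the downstream mixture clustering.
#' @param scale standardize attribution columns to unit variance before PCA
#'   (default `TRUE`): cluster identity lives in which parameters are
#'   attributed, not in the shared overall attribution magnitude.
#' @param seed integer seed; the embedding is deterministic given it.
#' @return A `shap_embedding`: `coords` (n x 2), plus transform state.
#' @export
embed_attributions <- function(sm, pca_dims = 20, n_neighbors = 8,
                               min_dist = 0.05, scale = TRUE, seed = 42L) {
  X <- sm$values
  n <- nrow(X)
  if (n < 3) stop("need at least 3 records to embed")
  spread <- max(apply(X, 2, stats::var))
  if (spread == 0) {
    # degenerate input: identical rows collapse to a single point
    return(structure(list(coords = matrix(0, n, 2), degenerate = TRUE,
                          pca = NULL, umap = NULL, pca_dims = 0,
                          record_ids = sm$record_ids, seed = seed),
                     class = "shap_embedding"))
  }
  col_center <- colMeans(X)
  col_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  col_scale[col_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, col_center), 2, col_scale, "/")
  k <- min(pca_dims, n - 1, ncol(X))
  pca <- stats::prcomp(Xs, center = FALSE, scale. = FALSE, rank. = k)
  nn <- min(n_neighbors, n - 1)
  um <- with_seed(seed,
    uwot::umap(pca$x, n_neighbors = nn, min_dist = min_dist,
               n_components = 2, ret_model = TRUE,
               n_threads = 1, n_sgd_threads = 0))
  structure(list(coords = unname(um$embedding), degenerate = FALSE,
                 pca = list(center = col_center, scale = col_scale,
                            rotation = pca$rotation),
                 umap = um, pca_dims = k, record_ids = sm$record_ids,
                 n_neighbors = nn, min_dist = min_dist, seed = seed),
            class = "shap_embedding")
}

#' @export
print.shap_embedding <- function(x, ...) {
  cat(sprintf("<shap_embedding> %d records, PCA %d dims -> UMAP 2\n",
              nrow(x$coords), x$pca_dims))
  invisible(x)
}

#' Cluster an attribution embedding with a variational Bayesian GMM
#'
#' @param emb a [embed_attributions()] result.
#' @param K_max maximum components; the occupied count is data-driven.
#' @param min_cluster_size clusters smaller than this are flagged
#'   "unexplained" (too few records to support decision criteria).
#' @param alpha0 Dirichlet concentration prior (default `1/K_max`).
#' @param seed integer seed.
#' @return A `shap_clusters` object with `labels` (1..effective_K, ordered
#'   by decreasing size), `responsibilities`, `sizes`, and `unexplained`
#'   (labels of under-sized clusters).
#' @export
cluster_embedding <- function(emb, K_max = 10, min_cluster_size = 10,
                              alpha0 = 1 / K_max, seed = 7L) {
  coords <- emb$coords
  if (any(!is.finite(coords))) stop("non-finite embedding coordinates")
  if (isTRUE(emb$degenerate)) {
    n <- nrow(coords)
    return(structure(list(labels = rep(1L, n),
                          responsibilities = matrix(1, n, 1),
                          sizes = n, unexplained = integer(),
                          effective_K = 1L, fit = NULL, relabel = 1L,
                          min_cluster_size = min_cluster_size),
                     class = "shap_clusters"))
  }
  fit <- vbgmm(coords, K_max = K_max, alpha0 = alpha0, seed = seed)
  # relabel occupied components 1..K_eff by decreasing size
  sizes0 <- tabulate(fit$labels, nbins = fit$K_max)
  ord <- order(-sizes0, seq_len(fit$K_max))
  ord <- ord[sizes0[ord] > 0]
  relabel <- integer(fit$K_max)
  relabel[ord] <- seq_along(ord)
  labels <- relabel[fit$labels]
  resp <- fit$responsibilities[, ord, drop = FALSE]
  sizes <- tabulate(labels, nbins = length(ord))
  structure(list(labels = labels, responsibilities = resp, sizes = sizes,
                 unexplained = which(sizes < min_cluster_size),
                 effective_K = length(ord), fit = fit, relabel = relabel,
                 min_cluster_size = min_cluster_size),
            class = "shap_clusters")
}

#' @export
print.shap_clusters <- function(x, ...) {
  cat(sprintf("<shap_clusters> %d clusters, sizes: %s\n", x$effective_K,
              paste(x$sizes, collapse = ", ")))
  if (length(x$unexplained))
    cat("  unexplained (too small):",
        paste(x$unexplained, collapse = ", "), "\n")
  invisible(x)
}

#' Project a new attribution vector into a fitted embedding
#'
#' Transforms one record's attribution vector through the stored PCA basis
#' and UMAP model and evaluates the cluster responsibilities at the
#' projected point — the way a newly acquired ECG is placed into the
#' existing explanation map.
#'
#' @param emb a fitted `shap_embedding`.
#' @param clusters the matching `shap_clusters`.
#' @param attr_row numeric attribution vector (length p of the original
#'   matrix).
#' @return List: `coords` (length-2), `cluster` (nearest cluster label),
#'   `responsibility` (its responsibility).
#' @export
project_attribution <- function(emb, clusters, attr_row) {
  if (isTRUE(emb$degenerate))
    return(list(coords = c(0, 0), cluster = 1L, responsibility = 1))
  if (length(attr_row) != nrow(emb$pca$rotation))
    stop("attribution vector has wrong length")
  scores <- matrix((attr_row - emb$pca$center) / emb$pca$scale, 1) %*%
    emb$pca$rotation
  coords <- with_seed(emb$seed,
    uwot::umap_transform(scores, emb$umap, n_threads = 1))
  if (is.null(clusters$fit)) {
    return(list(coords = as.numeric(coords), cluster = 1L,
                responsibility = 1))
  }
  resp_all <- vbgmm_responsibility(clusters$fit, coords)
  # reorder to the relabeled clusters
  keep <- which(clusters$relabel > 0)[order(clusters$relabel[clusters$relabel > 0])]
  resp <- resp_all[, keep, drop = FALSE]
  resp <- resp / sum(resp)
  k <- which.max(resp[1, ])
  list(coords = as.numeric(coords), cluster = as.integer(k),
       responsibility = as.numeric(resp[1, k]))
}
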