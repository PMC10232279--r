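# Attribution matrices with two planted, well-separated row groups.
two_blob_shap <- function(n_each = 40, p = 30, sep = 10, seed = 3) {
  set.seed(seed)
  base <- matrix(rnorm(2 * n_each * p, sd = 1), 2 * n_each, p)
  base[seq_len(n_each), 1:5] <- base[seq_len(n_each), 1:5] + sep
  colnames(base) <- paste0("f", seq_len(p))
  shap_matrix(base, base_value = 0.1)
}

test_that("the explanation cohort is predicted-positive and non-paced", {
  sch <- tiny_schema(2)
  n <- 429
  ds <- ecg_dataset(matrix(rnorm(n * 2), n, 2,
                           dimnames = list(NULL, sch$name)),
                    lvef = rep(30, n), paced = rep(c(TRUE, FALSE),
                                                   c(237, 192)),
                    schema = sch)
  idx <- select_explanation_cohort(ds, rep(0.9, n))
  expect_length(idx, 192)                       # 429 positive, 237 paced
  # no paced records: cohort equals the predicted-positive set
  ds2 <- ds; ds2$paced <- rep(FALSE, n)
  probs <- runif(n)
  expect_identical(select_explanation_cohort(ds2, probs),
                   which(probs > 0.5))
  # pure filter: subset of input, idempotent under re-filtering
  idx2 <- select_explanation_cohort(ds, rep(0.9, n))
  expect_identical(idx, idx2)
  expect_true(all(idx %in% seq_len(n)))
  expect_error(select_explanation_cohort(ds, runif(10)), "length")
})

test_that("embedding separates planted groups and is reproducible", {
  sm <- two_blob_shap()
  emb <- embed_attributions(sm, seed = 11)
  expect_equal(dim(emb$coords), c(80, 2))
  truth <- rep(1:2, each = 40)
  # mean silhouette on the 2-D coordinates
  d <- as.matrix(dist(emb$coords))
  sil <- vapply(seq_len(80), function(i) {
    a <- mean(d[i, truth == truth[i]][-which(which(truth == truth[i]) == i)])
    b <- mean(d[i, truth != truth[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
  emb2 <- embed_attributions(sm, seed = 11)
  expect_identical(emb$coords, emb2$coords)
})

test_that("degenerate and undersized attribution inputs are handled", {
  flat <- shap_matrix(matrix(0.2, 10, 6,
                             dimnames = list(NULL, paste0("f", 1:6))),
                      base_value = 0)
  emb <- embed_attributions(flat)
  expect_true(emb$degenerate)
  expect_lt(max(dist(emb$coords)), 1e-6)
  cl <- cluster_embedding(emb)
  expect_equal(cl$effective_K, 1L)
  expect_error(embed_attributions(shap_matrix(matrix(1, 2, 3), 0)),
               "at least 3")
})

test_that("clustering the embedding recovers planted groups and flags small ones", {
  sm <- two_blob_shap(n_each = 45)
  emb <- embed_attributions(sm, seed = 11)
  cl <- cluster_embedding(emb, K_max = 8, seed = 5)
  truth <- rep(1:2, each = 45)
  # the recovered partition refines the planted one: every cluster is pure
  # in truth (UMAP blob shapes may legitimately split, but never merge)
  expect_gte(cl$effective_K, 2)
  purity <- vapply(seq_len(cl$effective_K), function(k)
    max(table(truth[cl$labels == k])) / sum(cl$labels == k), 0)
  expect_true(all(purity >= 0.95))
  expect_length(cl$unexplained, 0)

  # a 9-member group with min_cluster_size 10 is flagged unexplained
  sm9 <- two_blob_shap(n_each = 45)
  sm9$values <- rbind(sm9$values, matrix(rnorm(9 * 30, mean = -10), 9, 30))
  emb9 <- embed_attributions(sm9, seed = 11)
  cl9 <- cluster_embedding(emb9, K_max = 8, min_cluster_size = 10, seed = 5)
  expect_gte(cl9$effective_K, 3)
  small <- which(cl9$sizes == 9)
  expect_length(small, 1)
  expect_true(small %in% cl9$unexplained)
  # and its factors are skipped by default
  fac <- decision_factors(sm9, cl9)
  expect_false(small %in% fac$cluster)
})

test_that("projection places known rows near their fitted coordinates", {
  sm <- two_blob_shap(n_each = 45)
  emb <- embed_attributions(sm, seed = 11)
  cl <- cluster_embedding(emb, K_max = 8, seed = 5)
  hits <- vapply(seq(1, 90, by = 9), function(i) {
    pr <- project_attribution(emb, cl, sm$values[i, ])
    pr$cluster == cl$labels[i]
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  pr <- project_attribution(emb, cl, sm$values[1, ])
  expect_true(all(is.finite(pr$coords)))
  expect_gte(pr$responsibility, 0.5)
  expect_error(project_attribution(emb, cl, rnorm(7)), "length")
})
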