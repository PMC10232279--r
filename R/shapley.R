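#' Attribution matrix container
#'
#' Per-record, per-parameter Shapley values in probability units, together
#' with the base value (expected model output over the background).  The
#' local-accuracy (efficiency) axiom holds row-wise: `base_value` plus the
#' row sum equals the model's predicted probability for that record.
#'
#' @param values n x p numeric matrix of Shapley values.
#' @param base_value scalar expected prediction over the background.
#' @param record_ids,feature_names row/column identities.
#' @param pred predicted probabilities for the explained records (optional).
#' @return A `shap_matrix`.
#' @export
shap_matrix <- function(values, base_value, record_ids = NULL,
                        feature_names = NULL, pred = NULL) {
  values <- as.matrix(values)
  structure(list(values = values, base_value = base_value,
                 record_ids = record_ids %||% rownames(values) %||%
                   as.character(seq_len(nrow(values))),
                 feature_names = feature_names %||% colnames(values),
                 pred = pred),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d records x %d features, base value %.4f\n",
              nrow(x$values), ncol(x$values), x$base_value))
  invisible(x)
}

#' Background specification for interventional attribution
#'
#' @param source `"subsample"` or `"full"`; with `"subsample"`, `size` rows
#'   are drawn from the training data with the given seed.
#' @param size number of background rows (default 64).
#' @param seed integer seed for the subsample.
#' @return A `background_spec`.
#' @export
background_spec <- function(source = c("subsample", "full"), size = 64,
                            seed = 1L) {
  source <- match.arg(source)
  stopifnot(size >= 1)
  structure(list(source = source, size = size, seed = seed),
            class = "background_spec")
}

draw_background <- function(train, spec) {
  x <- if (inherits(train, "ecg_dataset")) train$params else as.matrix(train)
  if (spec$source == "full" || spec$size >= nrow(x)) return(x)
  idx <- with_seed(spec$seed, sample(nrow(x), spec$size))
  x[idx, , drop = FALSE]
}

# Canonical tree encoding for the C++ kernel: columns (left, right, var,
# split, value), 0-based indices, var = -1 at terminal nodes.
forest_trees <- function(m) {
  rf <- m$fit
  classification <- rf$type == "classification"
  lapply(seq_len(rf$ntree), function(k) {
    tr <- randomForest::getTree(rf, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    val <- tr[, "prediction"]
    if (classification) val <- as.numeric(val == 2)  # level 2 == TRUE
    cbind(left = tr[, "left daughter"] - 1,
          right = tr[, "right daughter"] - 1,
          var = ifelse(leaf, -1, tr[, "split var"] - 1),
          split = tr[, "split point"],
          value = ifelse(leaf, val, 0))
  })
}

#' Interventional Shapley attributions for a fitted classifier
#'
#' Computes per-record SHAP values on the probability scale with
#' interventional (background-marginalized) semantics: the value of a
#' coalition S is the mean model output with the explained record's values
#' on S and background values elsewhere.  Three computational routes share
#' those semantics:
#'
#' * random forests use an exact tree-path algorithm (C++) that is linear in
#'   leaves x background rows;
#' * other families with p <= 13 features use kernel SHAP with full subset
#'   enumeration, which equals the exact Shapley values;
#' * larger non-tree models use sampled kernel SHAP (paired subsets), which
#'   still satisfies efficiency exactly via its constraint.
#'
#' @param m an `ecg_model`.
#' @param records records to explain ([ecg_dataset()] or matrix).
#' @param background background rows: a matrix, an `ecg_dataset`, or a
#'   training dataset plus [background_spec()] via `bg`.
#' @param bg a [background_spec()] applied to `background`.
#' @param nsamples subset budget for sampled kernel SHAP.
#' @return A [shap_matrix()].
#' @export
shap_values <- function(m, records, background, bg = background_spec(),
                        nsamples = 2048) {
  stopifnot(inherits(m, "ecg_model"))
  x <- model_matrix(m, records)
  z <- draw_background(background, bg)
  if (nrow(z) < 1) stop("empty background")
  z <- model_matrix(m, z)
  pred <- predict_proba(m, x)
  base <- mean(predict_proba(m, z))

  if (m$family == "random_forest") {
    trees <- forest_trees(m)
    res <- treeshap_interventional(x, z, trees)
    phi <- res$phi
  } else if (ncol(x) <= 13) {
    phi <- t(vapply(seq_len(nrow(x)), function(i)
      kernel_shap_exact(function(mm) predict_proba(m, mm), x[i, ], z),
      numeric(ncol(x))))
  } else {
    phi <- t(vapply(seq_len(nrow(x)), function(i)
      kernel_shap_sampled(function(mm) predict_proba(m, mm), x[i, ], z,
                          nsamples = nsamples,
                          seed = derive_seed(bg$seed, paste0("ks", i))),
      numeric(ncol(x))))
  }
  dimnames(phi) <- list(NULL, colnames(x))
  rid <- if (inherits(records, "ecg_dataset")) records$record_id else rownames(x)
  shap_matrix(phi, base_value = base, record_ids = rid,
              feature_names = colnames(x), pred = pred)
}

#' Exact Shapley values by subset enumeration
#'
#' Brute-force oracle for the interventional coalition game
#' `v(S) = mean_z f(x_S, z_else)`: enumerates all 2^p coalitions and applies
#' the Shapley formula directly.  Satisfies the efficiency, symmetry and
#' dummy axioms exactly; refuses more than 12 features.
#'
#' @param f prediction function taking a numeric matrix, returning a vector.
#' @param x explicand vector (length p <= 12).
#' @param background matrix of background rows (p columns).
#' @return Numeric vector of p Shapley values.
#' @export
exact_shapley <- function(f, x, background) {
  background <- as.matrix(background)
  p <- length(x)
  if (p > 12) stop("exact enumeration limited to p <= 12 features")
  B <- nrow(background)
  masks <- 0:(2^p - 1)
  inset <- vapply(seq_len(p), function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0,
                  logical(length(masks)))  # 2^p x p

  # evaluate v(S) for every coalition in one batched prediction
  comp <- background[rep(seq_len(B), times = length(masks)), , drop = FALSE]
  for (j in seq_len(p)) {
    rows <- rep(inset[, j], each = B)
    comp[rows, j] <- x[j]
  }
  fv <- f(comp)
  v <- vapply(seq_along(masks), function(k)
    mean(fv[((k - 1) * B + 1):(k * B)]), 0)

  sizes <- rowSums(inset)
  wgt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
               lfactorial(p))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- which(!inset[, j])
    with_j <- without + 2^(j - 1)
    phi[j] <- sum(wgt[sizes[without] + 1] * (v[with_j] - v[without]))
  }
  names(phi) <- names(x)
  phi
}

# Shapley kernel weight for coalition size s out of p features.
shapley_kernel <- function(p, s) (p - 1) / (choose(p, s) * s * (p - s))

# Constrained weighted least squares: given binary design Zm (subsets),
# targets y = v(S) - v0, weights w, and the efficiency constraint
# sum(phi) = delta, return the minimizer (equals exact Shapley values when
# all 2^p - 2 subsets are enumerated).
kernel_solve <- function(Zm, y, w, delta) {
  A <- crossprod(Zm * w, Zm)
  b <- crossprod(Zm * w, y)
  diag(A) <- diag(A) + 1e-10 * max(diag(A))  # numerical guard
  sol <- solve(A, cbind(b, 1))
  lam <- (sum(sol[, 2] * b) - delta) / sum(sol[, 2])
  # phi = A^-1 (b - lam * 1)
  as.numeric(sol[, 1] - lam * sol[, 2])
}

kernel_shap_exact <- function(f, x, background) {
  p <- length(x)
  B <- nrow(background)
  masks <- 1:(2^p - 2)  # all proper nonempty coalitions
  Zm <- vapply(seq_len(p), function(j)
    as.numeric(bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0),
    numeric(length(masks)))
  comp <- background[rep(seq_len(B), times = length(masks)), , drop = FALSE]
  for (j in seq_len(p)) {
    rows <- rep(Zm[, j] > 0, each = B)
    comp[rows, j] <- x[j]
  }
  fv <- f(comp)
  v <- vapply(seq_along(masks), function(k)
    mean(fv[((k - 1) * B + 1):(k * B)]), 0)
  v0 <- mean(f(background))
  fx <- as.numeric(f(matrix(x, 1, dimnames = list(NULL, colnames(background)))))
  s <- rowSums(Zm)
  w <- shapley_kernel(p, s)
  kernel_solve(Zm, v - v0, w, fx - v0)
}

kernel_shap_sampled <- function(f, x, background, nsamples = 2048, seed = 1L) {
  p <- length(x)
  B <- nrow(background)
  with_seed(seed, {
    sizes <- 1:(p - 1)
    size_w <- (p - 1) / (sizes * (p - sizes))
    half <- ceiling(nsamples / 2)
    s_draw <- sample(sizes, half, replace = TRUE, prob = size_w)
    Zm <- matrix(0, 2 * half, p)
    for (i in seq_len(half)) {
      on <- sample(p, s_draw[i])
      Zm[2 * i - 1, on] <- 1
      Zm[2 * i, -on] <- 1  # paired complement for variance reduction
    }
    v <- numeric(nrow(Zm))
    chunk <- max(1, floor(20000 / B))
    for (start in seq(1, nrow(Zm), by = chunk)) {
      ks <- start:min(start + chunk - 1, nrow(Zm))
      comp <- background[rep(seq_len(B), times = length(ks)), , drop = FALSE]
      for (j in seq_len(p)) {
        rows <- rep(Zm[ks, j] > 0, each = B)
        comp[rows, j] <- x[j]
      }
      fv <- f(comp)
      v[ks] <- vapply(seq_along(ks), function(k)
        mean(fv[((k - 1) * B + 1):(k * B)]), 0)
    }
    v0 <- mean(f(background))
    fx <- as.numeric(f(matrix(x, 1, dimnames = list(NULL, colnames(background)))))
    kernel_solve(Zm, v - v0, rep(1, nrow(Zm)), fx - v0)
  })
}

#' Write / read an attribution matrix as CSV + JSON sidecar
#'
#' @param sm a [shap_matrix()].
#' @param path CSV path; a `.json` sidecar with the base value is written
#'   alongside.
#' @return `read_shap_matrix` returns a [shap_matrix()].
#' @export
write_shap_matrix <- function(sm, path) {
  df <- data.frame(record_id = sm$record_ids, sm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(base_value = sm$base_value),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shap_matrix
#' @export
read_shap_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::fromJSON(sub("\\.csv$", ".json", path))
  shap_matrix(as.matrix(df[, -1, drop = FALSE]), base_value = side$base_value,
              record_ids = df$record_id,
              feature_names = colnames(df)[-1])
}
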