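MODEL_FAMILIES <- c("random_forest", "svm", "logistic_regression", "mlp")

#' Train a reduced-LVEF classifier on an ECG-parameter table
#'
#' Fits one of four model families to the binary reduced-LVEF label:
#' a random forest (fitted as a regression forest on the 0/1 label, so its
#' output is an average of leaf class frequencies — a probability machine),
#' an RBF support vector machine with Platt-calibrated probabilities, an
#' L2-penalized (ridge) logistic regression, or a single-hidden-layer
#' multi-layer perceptron.  Features are standardized internally for the
#' SVM, logistic and MLP fits.
#'
#' @param ds a training [ecg_dataset()].
#' @param family one of `"random_forest"`, `"svm"`, `"logistic_regression"`,
#'   `"mlp"`.
#' @param hyper named list of family hyperparameters.  Random forest:
#'   `ntree` (300), `maxnodes` (64), `mtry`; SVM: `cost` (1), `gamma`;
#'   logistic: `nfolds` (5); MLP: `size` (64), `decay` (1e-3), `maxit` (150).
#' @param balanced if `TRUE`, reweight classes inversely to frequency
#'   (SVM/logistic/MLP) or stratify the forest's bootstrap.
#' @param seed integer seed; fits are deterministic given it.
#' @return An object of class `ecg_model`.
#' @export
fit_lvef_model <- function(ds, family = "random_forest", hyper = list(),
                           balanced = FALSE, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  x <- ds$params
  y <- ds$reduced
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  w <- if (balanced) ifelse(y, 0.5 / mean(y), 0.5 / mean(!y)) else rep(1, length(y))

  fit <- with_seed(seed, switch(family,
    random_forest = {
      if (balanced) {
        nmin <- min(table(y))
        randomForest::randomForest(
          x, factor(y, levels = c(FALSE, TRUE)),
          ntree = hyper$ntree %||% 300, maxnodes = hyper$maxnodes %||% 64,
          mtry = hyper$mtry %||% max(floor(ncol(x) / 3), 1),
          sampsize = c(nmin, nmin), strata = factor(y))
      } else {
        # regression forest on the 0/1 label: leaf class frequencies
        suppressWarnings(randomForest::randomForest(
          x, as.numeric(y),
          ntree = hyper$ntree %||% 300, maxnodes = hyper$maxnodes %||% 64,
          mtry = hyper$mtry %||% max(floor(ncol(x) / 3), 1)))
      }
    },
    svm = e1071::svm(xs, factor(y, levels = c(FALSE, TRUE)),
                     kernel = "radial", probability = TRUE,
                     cost = hyper$cost %||% 1,
                     gamma = hyper$gamma %||% (1 / ncol(x)),
                     class.weights = if (balanced)
                       c("FALSE" = 0.5 / mean(!y), "TRUE" = 0.5 / mean(y))),
    logistic_regression = {
      nfolds <- hyper$nfolds %||% 5
      foldid <- sample(rep_len(seq_len(nfolds), length(y)))
      glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 0,
                        weights = w, foldid = foldid)
    },
    mlp = nnet::nnet(xs, as.numeric(y), size = hyper$size %||% 64,
                     decay = hyper$decay %||% 1e-3,
                     maxit = hyper$maxit %||% 150,
                     entropy = TRUE, weights = w,
                     MaxNWts = 100000, trace = FALSE)))

  structure(list(family = family, fit = fit, center = ctr, scale = scl,
                 feature_names = colnames(x), seed = seed,
                 hyper = hyper, balanced = balanced),
            class = c(paste0("ecg_model_", family), "ecg_model"))
}

#' @export
print.ecg_model <- function(x, ...) {
  cat(sprintf("<ecg_model> family = %s, %d features\n",
              x$family, length(x$feature_names)))
  invisible(x)
}

model_matrix <- function(m, records) {
  x <- if (inherits(records, "ecg_dataset")) records$params else as.matrix(records)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(m$feature_names))
      stop("records have ", ncol(x), " features; model expects ",
           length(m$feature_names))
    colnames(x) <- m$feature_names
  }
  if (!all(m$feature_names %in% colnames(x)))
    stop("records lack model feature(s): ",
         paste(head(setdiff(m$feature_names, colnames(x)), 5), collapse = ", "))
  extra <- setdiff(colnames(x), m$feature_names)
  if (length(extra))
    stop("records carry feature(s) unknown to the model: ",
         paste(head(extra, 5), collapse = ", "))
  x[, m$feature_names, drop = FALSE]
}

#' Predicted probability of reduced LVEF
#'
#' @param m an `ecg_model`.
#' @param records an [ecg_dataset()] or numeric matrix with the model's
#'   feature columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(m, records) {
  stopifnot(inherits(m, "ecg_model"))
  x <- model_matrix(m, records)
  xs <- scale(x, center = m$center, scale = m$scale)
  p <- switch(m$family,
    random_forest = {
      pr <- predict(m$fit, x,
                    type = if (m$fit$type == "regression") "response" else "prob")
      if (is.matrix(pr)) pr[, "TRUE"] else as.numeric(pr)
    },
    svm = {
      pr <- predict(m$fit, xs, probability = TRUE)
      attr(pr, "probabilities")[, "TRUE"]
    },
    logistic_regression =
      as.numeric(predict(m$fit, xs, s = "lambda.min", type = "response")),
    mlp = as.numeric(predict(m$fit, xs)))
  unname(pmin(pmax(p, 0), 1))
}

#' Binary call at a probability cut-off
#'
#' A record is called reduced-LVEF when its predicted probability strictly
#' exceeds the cut-off (a probability exactly at the cut-off is negative).
#'
#' @param probs numeric vector in \[0, 1\].
#' @param cutoff decision threshold, default 0.5.
#' @return Logical vector.
#' @export
classify <- function(probs, cutoff = 0.5) {
  stopifnot(all(probs >= 0 & probs <= 1))
  probs > cutoff
}
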