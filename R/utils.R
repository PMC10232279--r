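#' @useDynLib ecgxai, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median prcomp predict pchisq pnorm quantile rbinom rnorm
#'   runif sd var kmeans qnorm rpois cov
#' @importFrom utils read.csv write.csv head
#' @importFrom tools md5sum
#' @importFrom randomForest randomForest getTree
#' @importFrom e1071 svm
#' @importFrom glmnet cv.glmnet
#' @importFrom nnet nnet
#' @importFrom uwot umap umap_transform
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage label, keeping the result
# inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Population standard deviation (divisor n)
#'
#' Summary tables of per-reader metrics in multi-reader studies are
#' conventionally reported with the population SD (divisor `n`), not the
#' sample SD; this helper makes that convention explicit.
#'
#' @param x numeric vector.
#' @return The population standard deviation of `x`.
#' @export
pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to compare recovered attribution-space clusters with planted
#' phenotype truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Adjusted Rand index in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
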