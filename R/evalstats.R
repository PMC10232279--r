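#' Accuracy, sensitivity and specificity of binary calls
#'
#' @param calls logical vector of positive calls.
#' @param truth logical vector of true labels.
#' @param percent report as percentages (default) or unit-interval values.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`;
#'   sensitivity/specificity are `NA` (with a warning) when the truth lacks
#'   the corresponding class.
#' @export
confusion_metrics <- function(calls, truth, percent = TRUE) {
  stopifnot(length(calls) == length(truth))
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth); fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth); fp <- sum(calls & !truth)
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { warning("no positives in truth; sensitivity undefined"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { warning("no negatives in truth; specificity undefined"); NA_real_ }
  out <- c(accuracy = acc, sensitivity = sens, specificity = spec)
  if (percent) out * 100 else out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUROC with midrank tie correction: equals the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.
#'
#' @param scores numeric scores.
#' @param truth logical labels (both classes required).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement `B` times and returns the
#' percentile interval of `statistic` over the replicates.  Replicates on
#' which the statistic is undefined (e.g. a single-class resample of
#' sensitivity) are redrawn, and the redraw count is reported.
#'
#' @param statistic function of a data frame returning one number.
#' @param data a data frame (rows are resampling units).
#' @param B number of bootstrap replicates (>= 100; 10000 by convention).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is deterministic given it.
#' @return Numeric `c(low, high)` with attributes `point`, `B`, `redraws`.
#' @export
bootstrap_ci <- function(statistic, data, B = 10000, level = 0.95,
                         seed = 1L) {
  stopifnot(B >= 100)
  data <- as.data.frame(data)
  n <- nrow(data)
  with_seed(seed, {
    reps <- numeric(B); redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        v <- suppressWarnings(statistic(data[sample(n, n, replace = TRUE), ,
                                             drop = FALSE]))
        if (is.finite(v)) break
        redraws <- redraws + 1L
        if (redraws > 10 * B) stop("statistic undefined on nearly all resamples")
      }
      reps[b] <- v
    }
    ci <- unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                                 type = 7))
    structure(ci, point = statistic(data), B = B, redraws = redraws)
  })
}

reader_correct <- function(rs, phase = c("before", "after")) {
  phase <- match.arg(phase)
  d <- rs$data
  call <- if (phase == "before") d$call_before else d$call_after
  data.frame(reader_id = d$reader_id, correct = call == d$truth,
             truth = d$truth, call = call, stringsAsFactors = FALSE)
}

#' Clustered paired-proportions (Obuchowski) test
#'
#' Compares paired correct/incorrect calls (before vs after an
#' intervention) when observations are sampled in clusters — here, each
#' reader's set of ECG reads.  Per cluster the discordance counts are
#' `b_k` (correct before, wrong after) and `c_k` (wrong before, correct
#' after); the paired-proportion difference is tested with a
#' cluster-robust variance estimate on 1 df, which reduces to the
#' classical McNemar setting when clusters hold one observation each.
#'
#' With few clusters the statistic is (under the null) a squared t with
#' `M - 1` degrees of freedom, so the default reference is F(1, M-1), which
#' keeps the test calibrated at reader-study sizes; the large-sample
#' chi-square(1) tail is available via `ref = "chisq"`.
#'
#' @param rs a [reader_study()].
#' @param ref `"f"` (default, small-sample calibrated) or `"chisq"`
#'   (asymptotic in the number of clusters).
#' @return A `clustered_test` list: `statistic`, `df`, `p_value`, per-
#'   cluster `b_k`, `c_k`, the correctness difference `diff`, and a
#'   `no_discordance` flag.
#' @export
obuchowski_test <- function(rs, ref = c("f", "chisq")) {
  ref <- match.arg(ref)
  before <- reader_correct(rs, "before")
  after <- reader_correct(rs, "after")
  stopifnot(identical(before$reader_id, after$reader_id))
  readers <- unique(before$reader_id)
  if (length(readers) < 2) stop("need at least 2 clusters (readers)")
  b_k <- c_k <- n_k <- numeric(length(readers))
  for (i in seq_along(readers)) {
    sel <- before$reader_id == readers[i]
    b_k[i] <- sum(before$correct[sel] & !after$correct[sel])
    c_k[i] <- sum(!before$correct[sel] & after$correct[sel])
    n_k[i] <- sum(sel)
  }
  res <- clustered_chisq(b_k, c_k, n_k, ref = ref)
  structure(c(res, list(b_k = b_k, c_k = c_k, readers = readers, ref = ref,
                        no_discordance = all(b_k == 0 & c_k == 0))),
            class = "clustered_test")
}

# Cluster-robust statistic for the paired-proportion difference.
clustered_chisq <- function(b_k, c_k, n_k, ref = "f") {
  M <- length(b_k); N <- sum(n_k)
  x_k <- c_k - b_k
  dhat <- sum(x_k) / N
  v <- M / ((M - 1) * N^2) * sum((x_k - n_k * dhat)^2)
  if (v == 0) {
    stat <- if (dhat == 0) 0 else Inf
  } else stat <- dhat^2 / v
  p <- if (ref == "chisq") stats::pchisq(stat, 1, lower.tail = FALSE)
       else stats::pf(stat, 1, M - 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, diff = dhat, p_value = p)
}

#' @export
print.clustered_test <- function(x, ...) {
  cat(sprintf("Clustered paired-proportions test: X^2 = %.3f, df = 1, p = %.4f\n",
              x$statistic, x$p_value))
  cat(sprintf("  correctness difference (after - before): %+.3f over %d clusters\n",
              x$diff, length(x$b_k)))
  if (x$no_discordance) cat("  note: no discordant pairs\n")
  invisible(x)
}

#' Within-cluster permutation test (oracle for the clustered test)
#'
#' Exchanges the before/after phases within whole clusters (sign flips of
#' the per-cluster discordance difference).  For up to 14 clusters all
#' 2^M flips are enumerated, giving an exact reference distribution for
#' the clustered statistic.
#'
#' @param rs a [reader_study()].
#' @param n_perm Monte-Carlo permutations when exact enumeration is too
#'   large.
#' @param seed integer seed for the Monte-Carlo branch.
#' @return List `p_value`, `statistic`, `exact`.
#' @export
obuchowski_permutation <- function(rs, n_perm = 10000, seed = 1L) {
  ob <- obuchowski_test(rs)
  b_k <- ob$b_k; c_k <- ob$c_k
  n_k <- vapply(ob$readers, function(r)
    sum(rs$data$reader_id == r), 0)
  M <- length(b_k)
  stat_for <- function(signs) {
    bb <- ifelse(signs > 0, b_k, c_k)
    cc <- ifelse(signs > 0, c_k, b_k)
    clustered_chisq(bb, cc, n_k, ref = ob$ref)$statistic
  }
  obs <- ob$statistic
  if (M <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), M)))
    stats <- apply(signs, 1, stat_for)
    p <- mean(stats >= obs - 1e-12)
    exact <- TRUE
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      stat_for(sample(c(1, -1), M, replace = TRUE)), 0))
    p <- (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
    exact <- FALSE
  }
  list(p_value = p, statistic = obs, exact = exact)
}

#' Per-reader diagnostic metrics with mean and population SD
#'
#' Summarizes a reader study phase the way multi-reader tables are
#' printed: per-reader accuracy/sensitivity/specificity in percent, plus
#' their mean and population SD (divisor = number of readers), rounded to
#' one decimal.
#'
#' @param rs a [reader_study()].
#' @param phase `"before"` or `"after"`.
#' @return List: `table` (per-reader data frame), `mean`, `sd` (named
#'   vectors over the three metrics).
#' @export
reader_summary <- function(rs, phase = c("before", "after")) {
  phase <- match.arg(phase)
  d <- reader_correct(rs, phase)
  readers <- unique(d$reader_id)
  tab <- do.call(rbind, lapply(readers, function(r) {
    sel <- d$reader_id == r
    m <- confusion_metrics(d$call[sel], d$truth[sel])
    data.frame(reader_id = r, accuracy = m["accuracy"],
               sensitivity = m["sensitivity"],
               specificity = m["specificity"], row.names = NULL)
  }))
  mets <- c("accuracy", "sensitivity", "specificity")
  list(table = tab,
       mean = round(vapply(tab[mets], mean, 0), 1),
       sd = round(vapply(tab[mets], pop_sd, 0), 1))
}

#' Diagnostic performance report with bootstrap confidence intervals
#'
#' @param probs predicted probabilities.
#' @param truth logical labels.
#' @param cutoff decision threshold for the binary metrics.
#' @param B bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @return Data frame with point estimates and percentile 95% CIs for
#'   accuracy, sensitivity, specificity (percent) and AUROC.
#' @export
metric_report <- function(probs, truth, cutoff = 0.5, B = 10000, seed = 1L) {
  df <- data.frame(p = probs, y = as.logical(truth))
  stats_list <- list(
    accuracy = function(d) confusion_metrics(classify(d$p, cutoff), d$y)["accuracy"],
    sensitivity = function(d) confusion_metrics(classify(d$p, cutoff), d$y)["sensitivity"],
    specificity = function(d) confusion_metrics(classify(d$p, cutoff), d$y)["specificity"],
    auroc = function(d) if (length(unique(d$y)) < 2) NA_real_ else auroc(d$p, d$y))
  rows <- lapply(names(stats_list), function(nm) {
    ci <- bootstrap_ci(stats_list[[nm]], df, B = B,
                       seed = derive_seed(seed, nm))
    data.frame(metric = nm, estimate = attr(ci, "point"),
               ci_low = ci[1], ci_high = ci[2], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "B") <- B
  out
}
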