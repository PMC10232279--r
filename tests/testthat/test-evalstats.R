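test_that("confusion metrics reproduce a reconstructed reading-test row", {
  calls <- rep(c(TRUE, FALSE, FALSE, TRUE), c(26, 24, 36, 14))
  truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(26, 24, 36, 14))
  m <- confusion_metrics(calls, truth)
  expect_equal(unname(m), c(62, 52, 72))
  expect_equal(unname(confusion_metrics(truth, truth)), c(100, 100, 100))
  expect_warning(confusion_metrics(c(TRUE, FALSE), c(TRUE, TRUE)),
                 "specificity")
  # random calls against random truth: accuracy ~ 50%
  set.seed(2)
  acc <- confusion_metrics(runif(20000) < 0.5, runif(20000) < 0.5)["accuracy"]
  expect_lt(abs(acc - 50), 2)
})

test_that("AUROC matches the exhaustive pairwise oracle and pROC", {
  pairwise_auc <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(3)
  for (i in 1:6) {
    s <- round(rnorm(50), 1)           # rounding forces ties
    y <- runif(50) < 0.4
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), pairwise_auc(s, y), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  s <- rnorm(120); y <- runif(120) < 0.3
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUROC respects its boundary and invariance properties", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(4)
  s <- rnorm(80); y <- runif(80) < 0.5
  expect_equal(auroc(s, y), auroc(exp(s), y))        # monotone transform
  expect_equal(auroc(s, y), auroc(rank(s), y))
})

test_that("percentile bootstrap is deterministic with sane edge behavior", {
  df <- data.frame(x = rep(5, 30))
  ci <- bootstrap_ci(function(d) mean(d$x), df, B = 200, seed = 1)
  expect_equal(unname(ci[1]), unname(ci[2]))         # zero width

  df2 <- data.frame(x = rnorm(40))
  c1 <- bootstrap_ci(function(d) mean(d$x), df2, B = 300, seed = 9)
  c2 <- bootstrap_ci(function(d) mean(d$x), df2, B = 300, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1[1], attr(c1, "point"))
  expect_gte(c1[2], attr(c1, "point"))
  expect_error(bootstrap_ci(function(d) mean(d$x), df2, B = 50), "B >= 100")
})

test_that("the clustered test handles balanced and degenerate discordance", {
  # b_k == c_k for every reader: statistic 0, p = 1
  rs <- exact_reader_study(sens_before = c(60, 70), spec_before = c(80, 90),
                           sens_after = c(60, 70), spec_after = c(80, 90))
  # identical phases: no discordance at all
  ob <- obuchowski_test(rs)
  expect_equal(ob$statistic, 0)
  expect_equal(ob$p_value, 1)
  expect_true(ob$no_discordance)
  expect_error(obuchowski_test(reader_study(
    rs$data[rs$data$reader_id == "reader01", ])), "2 clusters")
})

test_that("the clustered test is invariant to relabeling and reordering", {
  rs <- simulate_reader_study(reader_study_config(seed = 77))
  base <- obuchowski_test(rs)

  d <- rs$data
  d$reader_id <- factor(d$reader_id,
                        labels = rev(sort(unique(d$reader_id))))
  d$reader_id <- as.character(d$reader_id)
  relabeled <- obuchowski_test(reader_study(d))
  expect_equal(relabeled$statistic, base$statistic)
  expect_equal(relabeled$p_value, base$p_value)

  set.seed(1)
  d2 <- rs$data[sample(nrow(rs$data)), ]
  reordered <- obuchowski_test(reader_study(d2))
  expect_equal(reordered$statistic, base$statistic)
})

test_that("one observation per cluster recovers McNemar-like decisions", {
  one_pair_study <- function(b, c, n_conc) {
    M <- b + c + n_conc
    correct_b <- rep(c(TRUE, FALSE, TRUE), c(b, c, n_conc))
    correct_a <- rep(c(FALSE, TRUE, TRUE), c(b, c, n_conc))
    truth <- rep(TRUE, M)
    reader_study(data.frame(
      reader_id = sprintf("r%03d", seq_len(M)), ecg_id = "e1",
      truth = truth, call_before = ifelse(correct_b, truth, !truth),
      call_after = ifelse(correct_a, truth, !truth)))
  }
  for (cfg in list(c(18, 3, 30), c(10, 9, 40), c(25, 5, 10), c(4, 3, 60))) {
    rs <- one_pair_study(cfg[1], cfg[2], cfg[3])
    ours <- obuchowski_test(rs, ref = "chisq")
    mcn <- stats::mcnemar.test(matrix(c(cfg[3], cfg[1], cfg[2], 0), 2),
                               correct = FALSE)
    expect_equal(ours$p_value < 0.05, mcn$p.value < 0.05,
                 info = paste(cfg, collapse = "/"))
  }
})

test_that("reader summaries use the population-SD convention", {
  v <- table4_values()
  rs <- table4_study()
  before <- reader_summary(rs, "before")
  after <- reader_summary(rs, "after")
  expect_equal(before$table$accuracy, v$acc_before)
  expect_equal(unname(before$mean), c(62.9, 37.4, 88.3))
  expect_equal(unname(before$sd), c(3.9, 9.3, 7.1))
  expect_equal(unname(after$mean), c(73.9, 71.1, 76.6))
  expect_equal(unname(after$sd), c(2.4, 8.1, 8.8))
  # a single reader has SD zero by the population convention
  solo <- reader_study(rs$data[rs$data$reader_id == "reader01", ])
  expect_equal(unname(reader_summary(solo, "before")$sd), c(0, 0, 0))
})

test_that("metric reports carry bootstrap intervals around the estimates", {
  set.seed(12)
  y <- runif(300) < 0.3
  p <- plogis(qlogis(0.3) + 2 * y + rnorm(300, 0, 1.2))
  rep <- metric_report(p, y, B = 200, seed = 4)
  expect_setequal(rep$metric,
                  c("accuracy", "sensitivity", "specificity", "auroc"))
  expect_true(all(rep$ci_low <= rep$estimate + 1e-9))
  expect_true(all(rep$ci_high >= rep$estimate - 1e-9))
})
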