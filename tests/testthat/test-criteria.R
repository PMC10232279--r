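# Build a shap_matrix whose per-parameter medians are exactly `med` for a
# single cluster (three identical rows make the median trivial).
shap_with_medians <- function(med, names = paste0("f", seq_along(med))) {
  shap_matrix(matrix(rep(med, each = 3), 3, length(med),
                     dimnames = list(NULL, names)), base_value = 0)
}

test_that("the mean + SD threshold picks exactly the dominant parameters", {
  # medians {0.5, 0.1, 0.0}: mean 0.2, population SD 0.21602,
  # threshold 0.41602 -> only the first parameter qualifies
  sm <- shap_with_medians(c(0.5, 0.1, 0.0))
  fac <- decision_factors(sm, rep(1L, 3))
  expect_equal(fac$parameter, "f1")
  expect_equal(fac$threshold[1], 0.2 + sqrt(mean((c(.5, .1, 0) - .2)^2)))
  expect_equal(fac$threshold[1], 0.4160247, tolerance = 1e-6)

  # all medians equal: SD 0, strict inequality -> empty factor set
  fac0 <- decision_factors(shap_with_medians(rep(0.3, 5)), rep(1L, 3))
  expect_equal(nrow(fac0), 0)
})

test_that("factor extraction matches a naive independent recomputation", {
  naive_factors <- function(values, labels) {
    out <- NULL
    for (k in sort(unique(labels))) {
      block <- values[labels == k, , drop = FALSE]
      med <- numeric(ncol(block))
      for (j in seq_len(ncol(block))) {          # sort-based median
        s <- sort(block[, j]); n <- length(s)
        med[j] <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
      }
      mu <- sum(med) / length(med)               # two-pass population SD
      sdv <- sqrt(sum((med - mu)^2) / length(med))
      hit <- which(med > mu + sdv)
      if (length(hit))
        out <- rbind(out, data.frame(cluster = k,
                                     parameter = colnames(values)[hit[order(-med[hit])]],
                                     median_shap = sort(med[hit], decreasing = TRUE)))
    }
    out
  }
  set.seed(21)
  for (rep in 1:5) {
    n <- 30; p <- 12
    vals <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    labels <- sample(1:3, n, replace = TRUE)
    sm <- shap_matrix(vals, base_value = 0)
    got <- decision_factors(sm, labels)
    want <- naive_factors(vals, labels)
    expect_equal(got$parameter, want$parameter)
    expect_equal(got$median_shap, want$median_shap, tolerance = 1e-12)
  }
})

# A cluster-1-style configuration: T amplitudes negative in I/aVR/V5-6,
# R amplitudes low in II/V4-5, S duration high in V3, age elevated.
cluster1_fixture <- function() {
  sch <- ecg_schema()
  factors <- data.frame(
    cluster = 1L,
    parameter = c("T_amp_I", "T_amp_aVR", "T_amp_V5", "T_amp_V6",
                  "R_amp_II", "R_amp_V4", "R_amp_V5", "age", "S_dur_V3"),
    median_shap = seq(0.9, 0.1, length.out = 9), threshold = 0.05,
    stringsAsFactors = FALSE)
  set.seed(5)
  ref <- matrix(rnorm(400 * nrow(sch)), 400, nrow(sch),
                dimnames = list(NULL, sch$name))
  prof <- ecgxai:::baseline_profile(sch)
  ref <- sweep(sweep(ref, 2, prof$sd, "*"), 2, prof$mean, "+")
  vals <- ref[1:40, ]
  shift <- function(par, k) vals[, par] <<- vals[, par] + k * prof$sd[par]
  for (par in factors$parameter[1:4]) shift(par, -2)
  for (par in factors$parameter[5:7]) shift(par, -2)
  shift("age", 1.5); shift("S_dur_V3", 2)
  list(factors = factors, vals = vals, ref = ref, sch = sch)
}

test_that("factors translate to signed findings with aVR and age dropped", {
  fx <- cluster1_fixture()
  cr <- interpret_criteria(fx$factors, fx$vals, rep(1L, 40), fx$ref, fx$sch)
  expect_setequal(cr$finding, c("negative T-wave inversion", "low voltage",
                                "S-wave prolongation"))
  expect_equal(cr$leads[cr$finding == "negative T-wave inversion"],
               "I/V5/V6")                        # aVR yields no finding
  expect_equal(cr$leads[cr$finding == "low voltage"], "II/V4/V5")
  expect_equal(cr$leads[cr$finding == "S-wave prolongation"], "V3")
  # the age factor yields no criterion row at all
  expect_equal(nrow(cr), 3)

  # no direction, no criterion: cluster values equal to the reference
  flat <- interpret_criteria(fx$factors[1, , drop = FALSE],
                             fx$ref, rep(1L, nrow(fx$ref)), fx$ref, fx$sch)
  expect_equal(nrow(flat), 0)

  expect_error(interpret_criteria(
    data.frame(cluster = 1, parameter = "nope", median_shap = 1,
               threshold = 0), fx$vals, rep(1L, 40), fx$ref, fx$sch),
    "unknown")
})

test_that("criteria map onto the six canonical categories", {
  mk <- function(cluster, finding, leads)
    data.frame(cluster = cluster, finding = finding, leads = leads,
               direction = "high", stringsAsFactors = FALSE)
  # cluster-3-style: broad low voltage + Q waves
  c3 <- rbind(mk(3, "low voltage", "I/II/V4/V5/V6"), mk(3, "Q wave", "V4/V5/V6"))
  expect_setequal(categorize_criteria(c3)[["3"]],
                  c("LOW_VOLTAGE_I_II_V46", "Q_WAVE_V36"))

  # cluster-2-style: single-lead low voltage V4 stays outside the category,
  # single-lead S prolongation V3 counts (two-lead canonical group)
  c2 <- rbind(mk(2, "negative T-wave inversion", "I/II/V5/V6"),
              mk(2, "VAT prolongation", "V5/V6"),
              mk(2, "low voltage", "V4"),
              mk(2, "QTc prolongation", "V1/V2/V3"),
              mk(2, "S-wave prolongation", "V3"))
  got <- categorize_criteria(c2)
  expect_setequal(got[["2"]],
                  c("NEG_T_INVERSION_I_V56", "VAT_PROLONG_I_V56",
                    "S_PROLONG_V23", "QTC_PROLONG"))
  expect_match(attr(got, "outside")[["2"]], "low voltage")
  expect_equal(attr(got, "supergroup")[["2"]],
               "intraventricular conduction delay")

  # empty in, empty out; order independence
  expect_length(categorize_criteria(c2[0, ]), 0)
  shuffled <- categorize_criteria(c2[c(4, 1, 5, 3, 2), ])
  expect_identical(got[["2"]], shuffled[["2"]])

  # an unknown finding is reported, never silently dropped
  odd <- categorize_criteria(mk(1, "delta wave", "V1"))
  expect_length(odd[["1"]], 0)
  expect_match(attr(odd, "outside")[["1"]], "delta wave")
})
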