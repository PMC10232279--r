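test_that("generation is deterministic and keeps truth separate", {
  cfg <- generator_config(n_patients = 300, seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$dataset$params, b$dataset$params)
  expect_identical(a$dataset$lvef, b$dataset$lvef)
  expect_identical(a$truth, b$truth)
  # truth is a sidecar, not a dataset field
  expect_false("phenotype" %in% names(a$dataset))
  expect_setequal(names(a), c("dataset", "truth"))
})

test_that("unknown phenotype parameters are rejected", {
  ph <- phenotype_spec("bad", c(NOT_A_PARAM = 2), 30, 5, 0.05)
  expect_error(simulate_population(generator_config(n_patients = 50, seed = 1),
                                   list(ph)), "NOT_A_PARAM")
})

test_that("degenerate mixtures behave as their closed forms dictate", {
  # all weight on the healthy class: prevalence converges to
  # P(LVEF < 40 | healthy) = pnorm((40-62)/10) ~ 1.4%
  cfg <- generator_config(n_patients = 4000, seed = 5)
  sim <- simulate_population(cfg, phenotypes = list())
  expect_lt(abs(mean(sim$dataset$reduced) - pnorm((40 - 62) / 10)), 0.01)
  expect_true(all(sim$truth$phenotype == "healthy"))

  # zero noise and a single phenotype: affected parameters are identical
  # across that phenotype's records
  ph <- phenotype_spec("only", c(T_amp_V5 = -2, VAT_V6 = 2), 30, 5, 1)
  cfg0 <- generator_config(n_patients = 60, noise_sd = 0,
                           paced_fraction = 0, seed = 2)
  sim0 <- simulate_population(cfg0, list(ph))
  expect_equal(var(sim0$dataset$params[, "T_amp_V5"]), 0)
  expect_equal(var(sim0$dataset$params[, "VAT_V6"]), 0)
})

test_that("per-class parameter means converge to their configured values", {
  cfg <- generator_config(n_patients = 5000, seed = 31)
  phen <- default_phenotypes()
  sim <- simulate_population(cfg, phen)
  prof <- ecgxai:::baseline_profile(ecg_schema())
  truth_by_rec <- sim$truth$phenotype
  n_healthy <- sum(truth_by_rec == "healthy")
  unpaced <- !sim$dataset$paced
  # healthy-class mean of an unshifted parameter: within 3 SE of baseline
  for (par in c("T_amp_V5", "QRS_duration", "R_amp_I")) {
    sel <- truth_by_rec == "healthy" & unpaced
    se <- prof$sd[par] / sqrt(sum(sel))
    expect_lt(abs(mean(sim$dataset$params[sel, par]) - prof$mean[par]), 3.5 * se)
  }
  # a planted shift lands at baseline + shift * sd
  ph <- phen[[1]]  # lateral_tinv_lowvolt: T_amp_V5 at -2.5 SD
  sel <- truth_by_rec == ph$name & unpaced
  target <- prof$mean["T_amp_V5"] + ph$shifts["T_amp_V5"] * prof$sd["T_amp_V5"]
  se <- prof$sd["T_amp_V5"] / sqrt(sum(sel))
  expect_lt(abs(mean(sim$dataset$params[sel, "T_amp_V5"]) - target), 3.5 * se)
  # realized prevalence lands near the 9.2% design target
  expect_lt(abs(prevalence(sim$dataset) - 9.2), 2)
})

test_that("reader-study simulation honors its marginals and correlation", {
  # perfectly correlated null: before and after reads identical
  cfg1 <- reader_study_config(n_readers = 3, n_ecgs = 40,
                              sens_before = 0.7, spec_before = 0.8,
                              sens_after = 0.7, spec_after = 0.8,
                              within_reader_correlation = 1, seed = 3)
  rs1 <- simulate_reader_study(cfg1)
  expect_identical(rs1$data$call_before, rs1$data$call_after)

  # marginal correctness rate equals sens*prev + spec*(1-prev)
  cfg2 <- reader_study_config(n_readers = 1, n_ecgs = 10000,
                              positive_fraction = 0.3,
                              sens_before = 0.6, spec_before = 0.9,
                              sens_after = 0.6, spec_after = 0.9,
                              within_reader_correlation = 0.4, seed = 4)
  rs2 <- simulate_reader_study(cfg2)
  correct <- with(rs2$data, call_before == truth)
  expected <- 0.6 * 0.3 + 0.9 * 0.7
  expect_lt(abs(mean(correct) - expected),
            3 * sqrt(expected * (1 - expected) / 10000))

  expect_identical(simulate_reader_study(cfg2)$data, rs2$data)
})

test_that("reader studies at the printed operating points land near the printed means", {
  accs <- vapply(1:60, function(s) {
    rs <- simulate_reader_study(reader_study_config(seed = s))
    c(reader_summary(rs, "before")$mean[["accuracy"]],
      reader_summary(rs, "after")$mean[["accuracy"]])
  }, c(0, 0))
  expect_lt(abs(mean(accs[1, ]) - 62.9), 1)
  expect_lt(abs(mean(accs[2, ]) - 73.9), 1)
})
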