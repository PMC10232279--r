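make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

toy_table <- function(sch = ecg_schema(), lvef = c(62, 35, 55)) {
  vals <- matrix(seq_len(3 * nrow(sch)) / 7, 3, nrow(sch),
                 dimnames = list(NULL, sch$name))
  data.frame(record_id = c("a", "b", "c"), patient_id = c("p1", "p1", "p2"),
             lvef = lvef, paced = c(FALSE, TRUE, FALSE),
             vals, check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("loading applies the 40% LVEF threshold and validates columns", {
  sch <- ecg_schema()
  ds <- read_ecg_dataset(make_csv(toy_table(sch)), sch)
  expect_equal(ds$reduced, c(FALSE, TRUE, FALSE))
  expect_equal(ds$paced, c(FALSE, TRUE, FALSE))

  broken <- toy_table(sch)
  broken$VAT_V5 <- NULL
  expect_error(read_ecg_dataset(make_csv(broken), sch), "VAT_V5")

  bad_lvef <- toy_table(sch, lvef = c(62, 135, 55))
  expect_error(read_ecg_dataset(make_csv(bad_lvef), sch), "lvef")
})

test_that("write/load round-trip is bit-exact and order-insensitive", {
  sch <- ecg_schema()
  ds <- read_ecg_dataset(make_csv(toy_table(sch)), sch)
  f <- tempfile(fileext = ".csv")
  write_ecg_dataset(ds, f)
  back <- read_ecg_dataset(f, sch)
  expect_identical(back$params, ds$params)
  expect_identical(back$lvef, ds$lvef)

  # permuting input columns must not change the loaded vectors
  tab <- toy_table(sch)
  perm <- tab[, sample(ncol(tab))]
  back2 <- read_ecg_dataset(make_csv(perm), sch)
  expect_identical(back2$params, ds$params)
})

test_that("missing cells are rejected unless imputation is requested", {
  sch <- ecg_schema()
  tab <- toy_table(sch)
  tab$VAT_V5[2] <- NA
  expect_error(read_ecg_dataset(make_csv(tab), sch), "missing value")
  ds <- read_ecg_dataset(make_csv(tab), sch, impute = TRUE)
  expect_equal(unname(ds$params[2, "VAT_V5"]),
               median(tab$VAT_V5, na.rm = TRUE))
})

test_that("patient-grouped splits never separate a patient's records", {
  sch <- tiny_schema(4)
  for (seed in 1:8) {
    set.seed(seed + 100)
    n_pat <- sample(20:60, 1)
    recs <- sample(1:5, n_pat, replace = TRUE)
    pid <- rep(sprintf("p%02d", seq_len(n_pat)), recs)
    n <- length(pid)
    ds <- ecg_dataset(matrix(rnorm(n * 4), n, 4,
                             dimnames = list(NULL, sch$name)),
                      lvef = runif(n, 20, 80), patient_id = pid,
                      schema = sch)
    sp <- split_by_patient(ds, 0.33, seed = seed)
    expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
    frac <- length(sp$test) / n
    expect_lt(abs(frac - 0.33), 0.05 + max(recs) / n)
    sp2 <- split_by_patient(ds, 0.33, seed = seed)
    expect_identical(sp2$test$record_id, sp$test$record_id)
  }
  expect_error(split_by_patient(ds[ds$patient_id == "p01"], 0.3, 1),
               "2 patients")
})

test_that("prevalence reproduces printed-count arithmetic", {
  expect_equal(prevalence(rep(c(TRUE, FALSE), c(2764, 29907 - 2764))), 9.2)
  expect_equal(prevalence(rep(c(TRUE, FALSE), c(737, 7196 - 737))), 10.2)
  expect_equal(prevalence(rep(TRUE, 5)), 100.0)
  expect_error(prevalence(logical(0)), "empty")
})
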