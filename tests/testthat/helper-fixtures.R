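# Shared fixtures: built in code at test time, cached per session.

# A minimal schema of p generic global parameters, for tests that need a
# feature table without the full 178-entry ECG vocabulary.
tiny_schema <- function(p, prefix = "f") {
  df <- data.frame(name = paste0(prefix, seq_len(p)), lead = "GLOBAL",
                   kind = "HR", unit = "bpm", stringsAsFactors = FALSE)
  class(df) <- c("ecg_schema", "data.frame")
  df
}

# Linearly separable toy dataset: one informative parameter.
separable_dataset <- function(n = 120, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- X[, 1] > 0
  X[, 1] <- X[, 1] + ifelse(y, 3, -3)  # wide margin
  ecg_dataset(X, lvef = ifelse(y, 30, 60), schema = tiny_schema(p))
}

# Multi-reader study with exact per-reader confusion counts (50 positives /
# 50 negatives per reader), so per-reader sensitivities and specificities
# are hit exactly, not in expectation.
exact_reader_study <- function(sens_before, spec_before, sens_after,
                               spec_after) {
  R <- length(sens_before)
  truth <- rep(c(TRUE, FALSE), each = 50)
  calls_for <- function(sens, spec) {
    tp <- round(sens / 100 * 50); tn <- round(spec / 100 * 50)
    c(rep(c(TRUE, FALSE), c(tp, 50 - tp)),    # positives: TP then FN
      rep(c(FALSE, TRUE), c(tn, 50 - tn)))    # negatives: TN then FP
  }
  rows <- lapply(seq_len(R), function(r)
    data.frame(reader_id = sprintf("reader%02d", r),
               ecg_id = sprintf("ecg%03d", seq_along(truth)),
               truth = truth,
               call_before = calls_for(sens_before[r], spec_before[r]),
               call_after = calls_for(sens_after[r], spec_after[r]),
               stringsAsFactors = FALSE))
  reader_study(do.call(rbind, rows))
}

# The printed seven-cardiologist reading-test table, used as simulation
# input and as the arithmetic fixture for reader summaries.
table4_values <- function() {
  list(acc_before = c(62, 57, 64, 63, 61, 71, 62),
       sens_before = c(52, 26, 36, 36, 34, 50, 28),
       spec_before = c(72, 88, 92, 90, 88, 92, 96),
       acc_after = c(72, 76, 71, 74, 71, 77, 76),
       sens_after = c(66, 70, 84, 60, 64, 74, 80),
       spec_after = c(78, 82, 58, 88, 78, 80, 72))
}

table4_study <- function() {
  v <- table4_values()
  exact_reader_study(v$sens_before, v$spec_before, v$sens_after, v$spec_after)
}

# Default synthetic benchmark (five planted phenotypes, n_patients = 5000),
# computed once per test session and shared across acceptance checks.
benchmark_env <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (!is.null(benchmark_env$res)) return(benchmark_env$res)
  gen_cfg <- generator_config(n_patients = 5000, seed = 1L)
  phen <- default_phenotypes()
  sim <- simulate_population(gen_cfg, phen)
  sp <- split_by_patient(sim$dataset, 0.3, seed = 2L)
  pipe_cfg <- pipeline_config(bootstrap_B = 200, seed = 1L)
  res <- run_lvef_pipeline(sp$train, sp$test, pipe_cfg)
  truth <- sim$truth$phenotype[match(res$cohort$record_id,
                                     sim$truth$record_id)]
  benchmark_env$res <- list(gen_cfg = gen_cfg, phen = phen, sim = sim,
                            split = sp, pipe_cfg = pipe_cfg, pipe = res,
                            cohort_truth = truth)
  benchmark_env$res
}
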