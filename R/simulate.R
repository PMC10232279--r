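# Baseline population profile: per-parameter means and SDs for an adult
# echocardiography-referral population.  Global intervals follow routinely
# reported clinical means (HR 74 bpm, PR 171.5 ms, QRS 105.8 ms, QT 396.9 ms,
# QTc 435 ms); per-lead amplitudes and durations use conventional adult
# 12-lead values.
baseline_kind_profile <- function() {
  list(
    R_amp = c(0.80, 0.40), S_amp = c(0.35, 0.25), Q_amp = c(0.05, 0.05),
    T_amp = c(0.25, 0.15), P_amp = c(0.10, 0.05), ST_level = c(0.00, 0.05),
    R_dur = c(45, 12), S_dur = c(35, 12), Q_dur = c(10, 8),
    P_dur = c(100, 15), T_dur = c(160, 25), VAT = c(35, 10),
    QTc_lead = c(435, 34), RR_lead = c(810, 150),
    HR = c(74.0, 15.4), PR_interval = c(171.5, 43.9),
    QRS_duration = c(105.8, 22.6), QT_interval = c(396.9, 40.0),
    QTc = c(435.0, 34.1), RR_interval = c(810, 150),
    QRS_axis = c(28.1, 45.3), P_axis = c(41.5, 34.8),
    age = c(63.4, 16.9), sex = c(0.565, 0.5))
}

baseline_profile <- function(schema = ecg_schema()) {
  prof <- baseline_kind_profile()
  mu <- vapply(schema$kind, function(k) prof[[k]][1], 0)
  sdv <- vapply(schema$kind, function(k) prof[[k]][2], 0)
  names(mu) <- names(sdv) <- schema$name
  list(mean = mu, sd = sdv)
}

#' Phenotype specification for the synthetic generator
#'
#' A reduced-LVEF phenotype is a named set of parameter shifts (in baseline
#' SD units) together with the LVEF distribution of patients expressing it
#' and its canonical ECG finding categories.
#'
#' @param name phenotype label.
#' @param shifts named numeric vector: schema parameter name -> shift in SDs
#'   (signed).
#' @param lvef_mean,lvef_sd LVEF distribution (percent) for the phenotype.
#' @param weight mixing weight (patients).
#' @param findings character vector of canonical category codes (see
#'   [finding_categories()]).
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(name, shifts, lvef_mean, lvef_sd, weight,
                           findings = character()) {
  stopifnot(is.numeric(shifts), !is.null(names(shifts)),
            all(is.finite(shifts)), weight >= 0)
  structure(list(name = name, shifts = shifts, lvef_mean = lvef_mean,
                 lvef_sd = lvef_sd, weight = weight, findings = findings),
            class = "phenotype_spec")
}

#' Default phenotype panel
#'
#' Five reduced-LVEF phenotypes whose parameter signatures realize the
#' canonical combinations of the six ECG finding categories observed in
#' attribution-space clusters of reduced-LVEF classifiers: lateral T-wave
#' inversion with low lateral voltage, conduction-delay patterns (VAT and
#' S-wave prolongation with QTc prolongation), and anterolateral Q-wave /
#' low-voltage patterns.  Shifts are 1.8-2.2 SD; LVEF means 28-33%.
#' The healthy class keeps the remaining weight with LVEF ~ N(62, 10), so
#' labels are noisy relative to phenotype membership by construction.
#'
#' @param total_weight total mixing weight of the five phenotypes; the
#'   default 0.086 yields ~9.2% overall prevalence of reduced LVEF.
#' @return List of five [phenotype_spec()] objects.
#' @export
default_phenotypes <- function(total_weight = 0.086) {
  w <- total_weight / 5
  # Each phenotype's *dominant* components (largest shifts) are the findings
  # that distinguish it; findings shared across phenotypes enter with smaller
  # shifts or different leads, so the signatures stay identifiable in
  # attribution space while still overlapping clinically.
  list(
    phenotype_spec("lateral_tinv_lowvolt",
      c(T_amp_I = -2.5, T_amp_V5 = -2.5, T_amp_V6 = -2.5,
        R_amp_II = -2.0, R_amp_V4 = -2.0, R_amp_V5 = -2.0,
        S_dur_V3 = 2.0, age = 1.5),
      lvef_mean = 32, lvef_sd = 6, weight = w,
      findings = c("NEG_T_INVERSION_I_V56", "LOW_VOLTAGE_I_II_V46",
                   "S_PROLONG_V23")),
    phenotype_spec("conduction_delay_qtc",
      c(VAT_V5 = 2.8, VAT_V6 = 2.8, S_dur_V3 = 2.5,
        QTc_V1 = 2.2, QTc_V2 = 2.2, QTc_V3 = 2.2,
        T_amp_I = -1.5, T_amp_II = -1.5, T_amp_V5 = -1.5, T_amp_V6 = -1.5,
        R_amp_V4 = -1.5),
      lvef_mean = 30, lvef_sd = 6, weight = w,
      findings = c("NEG_T_INVERSION_I_V56", "VAT_PROLONG_I_V56",
                   "S_PROLONG_V23", "QTC_PROLONG")),
    phenotype_spec("anterolateral_q_lowvolt",
      c(R_amp_I = -2.2, R_amp_II = -2.2, R_amp_V4 = -2.2,
        R_amp_V5 = -2.2, R_amp_V6 = -2.2,
        Q_dur_V4 = 2.5, Q_dur_V5 = 2.5, Q_dur_V6 = 2.5, age = 1.5),
      lvef_mean = 28, lvef_sd = 6, weight = w,
      findings = c("LOW_VOLTAGE_I_II_V46", "Q_WAVE_V36")),
    phenotype_spec("septal_delay_qtc",
      c(QTc_III = 2.5, QTc_aVL = 2.5, QTc_V4 = 2.5, QTc_V5 = 2.5,
        VAT_I = 2.5, VAT_V6 = 2.5, S_dur_V2 = 2.5, S_dur_V3 = 2.2,
        T_amp_I = -1.5, T_amp_V5 = -1.5, T_amp_V6 = -1.5, age = 1.5),
      lvef_mean = 31, lvef_sd = 6, weight = w,
      findings = c("NEG_T_INVERSION_I_V56", "VAT_PROLONG_I_V56",
                   "S_PROLONG_V23", "QTC_PROLONG")),
    phenotype_spec("inferior_q_tinv",
      c(Q_dur_V3 = 2.5, Q_dur_V4 = 2.5, Q_amp_V3 = 2.2,
        R_amp_II = -2.0, R_amp_V4 = -2.0,
        T_amp_I = -1.8, T_amp_II = -1.8, T_amp_V5 = -1.8, T_amp_V6 = -1.8),
      lvef_mean = 33, lvef_sd = 6, weight = w,
      findings = c("NEG_T_INVERSION_I_V56", "LOW_VOLTAGE_I_II_V46",
                   "Q_WAVE_V36")))
}

#' Generator configuration
#'
#' @param n_patients number of patients (>= 2).
#' @param records_per_patient_mean mean ECGs per patient (>= 1); counts are
#'   1 + Poisson(mean - 1).  The default 2 matches the roughly two paired
#'   ECGs per patient seen in echocardiography-referral populations.
#' @param paced_fraction fraction of patients with a paced rhythm.
#' @param noise_sd multiplier on baseline SDs (1 = calibrated baseline).
#' @param correlation within-lead equicorrelation of the record-level noise
#'   component, in \[0, 1).
#' @param patient_effect_share share of parameter variance attributable to a
#'   stable patient-level effect (repeated ECGs of a patient correlate).
#' @param healthy_lvef_mean,healthy_lvef_sd LVEF distribution of the healthy
#'   class (percent).
#' @param seed integer RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 5000, records_per_patient_mean = 2,
                             paced_fraction = 0.05, noise_sd = 1,
                             correlation = 0.3, patient_effect_share = 0.3,
                             healthy_lvef_mean = 62, healthy_lvef_sd = 10,
                             seed = 1L) {
  stopifnot(n_patients >= 2, records_per_patient_mean >= 1,
            paced_fraction >= 0, paced_fraction <= 1,
            correlation >= 0, correlation < 1,
            patient_effect_share >= 0, patient_effect_share < 1)
  structure(as.list(environment()), class = "generator_config")
}

# Paced rhythm: wide ventricular complexes.  Applied on top of any class.
paced_shifts <- function(schema) {
  s <- c(QRS_duration = 2.5)
  for (ld in ECG_LEADS) {
    s[paste0("VAT_", ld)] <- 1.5
    s[paste0("R_dur_", ld)] <- 1.5
  }
  s
}

#' Simulate an ECG-parameter population with planted phenotypes
#'
#' Patients are assigned to the healthy class or one of the phenotypes by
#' the phenotype mixing weights; each patient contributes one or more ECG
#' records.  Parameter values are baseline mean + SD x (patient effect +
#' within-lead equicorrelated record noise), plus the phenotype's planted
#' shifts (and a wide-QRS shift for paced patients).  LVEF is drawn from the
#' class's LVEF distribution and thresholded at 40% for the label, so labels
#' are intentionally noisy relative to phenotype membership.
#'
#' @param cfg a [generator_config()].
#' @param phenotypes list of [phenotype_spec()]; weights plus the implicit
#'   healthy class must total at most 1.
#' @param schema an [ecg_schema()].
#' @return A list: `dataset` (an [ecg_dataset()]) and `truth` (data frame
#'   `record_id`, `phenotype`; kept separate so downstream stages cannot read
#'   it accidentally).
#' @export
simulate_population <- function(cfg = generator_config(),
                                phenotypes = default_phenotypes(),
                                schema = ecg_schema()) {
  prof <- baseline_profile(schema)
  for (ph in phenotypes) {
    unknown <- setdiff(names(ph$shifts), schema$name)
    if (length(unknown))
      stop("phenotype '", ph$name, "' shifts unknown parameter(s): ",
           paste(unknown, collapse = ", "))
  }
  wts <- vapply(phenotypes, `[[`, 0, "weight")
  if (sum(wts) > 1) stop("phenotype weights exceed 1")
  class_names <- c("healthy", vapply(phenotypes, `[[`, "", "name"))
  class_w <- c(1 - sum(wts), wts)

  p <- nrow(schema)
  with_seed(cfg$seed, {
    np <- cfg$n_patients
    pat_class <- sample(class_names, np, replace = TRUE, prob = class_w)
    pat_paced <- runif(np) < cfg$paced_fraction
    pat_sex <- as.numeric(runif(np) < prof$mean["sex"])
    n_rec <- 1L + rpois(np, cfg$records_per_patient_mean - 1)
    n <- sum(n_rec)
    pat_effect <- matrix(rnorm(np * p), np, p)

    rec_pat <- rep(seq_len(np), n_rec)
    # record-level noise with within-lead equicorrelation
    lead_of <- schema$lead
    z <- matrix(rnorm(n * p), n, p)
    if (cfg$correlation > 0) {
      rho <- cfg$correlation
      for (ld in ECG_LEADS) {
        idx <- which(lead_of == ld)
        g <- rnorm(n)
        z[, idx] <- sqrt(rho) * g + sqrt(1 - rho) * z[, idx]
      }
    }
    tau <- cfg$patient_effect_share
    noise <- sqrt(tau) * pat_effect[rec_pat, , drop = FALSE] +
      sqrt(1 - tau) * z

    values <- matrix(rep(prof$mean, each = n), n, p) +
      cfg$noise_sd * matrix(rep(prof$sd, each = n), n, p) * noise
    colnames(values) <- schema$name

    # planted phenotype shifts (patient-class level)
    shift_mat <- class_shift_matrix(class_names, phenotypes, schema, prof)
    cls_idx <- match(pat_class, class_names)[rec_pat]
    values <- values + shift_mat[cls_idx, , drop = FALSE]

    # paced-rhythm shift
    ps <- paced_shifts(schema)
    paced_rec <- pat_paced[rec_pat]
    if (any(paced_rec)) {
      add <- ps * prof$sd[names(ps)]
      values[paced_rec, names(ps)] <-
        values[paced_rec, names(ps)] + rep(add, each = sum(paced_rec))
    }

    # deterministic patient-level fields
    values[, "sex"] <- pat_sex[rec_pat]
    pat_age <- values[, "age"][!duplicated(rec_pat)]
    values[, "age"] <- pat_age[rec_pat]
    values[, "age"] <- pmin(pmax(values[, "age"], 18), 100)

    # LVEF per record, from the class's LVEF distribution
    lvef_mean <- c(cfg$healthy_lvef_mean,
                   vapply(phenotypes, `[[`, 0, "lvef_mean"))
    lvef_sd <- c(cfg$healthy_lvef_sd, vapply(phenotypes, `[[`, 0, "lvef_sd"))
    lvef <- rnorm(n, lvef_mean[cls_idx], lvef_sd[cls_idx])
    lvef <- pmin(pmax(lvef, 1), 90)

    record_id <- sprintf("rec%06d", seq_len(n))
    patient_id <- sprintf("pat%05d", rec_pat)
    ds <- ecg_dataset(values, lvef = lvef, record_id = record_id,
                      patient_id = patient_id, paced = paced_rec,
                      days_to_echo = sample(0:28, n, replace = TRUE),
                      schema = schema)
    truth <- data.frame(record_id = record_id,
                        phenotype = pat_class[rec_pat],
                        stringsAsFactors = FALSE)
    list(dataset = ds, truth = truth)
  })
}

# n_classes x p matrix of additive mean shifts (in measurement units).
class_shift_matrix <- function(class_names, phenotypes, schema, prof) {
  shift_mat <- matrix(0, length(class_names), nrow(schema),
                      dimnames = list(class_names, schema$name))
  for (ph in phenotypes)
    shift_mat[ph$name, names(ph$shifts)] <-
      ph$shifts * prof$sd[names(ph$shifts)]
  shift_mat
}

#' True class posterior of reduced LVEF under the generator
#'
#' Closed-form Bayes score for generated records: the posterior probability
#' that a record's LVEF is below 40%, computed from the generator's own
#' mixture densities (block-equicorrelated Gaussians per lead) and per-class
#' LVEF distributions.  Scoring a test set with this posterior gives a
#' Monte-Carlo estimate of the Bayes-optimal AUROC, the ceiling against
#' which trained classifiers are judged.
#'
#' @param ds an [ecg_dataset()] produced by [simulate_population()].
#' @param cfg,phenotypes,schema the generator configuration used.
#' @return Numeric vector of posterior probabilities, one per record.
#' @export
true_posterior <- function(ds, cfg = generator_config(),
                           phenotypes = default_phenotypes(),
                           schema = ecg_schema()) {
  prof <- baseline_profile(schema)
  class_names <- c("healthy", vapply(phenotypes, `[[`, "", "name"))
  wts <- vapply(phenotypes, `[[`, 0, "weight")
  class_w <- c(1 - sum(wts), wts)
  shift_mat <- class_shift_matrix(class_names, phenotypes, schema, prof)

  # parameters entering the likelihood: everything except sex (identical
  # across classes) and age/days bookkeeping handled as independent normals
  use <- schema$name != "sex"
  rho_eff <- (1 - cfg$patient_effect_share) * cfg$correlation

  n <- nrow(ds$params)
  x <- ds$params
  ps <- paced_shifts(schema)
  loglik <- matrix(0, n, length(class_names))
  for (ci in seq_along(class_names)) {
    mu <- matrix(rep(prof$mean + shift_mat[ci, ], each = n), n, nrow(schema))
    # paced shift is class-independent; condition on the observed flag
    if (any(ds$paced)) {
      add <- ps * prof$sd[names(ps)]
      jdx <- match(names(ps), schema$name)
      mu[ds$paced, jdx] <- mu[ds$paced, jdx] + rep(add, each = sum(ds$paced))
    }
    z <- (x - mu) / rep(cfg$noise_sd * prof$sd, each = n)
    ll <- numeric(n)
    for (ld in c(ECG_LEADS, "GLOBAL")) {
      idx <- which(schema$lead == ld & use)
      m <- length(idx)
      zb <- z[, idx, drop = FALSE]
      if (ld == "GLOBAL" || rho_eff == 0) {
        ll <- ll - 0.5 * rowSums(zb^2)
      } else {
        # equicorrelation R = (1-rho)I + rho J: closed-form inverse/logdet
        s1 <- rowSums(zb^2); s2 <- rowSums(zb)^2
        denom <- 1 - rho_eff + rho_eff * m
        q <- (s1 - rho_eff * s2 / denom) / (1 - rho_eff)
        logdet <- (m - 1) * log(1 - rho_eff) + log(denom)
        ll <- ll - 0.5 * (q + logdet)
      }
    }
    loglik[, ci] <- ll
  }
  loglik <- loglik + rep(log(class_w), each = n)
  loglik <- loglik - apply(loglik, 1, max)
  post <- exp(loglik) / rowSums(exp(loglik))

  lvef_mean <- c(cfg$healthy_lvef_mean, vapply(phenotypes, `[[`, 0, "lvef_mean"))
  lvef_sd <- c(cfg$healthy_lvef_sd, vapply(phenotypes, `[[`, 0, "lvef_sd"))
  p_red <- pnorm((40 - lvef_mean) / lvef_sd)
  as.numeric(post %*% p_red)
}

#' Reader-study configuration
#'
#' @param n_readers number of readers (clusters).
#' @param n_ecgs ECGs per reader (all readers rate the same set).
#' @param positive_fraction fraction of truly positive ECGs.
#' @param sens_before,spec_before,sens_after,spec_after marginal per-reader
#'   probabilities of a correct call; scalars are recycled across readers.
#' @param within_reader_correlation Gaussian-copula correlation between a
#'   reader's before and after calls on the same ECG, in \[0, 1\].
#' @param seed integer RNG seed.
#' @return A `reader_study_config` list.
#' @export
reader_study_config <- function(n_readers = 7, n_ecgs = 100,
                                positive_fraction = 0.5,
                                sens_before = 0.374, spec_before = 0.883,
                                sens_after = 0.711, spec_after = 0.766,
                                within_reader_correlation = 0.3,
                                seed = 1L) {
  pr <- c(sens_before, spec_before, sens_after, spec_after,
          positive_fraction)
  stopifnot(all(pr >= 0 & pr <= 1),
            within_reader_correlation >= 0, within_reader_correlation <= 1)
  structure(as.list(environment())[c("n_readers", "n_ecgs",
                                     "positive_fraction",
                                     "sens_before", "spec_before",
                                     "sens_after", "spec_after",
                                     "within_reader_correlation", "seed")],
            class = "reader_study_config")
}

#' Simulate a multi-reader before/after ECG interpretation study
#'
#' Each reader independently calls the same set of ECGs positive/negative in
#' two phases.  Per reader and ECG the two phases' correctness indicators are
#' drawn through a bivariate Gaussian copula, so the stated sensitivities and
#' specificities hold marginally while a configurable correlation links a
#' reader's two reads of the same ECG.
#'
#' @param cfg a [reader_study_config()].
#' @return A `reader_study` object: data frame `reader_id`, `ecg_id`,
#'   `truth`, `call_before`, `call_after`.
#' @export
simulate_reader_study <- function(cfg = reader_study_config()) {
  rec <- function(x) rep_len(x, cfg$n_readers)
  sens_b <- rec(cfg$sens_before); spec_b <- rec(cfg$spec_before)
  sens_a <- rec(cfg$sens_after); spec_a <- rec(cfg$spec_after)
  with_seed(cfg$seed, {
    n_pos <- round(cfg$positive_fraction * cfg$n_ecgs)
    truth <- sample(rep(c(TRUE, FALSE), c(n_pos, cfg$n_ecgs - n_pos)))
    rho <- cfg$within_reader_correlation
    rows <- lapply(seq_len(cfg$n_readers), function(r) {
      z1 <- rnorm(cfg$n_ecgs)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(cfg$n_ecgs)
      p_b <- ifelse(truth, sens_b[r], spec_b[r])
      p_a <- ifelse(truth, sens_a[r], spec_a[r])
      correct_b <- z1 < qnorm(p_b)
      correct_a <- z2 < qnorm(p_a)
      data.frame(reader_id = sprintf("reader%02d", r),
                 ecg_id = sprintf("ecg%03d", seq_len(cfg$n_ecgs)),
                 truth = truth,
                 call_before = ifelse(truth, correct_b, !correct_b),
                 call_after = ifelse(truth, correct_a, !correct_a),
                 stringsAsFactors = FALSE)
    })
    structure(list(data = do.call(rbind, rows)), class = "reader_study")
  })
}

#' Build a reader study from explicit per-reader data
#'
#' @param data data frame with columns `reader_id`, `ecg_id`, `truth`,
#'   `call_before`, `call_after`; every reader must rate the same ECG set.
#' @return A `reader_study`.
#' @export
reader_study <- function(data) {
  need <- c("reader_id", "ecg_id", "truth", "call_before", "call_after")
  stopifnot(all(need %in% names(data)))
  sets <- tapply(data$ecg_id, data$reader_id, function(x) paste(sort(x), collapse = ";"))
  if (length(unique(sets)) != 1)
    stop("all readers must rate the identical ECG set")
  structure(list(data = as.data.frame(data)), class = "reader_study")
}

#' @export
print.reader_study <- function(x, ...) {
  d <- x$data
  cat(sprintf("<reader_study> %d readers x %d ECGs (%.0f%% positive)\n",
              length(unique(d$reader_id)),
              length(unique(d$ecg_id)),
              100 * mean(d$truth[!duplicated(d$ecg_id)])))
  invisible(x)
}
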