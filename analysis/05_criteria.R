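#!/usr/bin/env Rscript
# Stage 5 — extract decision factors and translate them into criteria.
#
# Applies the per-cluster decision-factor statistic (median SHAP above
# mean + SD over parameters), reads each factor against the parameter
# distributions to name a signed ECG finding, and maps the findings onto
# the six canonical categories.

library(ecgxai)

sm <- read_shap_matrix("results/attributions.csv")
state <- readRDS("results/embedding_state.rds")
test <- read_ecg_dataset("results/data/test.csv")
preds <- utils::read.csv("results/predictions.csv")
truth_tab <- utils::read.csv("results/data/phenotype_truth.csv")

cohort <- test[match(sm$record_ids, test$record_id)]
factors <- decision_factors(sm, state$cl)
criteria <- interpret_criteria(factors, cohort$params, state$cl$labels,
                               reference = test$params, schema = test$schema)
categories <- categorize_criteria(criteria)

cat("decision factors per cluster:\n")
print(tapply(factors$parameter, factors$cluster, paste, collapse = ", "))
cat("\ndecision criteria:\n")
print(as.data.frame(criteria), row.names = FALSE)
cat("\ncanonical category combinations per cluster:\n")
for (k in names(categories))
  cat(sprintf("  cluster %s: %s\n", k, paste(categories[[k]], collapse = " + ")))
out <- attr(categories, "outside")
if (length(out))
  for (k in names(out))
    cat(sprintf("  cluster %s, outside the six categories: %s\n",
                k, paste(out[[k]], collapse = "; ")))

# recovery against the planted signatures
cfg <- readRDS("results/data/config.rds")
truth <- truth_tab$phenotype[match(sm$record_ids, truth_tab$record_id)]
sigs <- setNames(lapply(cfg$phen, function(p) names(p$shifts)),
                 vapply(cfg$phen, `[[`, "", "name"))
cat("\nper-cluster factor recovery vs planted signatures:\n")
for (k in sort(unique(factors$cluster))) {
  maj <- names(which.max(table(truth[state$cl$labels == k])))
  if (maj == "healthy") next
  fac <- factors$parameter[factors$cluster == k]
  cat(sprintf("  cluster %d (majority %s): recall %.2f, precision %.2f\n",
              k, maj, mean(sigs[[maj]] %in% fac), mean(fac %in% sigs[[maj]])))
}

write_criteria_report(factors, criteria, categories, "results")
cat("\nwrote results/decision_factors.csv and results/decision_criteria.json\n")
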