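#!/usr/bin/env Rscript
# Stage 2 — train the four classifier families and compare test performance.
#
# Fits random forest, SVM, ridge logistic regression and MLP on the training
# split, evaluates each on the test split with bootstrap 95% CIs, and keeps
# the best family (by AUROC) for explanation.  Also scores the test set with
# the generator's closed-form Bayes posterior as the attainable ceiling.

library(ecgxai)

cfg <- readRDS("results/data/config.rds")
train <- read_ecg_dataset("results/data/train.csv")
test <- read_ecg_dataset("results/data/test.csv")

families <- c("random_forest", "logistic_regression", "svm", "mlp")
rows <- list(); models <- list()
for (fam in families) {
  cat("fitting", fam, "...\n")
  hyper <- if (fam == "mlp") list(size = 16, maxit = 120) else list()
  m <- fit_lvef_model(train, fam, hyper = hyper, seed = cfg$seed)
  p <- predict_proba(m, test)
  rows[[fam]] <- data.frame(family = fam,
                            auroc = auroc(p, test$reduced),
                            metric_report(p, test$reduced, B = 1000,
                                          seed = cfg$seed)[1:3, 1:2])
  models[[fam]] <- m
}
perf <- do.call(rbind, rows)
bayes <- auroc(true_posterior(test, cfg$gen_cfg, cfg$phen), test$reduced)

cat("\ntest-set AUROC by family (Bayes ceiling ", round(bayes, 3), "):\n", sep = "")
print(unique(perf[, c("family", "auroc")]), row.names = FALSE)

best <- perf$family[which.max(perf$auroc)]
cat("best family:", best, "-> used for explanation\n")

utils::write.csv(perf, "results/model_performance.csv", row.names = FALSE)
saveRDS(models[[best]], "results/best_model.rds")
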