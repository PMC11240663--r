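#!/usr/bin/env Rscript
# Step 5 -- forest hypertuning, training and evaluation.
#
# 10-fold cross-validation over 100/300/500 trees on the balanced training
# windows (ties resolved toward the computationally lighter forest), then
# evaluation of the selected model on the two window sets the model never
# saw: held-out birds of the training strains and the unseen strain.
# Confusion matrices and metric grids go to results/.

library(accbehave)

seed <- 20260928L
train <- read_feature_table("scratch/features/train_balanced.csv")
test1 <- read_feature_table("scratch/features/test_unseen_birds.csv")
test2 <- read_feature_table("scratch/features/test_unseen_strain.csv")

cv <- cross_validate(train, k = 10, n_trees_grid = c(100, 300, 500), seed = seed)
write.csv(cv$metrics, "results/05_cv_tree_grid.csv", row.names = FALSE)
cat("Cross-validated accuracy by forest size:\n")
print(cv$metrics)
cat(sprintf("Selected forest: %d trees.\n\n", cv$best_n_trees))

evaluate_on <- function(test, tag, label) {
  cm <- confusion(test$behaviour, predict(cv$model, test))
  rep <- metrics_report(cm, rounded = TRUE)
  write.csv(as.data.frame(unclass(cm)),
            sprintf("results/05_confusion_%s.csv", tag))
  write.csv(rep, sprintf("results/05_metrics_%s.csv", tag), row.names = FALSE)
  cat(sprintf("%s (%d windows):\n", label, sum(cm)))
  print(cm)
  print(rep)
  cat("\n")
}
evaluate_on(test1, "unseen_birds", "Held-out birds of the training strains")
evaluate_on(test2, "unseen_strain", "Unseen strain (FGC)")
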