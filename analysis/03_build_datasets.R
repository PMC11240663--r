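#!/usr/bin/env Rscript
# Step 3 -- train/test construction.
#
# Bird-level 80:20 split within each training strain (6:2 / 8:2 / 12:3 for
# 8/10/15 birds), training windows cleaned to 100% purity and upsampled so
# every strain-by-behaviour cell matches the largest cell; two test sets are
# kept at natural frequencies and >= 60% purity: held-out birds of the
# training strains ("test1 analogue") and the unseen strain ("test2
# analogue").

library(accbehave)

seed <- 20260928L
man <- read.csv("results/01_flock_manifest.csv")
feats <- read_feature_table("scratch/features/windows.csv")
by_bird <- split(feats, feats$bird_id)

pool <- man[man$role == "train-pool", c("bird_id", "strain")]
plan <- split_birds(pool, ratio = 0.8, seed = seed)
ds <- build_datasets(by_bird, plan, train_purity = 1.0, test_purity = 0.6,
                     seed = seed)
unseen <- do.call(rbind, by_bird[man$bird_id[man$role == "unseen-strain"]])
unseen <- unseen[unseen$purity >= 0.6, ]

before <- table(strain = ds$test$strain, behaviour = ds$test$behaviour)
after <- table(strain = ds$train$strain, behaviour = ds$train$behaviour)
write.csv(as.data.frame(after), "results/03_train_cell_counts.csv", row.names = FALSE)
write_feature_table(ds$train, "scratch/features/train_balanced.csv")
write_feature_table(ds$test, "scratch/features/test_unseen_birds.csv")
write_feature_table(unseen, "scratch/features/test_unseen_strain.csv")

cat("Held-out birds per strain:\n")
print(table(plan$test$strain))
cat(sprintf("\nBalanced training table: %d windows; every cell at %d:\n",
            nrow(ds$train), max(after)))
print(after)
cat(sprintf("\nTest sets: %d unseen-bird windows, %d unseen-strain windows (never upsampled).\n",
            nrow(ds$test), nrow(unseen)))
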