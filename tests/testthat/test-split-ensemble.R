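test_that("block splits give exact 2/1/1 quotas with remainder to train", {
  cl296 <- clinical_cohort(296, seed = 4)$clinical
  sp <- block_split(cl296, seed = 1)
  expect_equal(as.vector(table(sp$group)[c("train", "val", "test")]),
               c(148L, 74L, 74L))
  # partition: every patient exactly once
  expect_setequal(sp$patient_id, cl296$patient_id)
  expect_equal(anyDuplicated(sp$patient_id), 0L)

  cl4 <- clinical_cohort(4, seed = 2)$clinical
  expect_equal(as.vector(table(block_split(cl4, 1)$group)[c("train", "val", "test")]),
               c(2L, 1L, 1L))
  cl6 <- clinical_cohort(6, seed = 2)$clinical
  expect_equal(as.vector(table(block_split(cl6, 1)$group)[c("train", "val", "test")]),
               c(4L, 1L, 1L))
  expect_error(block_split(clinical_cohort(3, seed = 1)$clinical, 1),
               "at least 4")
})

test_that("blocks are outcome-balanced: group event fractions stay close", {
  cl <- clinical_cohort(296, seed = 8)$clinical
  sp <- block_split(cl, seed = 3)
  ev <- tapply(cl$event[match(sp$patient_id, cl$patient_id)], sp$group, mean)
  # sorted blocks ensure every group sees nearly the same event mix
  expect_lt(max(ev) - min(ev), 0.05)
})

test_that("splits are deterministic and seed-sensitive", {
  cl <- clinical_cohort(40, seed = 1)$clinical
  expect_identical(block_split(cl, 7), block_split(cl, 7))
  expect_false(identical(block_split(cl, 7)$group, block_split(cl, 8)$group))
})

test_that("repeat machinery flags tuning repeats and derives stable seeds", {
  cl <- clinical_cohort(40, seed = 1)$clinical
  reps <- run_repeats(cl, n_tune = 8, n_eval = 24, master_seed = 5)
  expect_equal(length(unique(reps$repeat_id)), 32)
  expect_equal(sum(reps$is_tuning) / 40, 8)
  single <- run_repeats(cl, n_tune = 0, n_eval = 1, master_seed = 5)
  expect_equal(unique(single$repeat_id), 1)
  # adding evaluation repeats never reshuffles tuning splits
  more <- run_repeats(cl, n_tune = 8, n_eval = 30, master_seed = 5)
  expect_identical(reps[reps$repeat_id <= 8, ],
                   more[more$repeat_id <= 8, ])
})

test_that("per-repeat test probability is exactly one fourth", {
  cl <- clinical_cohort(296, seed = 4)$clinical
  reps <- run_repeats(cl, n_tune = 8, n_eval = 24, master_seed = 2)
  for (r in unique(reps$repeat_id)) {
    sub <- reps[reps$repeat_id == r, ]
    expect_equal(mean(sub$group == "test"), 0.25)
  }
  # counting identity: mean test-membership per patient = 32/4 = 8 exactly
  counts <- table(factor(reps$patient_id[reps$group == "test"],
                         levels = cl$patient_id))
  expect_equal(mean(counts), 8)
})

test_that("hyperparameter selection maximizes the mean and honors ties", {
  cands <- list(a = list(lr = 1), b = list(lr = 2))
  metrics <- data.frame(candidate = c(1, 1, 2, 2), repeat_id = c(1, 2, 1, 2),
                        metric = c(0.7, 0.7, 0.64, 0.64))
  expect_equal(select_hyperparameters(cands, metrics)$index, 1)
  metrics$metric <- c(0.5, 0.75, 0.75, 0.5)  # equal means -> earlier wins
  expect_equal(select_hyperparameters(cands, metrics)$index, 1)
  expect_equal(select_hyperparameters(cands[1],
                                      metrics[metrics$candidate == 1, ])$index,
               1)
  expect_error(select_hyperparameters(cands, metrics[-1, ]), "candidate 1")
})

test_that("out-of-sample pooling averages per patient and audits inputs", {
  preds <- data.frame(patient_id = c("A", "A", "B", "B", "B"),
                      repeat_id = c(1, 2, 1, 2, 3),
                      score = c(2, 2, 1, 2, 4))
  ens <- pool_out_of_sample(preds)
  expect_equal(ens$ensemble_score[ens$patient_id == "A"], 2)
  expect_equal(ens$ensemble_score[ens$patient_id == "B"], 7 / 3)
  expect_equal(ens$n_oos, c(2, 3))

  dup <- rbind(preds, data.frame(patient_id = "A", repeat_id = 1,
                                 score = 9))
  expect_error(pool_out_of_sample(dup), "duplicate")
  expect_warning(pool_out_of_sample(preds, cohort_ids = c("A", "B", "C")),
                 "C")
})
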