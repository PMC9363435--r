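# shared small simulated cohort for the model tests (built once per run)
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulator_config(mean_depth = 20000, seed = 101)
      spec <- cohort_spec(c("aa/aa" = 400, "aa/SEA" = 60, "aa/3.7" = 50,
                            "aa/4.2" = 30, "3.7/SEA" = 6, "aa/THAI" = 6))
      sim <- simulate_cohort(spec, cfg)
      data <- dplyr::left_join(sim$tpm, sim$labels[, c("sample_id", "label")],
                               by = "sample_id")
      cache <<- data
    }
    cache
  }
})

test_that("stratified splitting is exact, seeded and prevalence-preserving", {
  data <- model_fixture()
  sp <- split_dataset(data, "label", prop = c(0.6, 0.2, 0.2), seed = 5)
  expect_equal(nrow(sp), nrow(data))

  # per-class test proportions within one sample of 20%
  per_class <- table(sp$label, sp$.split)
  for (cl in rownames(per_class)) {
    nk <- sum(per_class[cl, ])
    expect_lte(abs(per_class[cl, "test"] - 0.2 * nk), 1)
    expect_lte(abs(per_class[cl, "validate"] - 0.2 * nk), 1)
  }

  # same seed -> identical partition; different seed -> different
  sp2 <- split_dataset(data, "label", seed = 5)
  expect_identical(sp$.split, sp2$.split)
  sp3 <- split_dataset(data, "label", seed = 6)
  expect_false(identical(sp$.split, sp3$.split))

  # class with < 3 members errors by name
  tiny <- data[c(which(data$label == "aa_aa"),
                 which(data$label == "aa_SEA")[1:2]), ]
  expect_error(split_dataset(tiny, "label"), "aa_SEA")
})

test_that("rebalancing downsamples the normal class to the abnormal count", {
  data <- model_fixture()
  bal <- rebalance_training(data, seed = 3)
  tal <- table(collapse_binary(bal$label))
  expect_equal(unname(tal["normal"]), unname(tal["abnormal"]))
  # abnormal subclass labels intact
  expect_equal(sort(unique(bal$label[bal$label != "aa_aa"])),
               sort(unique(data$label[data$label != "aa_aa"])))
  # retained normals are a subset of the original normals, no replacement
  expect_true(all(bal$sample_id[bal$label == "aa_aa"] %in%
                    data$sample_id[data$label == "aa_aa"]))
  expect_false(any(duplicated(bal$sample_id)))

  # already balanced input returned unchanged
  small <- data[c(which(data$label == "aa_aa")[1:5],
                  which(data$label != "aa_aa")[1:5]), ]
  expect_identical(rebalance_training(small, seed = 1), small)

  # no abnormal -> error
  expect_error(rebalance_training(data[data$label == "aa_aa", ]),
               "no abnormal")
})

test_that("hyperparameter validation rejects out-of-range values", {
  expect_error(ensemble_hyperparameters(n_trees = 0), "n_trees")
  expect_error(ensemble_hyperparameters(n_trees = 2e5), "n_trees")
  expect_error(ensemble_hyperparameters(mtry = 0.5), "mtry")
  expect_error(ensemble_hyperparameters(min_node_size = 0), "min_node_size")
  h <- ensemble_hyperparameters(n_trees = 100, mtry = 8)
  expect_equal(h$n_trees, 100)
})

test_that("training, routing and prediction behave as a two-stage ensemble", {
  data <- model_fixture()
  sp <- split_dataset(data, "label", seed = 7)
  train <- sp[sp$.split == "train", ]
  validate <- sp[sp$.split == "validate", ]
  hyper <- ensemble_hyperparameters(n_trees = 200)
  model <- suppressMessages(train_ensemble(train, validate, hyper, seed = 7))

  # training without a full label set errors by class name
  expect_error(train_ensemble(train[train$label != "aa_4.2", ], seed = 1),
               "aa_4.2")

  test <- sp[sp$.split == "test", ]
  calls <- predict(model, test)
  expect_true(all(calls$.pred %in% c("aa_aa", "aa_SEA", "aa_3.7",
                                     "aa_4.2", "Others")))

  # routing exactness: aa_aa call <=> stage-1 score at or below 0.5
  expect_identical(calls$.pred == "aa_aa", calls$.stage1_abnormal <= 0.5)

  # determinism: same seed, same fits, same confusion matrix
  model2 <- suppressMessages(train_ensemble(train, validate, hyper, seed = 7))
  calls2 <- predict(model2, test)
  expect_identical(calls, calls2)
  expect_identical(model$meta$validation, model2$meta$validation)

  # near-noiseless profile of a SEA carrier classifies correctly
  cfg0 <- simulator_config(mean_depth = 20000, bias_sigma = 0,
                           dispersion = 1e9, seed = 1)
  p <- simulate_counts(genotype("aa", "SEA"), cfg0)
  probe <- profiles_to_table(list(p), "tpm")
  expect_equal(predict(model, probe)$.pred, "aa_SEA")

  # schema mismatch: wrong feature count errors
  expect_error(predict(model, test[, 1:60]), "schema")

  # normalization flag mismatch errors
  raw_probe <- profiles_to_table(list(p), "raw")
  expect_error(predict(model, raw_probe), "normalization")

  # tidy/glance expose the fit metadata
  td <- tidy(model)
  expect_equal(td$stage, c("stage1_binary", "stage2_subtype"))
  expect_true(all(td$n_trees == 200))
  gl <- glance(model)
  expect_equal(gl$n_features, 66)
  expect_equal(gl$seed, 7)
})

test_that("models persist and reload to identical predictions", {
  data <- model_fixture()
  sp <- split_dataset(data, "label", seed = 9)
  model <- train_ensemble(sp[sp$.split == "train", ], NULL,
                          ensemble_hyperparameters(n_trees = 100), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  probe <- sp[sp$.split == "test", ]
  expect_identical(predict(model, probe), predict(back, probe))
  expect_identical(back$schema, model$schema)
  expect_equal(back$meta$seed, 9)

  # corrupted file errors
  writeLines("not a model", path)
  expect_error(load_model(path), "cannot read|not a saved")

  # wrong object errors
  saveRDS(list(a = 1), path)
  expect_error(load_model(path), "not a saved ensemble")
})

test_that("classifier recovers genotypes and degrades with bin bias", {
  # macro-F1 at increasing bias_sigma is non-increasing in trend
  run_at <- function(bias_sigma, seed) {
    cfg <- simulator_config(mean_depth = 20000, bias_sigma = bias_sigma,
                            dispersion = 20, seed = seed)
    spec <- cohort_spec(c("aa/aa" = 300, "aa/SEA" = 50, "aa/3.7" = 40,
                          "aa/4.2" = 25, "3.7/SEA" = 5, "aa/THAI" = 5))
    sim <- simulate_cohort(spec, cfg)
    data <- dplyr::left_join(sim$tpm, sim$labels[, c("sample_id", "label")],
                             by = "sample_id")
    sp <- split_dataset(data, "label", seed = seed)
    m <- train_ensemble(sp[sp$.split == "train", ], NULL,
                        ensemble_hyperparameters(n_trees = 150), seed = seed)
    test <- sp[sp$.split == "test", ]
    cm <- confusion(test$label, predict(m, test)$.pred,
                    c("aa_aa", "aa_SEA", "aa_3.7", "aa_4.2", "Others"))
    met <- class_metrics(cm)
    f1 <- met$f1[met$class != "Others"]
    mean(ifelse(is.na(f1), 0, f1)) # a class never predicted scores 0
  }
  f1_default <- vapply(1:3, function(s) run_at(0.1, s), numeric(1))
  f1_noisy <- vapply(1:3, function(s) run_at(0.8, s), numeric(1))
  expect_gt(mean(f1_default), 0.9)
  expect_lte(mean(f1_noisy), mean(f1_default))
})
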