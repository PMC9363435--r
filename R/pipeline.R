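#' Default end-to-end run configuration
#'
#' @param n_samples Cohort size for the simulated demo cohort. The default
#'   4000 is the smallest round size at which the rare (`Others`) genotypes,
#'   at their observed combined frequency of ~0.1%, are represented by
#'   enough samples (>= 3) to stratify across train/validate/test.
#' @param seed Master seed for simulation, splitting and training.
#' @param prop Train/validate/test proportions.
#' @param sim_config A `thal_sim_config` (default study-condition simulator).
#' @param hyper A `thal_hyper`.
#' @param n_births Birth count for the population-burden report.
#' @return List of class `thal_run_config`.
#' @export
run_config <- function(n_samples = 4000, seed = 7,
                       prop = c(0.6, 0.2, 0.2),
                       sim_config = simulator_config(seed = seed),
                       hyper = ensemble_hyperparameters(),
                       n_births = 1394401) {
  stopf(is_count(n_samples) && n_samples >= 100,
        "n_samples must be an integer >= 100")
  structure(list(n_samples = n_samples, seed = seed, prop = prop,
                 sim_config = sim_config, hyper = hyper,
                 n_births = n_births),
            class = "thal_run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the whole screening workflow end to end
#'
#' Simulate a cohort at the observed genotype frequencies, TPM-normalize,
#' split 60:20:20 stratified by class, rebalance and train the two-stage
#' ensemble, predict the held-out test set, evaluate both stages, and
#' produce the population-burden report. All artifacts (counts, labels,
#' model, calls, metrics, popgen report) are written under `out_dir`
#' together with a run manifest listing every file with its MD5 checksum;
#' repeat runs with the same config are bit-identical. A failing stage
#' raises an error naming the stage and leaves earlier artifacts intact.
#'
#' @param config A `thal_run_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the evaluation, the model, the popgen
#'   report and the manifest tibble.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = tempfile("thal_run_")) {
  stopf(inherits(config, "thal_run_config"), "config must be a thal_run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  add <- function(key, file) { paths[[key]] <<- file.path(out_dir, file) }

  sim <- run_stage("simulate", {
    spec <- cohort_spec(frequencies = default_cohort_frequencies(),
                        n_samples = config$n_samples)
    simulate_cohort(spec, config$sim_config, seed = config$seed)
  })
  run_stage("write-counts", {
    add("counts", "counts_tpm.tsv")
    write_count_table(sim$tpm, paths$counts)
    add("labels", "labels.tsv")
    readr::write_tsv(sim$labels, paths$labels)
  })
  splits <- run_stage("split", {
    data <- dplyr::left_join(sim$tpm, sim$labels[, c("sample_id", "label")],
                             by = "sample_id")
    split_dataset(data, "label", prop = config$prop, seed = config$seed)
  })
  model <- run_stage("train", {
    train_ensemble(splits[splits$.split == "train", ],
                   splits[splits$.split == "validate", ],
                   hyper = config$hyper, seed = config$seed)
  })
  run_stage("save-model", {
    add("model", "model.rds")
    save_model(model, paths$model)
  })
  test <- splits[splits$.split == "test", ]
  calls <- run_stage("predict", predict(model, test))
  run_stage("write-calls", {
    add("calls", "calls.tsv")
    readr::write_tsv(calls, paths$calls)
  })
  evaluation <- run_stage("evaluate", {
    ev <- evaluate_predictions(test$label, calls$.pred)
    add("metrics", "metrics.json")
    jsonlite::write_json(list(
      stage1 = list(accuracy = ev$stage1$accuracy,
                    metrics = metrics_as_percent(ev$stage1$metrics)),
      ensemble = list(accuracy = ev$ensemble$accuracy,
                      metrics = metrics_as_percent(ev$ensemble$metrics))
    ), paths$metrics, auto_unbox = TRUE, digits = NA)
    ev
  })
  pop <- run_stage("popgen", {
    rep <- popgen_report(n_births = config$n_births)
    add("popgen", "popgen.json")
    jsonlite::write_json(list(
      allele_frequencies = rep$allele_frequencies,
      phenotype_percent = setNames(as.list(rep$phenotype_frequencies$percent),
                                   rep$phenotype_frequencies$phenotype),
      projected_births = setNames(as.list(rep$projection$expected_births),
                                  rep$projection$phenotype),
      carrier_total = rep$carrier_total
    ), paths$popgen, auto_unbox = TRUE, digits = NA)
    rep
  })
  manifest <- run_stage("manifest", {
    files <- unlist(paths)
    m <- tibble(artifact = names(paths), path = unname(files),
                md5 = unname(tools::md5sum(files)))
    readr::write_tsv(m, file.path(out_dir, "manifest.tsv"))
    m
  })
  inform(sprintf("run complete: %d artifacts in %s", nrow(manifest), out_dir))
  invisible(list(evaluation = evaluation, model = model, popgen = pop,
                 manifest = manifest, out_dir = out_dir))
}
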