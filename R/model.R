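#' @importFrom ranger ranger
NULL

ENSEMBLE_LABELS <- c("aa_aa", "aa_SEA", "aa_3.7", "aa_4.2", "Others")
STAGE2_LABELS <- c("aa_SEA", "aa_3.7", "aa_4.2", "Others")
MODEL_FORMAT_VERSION <- 1L

feature_cols <- function(data) {
  setdiff(names(data), c("sample_id", "genotype", "label", ".split"))
}

#' Stratified train/validate/test split
#'
#' Partitions samples into train, validate and test sets at the given
#' proportions (default 60:20:20), stratified by class label so that the
#' validation and test sets reflect the true prevalence of each class.
#' Within each class, integer set sizes are fixed by largest-remainder
#' rounding of the proportions and samples are then assigned by a seeded
#' random permutation, so the partition is exact and reproducible.
#'
#' @param data Wide tibble with a `sample_id` column and feature columns.
#' @param labels Character vector of class labels aligned to rows, or the
#'   name of a label column in `data`.
#' @param prop Numeric vector of three positive proportions summing to 1.
#' @param seed Integer seed for the permutation.
#' @return `data` (with a `label` column) plus a `.split` column taking
#'   values `"train"`, `"validate"`, `"test"`.
#' @export
split_dataset <- function(data, labels = "label", prop = c(0.6, 0.2, 0.2),
                          seed = 1) {
  if (is.character(labels) && length(labels) == 1 && labels %in% names(data)) {
    labels <- data[[labels]]
  } else {
    stopf(length(labels) == nrow(data),
          "labels (%d) must align with rows (%d)", length(labels), nrow(data))
    data$label <- labels
  }
  stopf(length(prop) == 3 && all(prop > 0) && abs(sum(prop) - 1) < 1e-9,
        "prop must be three positive proportions summing to 1")
  tallies <- table(labels)
  small <- names(tallies)[tallies < 3]
  stopf(length(small) == 0,
        "class(es) with fewer than 3 samples: %s", paste(small, collapse = ", "))

  set.seed(seed)
  split <- character(nrow(data))
  for (cl in names(tallies)) {
    idx <- which(labels == cl)
    nk <- length(idx)
    raw <- prop * nk
    sizes <- floor(raw)
    rem <- nk - sum(sizes)
    add <- head(order(raw - sizes, decreasing = TRUE), rem)
    sizes[add] <- sizes[add] + 1
    perm <- sample(idx)
    split[perm] <- rep(c("train", "validate", "test"), sizes)
  }
  data$.split <- split
  data
}

#' Rebalance the stage-1 training set
#'
#' Down-samples the majority normal class (without replacement) to the
#' abnormal count, so the binary normal/abnormal forest trains on a balanced
#' set. Abnormal samples are all retained with their subclass labels intact.
#'
#' @param data Training tibble with a `label` column.
#' @param normal_label The normal class label (default `"aa_aa"`).
#' @param seed Integer seed for the down-sampling.
#' @return The rebalanced tibble.
#' @export
rebalance_training <- function(data, normal_label = "aa_aa", seed = 1) {
  is_norm <- data$label == normal_label
  n_ab <- sum(!is_norm)
  stopf(n_ab > 0, "no abnormal samples to balance against")
  if (sum(is_norm) <= n_ab) return(data)
  set.seed(seed)
  keep_norm <- sample(which(is_norm), n_ab)
  data[sort(c(keep_norm, which(!is_norm))), ]
}

#' Random-forest hyperparameters
#'
#' @param n_trees Number of trees per forest (1 to 1e5; default 500).
#' @param mtry Features tried per split; `NULL` (default) uses
#'   `floor(sqrt(p))`.
#' @param min_node_size Minimal terminal node size (default 1).
#' @param class_weights If `TRUE`, weight stage-2 classes inversely to their
#'   frequency (off by default: only the normal:abnormal imbalance is
#'   rebalanced, the stage-2 subclass mix is left at prevalence).
#' @return List of class `thal_hyper`.
#' @export
ensemble_hyperparameters <- function(n_trees = 500, mtry = NULL,
                                     min_node_size = 1,
                                     class_weights = FALSE) {
  stopf(is_count(n_trees) && n_trees >= 1 && n_trees <= 1e5,
        "n_trees must be an integer in [1, 1e5]")
  stopf(is.null(mtry) || (is_count(mtry) && mtry >= 1),
        "mtry must be NULL or a positive integer")
  stopf(is_count(min_node_size) && min_node_size >= 1,
        "min_node_size must be a positive integer")
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size,
                 class_weights = isTRUE(class_weights)),
            class = "thal_hyper")
}

fit_forest <- function(data, label, hyper, seed) {
  p <- ncol(data)
  mtry <- hyper$mtry %||% max(1, floor(sqrt(p)))
  stopf(mtry <= p, "mtry (%d) exceeds feature count (%d)", mtry, p)
  weights <- NULL
  if (hyper$class_weights) {
    tal <- table(label)
    weights <- as.numeric(sum(tal) / (length(tal) * tal))[match(names(tal), levels(label))]
    names(weights) <- names(tal)
  }
  ranger::ranger(x = as.data.frame(data), y = label,
                 num.trees = hyper$n_trees, mtry = mtry,
                 min.node.size = hyper$min_node_size,
                 probability = TRUE, seed = seed, num.threads = 1,
                 class.weights = weights)
}

#' Train the two-stage carrier-screening ensemble
#'
#' Stage 1 is a binary random forest separating normal (`aa_aa`) from
#' abnormal samples, trained on a rebalanced set (normal down-sampled to the
#' abnormal count). Stage 2 is a four-class random forest (`aa_SEA`,
#' `aa_3.7`, `aa_4.2`, `Others`) trained on the truth-labeled abnormal
#' subset of the original (un-rebalanced) training data, so stage-1 errors
#' never leak into stage-2 labels. Features are the TPM-normalized bin
#' values. Validation-set macro-F1 for both stages is recorded in the model
#' metadata when a validation set is supplied.
#'
#' @param train Tibble of training samples: feature columns plus `label`
#'   (and optionally `sample_id`). Must contain all five classes.
#' @param validate Optional validation tibble of the same shape.
#' @param hyper A `thal_hyper` (default [ensemble_hyperparameters()]).
#' @param seed Integer seed governing rebalancing and both forest fits.
#' @param normalization Flag recorded in the feature schema (default
#'   `"tpm"`); predictions check it.
#' @return An object of class `thal_ensemble`.
#' @export
train_ensemble <- function(train, validate = NULL,
                           hyper = ensemble_hyperparameters(), seed = 1,
                           normalization = "tpm") {
  stopf(inherits(hyper, "thal_hyper"),
        "hyper must come from ensemble_hyperparameters()")
  stopf("label" %in% names(train), "train must have a label column")
  missing_cls <- setdiff(ENSEMBLE_LABELS, unique(train$label))
  stopf(length(missing_cls) == 0, "training set lacks class(es): %s",
        paste(missing_cls, collapse = ", "))
  feats <- feature_cols(train)
  schema <- list(n_features = length(feats), features = feats,
                 normalization = normalization)

  balanced <- rebalance_training(train, seed = seed)
  y1 <- factor(collapse_binary(balanced$label),
               levels = c("normal", "abnormal"))
  stage1 <- fit_forest(balanced[, feats], y1, hyper, seed)

  abnormal <- train[train$label != "aa_aa", ]
  y2 <- factor(abnormal$label, levels = STAGE2_LABELS)
  stage2 <- fit_forest(abnormal[, feats], y2, hyper, seed + 1L)

  meta <- list(
    seed = seed,
    class_counts = as.list(table(train$label)),
    balanced_counts = as.list(table(collapse_binary(balanced$label))),
    validation = NULL
  )
  model <- structure(
    list(stage1 = stage1, stage2 = stage2, schema = schema, hyper = hyper,
         meta = meta, format_version = MODEL_FORMAT_VERSION),
    class = "thal_ensemble")

  if (!is.null(validate) && nrow(validate) > 0) {
    calls <- predict(model, validate)
    cm2 <- confusion(collapse_binary(validate$label),
                     collapse_binary(calls$.pred), c("normal", "abnormal"))
    cm5 <- confusion(validate$label, calls$.pred, ENSEMBLE_LABELS)
    model$meta$validation <- list(
      stage1_macro_f1 = macro_f1(cm2),
      stage1_abnormal_sensitivity =
        class_metrics(cm2)$sensitivity[rownames(cm2) == "abnormal"],
      ensemble_accuracy = attr(class_metrics(cm5), "accuracy")
    )
    inform(sprintf(
      "validation: stage-1 macro-F1 %.4f, abnormal sensitivity %.4f, ensemble accuracy %.4f",
      model$meta$validation$stage1_macro_f1,
      model$meta$validation$stage1_abnormal_sensitivity,
      model$meta$validation$ensemble_accuracy))
  }
  model
}

#' @export
print.thal_ensemble <- function(x, ...) {
  cat(sprintf(
    "<two-stage ensemble: %d features (%s), %d trees/stage, seed %d>\n",
    x$schema$n_features, x$schema$normalization, x$hyper$n_trees,
    x$meta$seed))
  invisible(x)
}

#' Predict carrier genotype classes
#'
#' Routes each sample through the two stages: stage 1 scores the abnormal
#' probability; samples at or below 0.5 are called `aa_aa` and never reach
#' stage 2, all others take the stage-2 argmax among the four carrier
#' classes. Score vectors from both stages are returned for audit (stage-2
#' scores are computed for every sample but only govern the label of
#' stage-1 positives).
#'
#' @param object A `thal_ensemble`.
#' @param new_data Tibble whose feature columns match the model's schema
#'   (same bin count and normalization).
#' @param ... Unused.
#' @return Tibble: `sample_id` (if present), `.pred`, `.stage1_abnormal`,
#'   and `.stage2_<class>` score columns.
#' @export
predict.thal_ensemble <- function(object, new_data, ...) {
  feats <- object$schema$features
  present <- intersect(feats, names(new_data))
  stopf(length(present) == length(feats),
        "feature schema mismatch: model expects %d features, data has %d matching",
        length(feats), length(present))
  norm <- attr(new_data, "normalization")
  if (!is.null(norm) && norm != "unknown" &&
      norm != object$schema$normalization) {
    abort(sprintf("normalization mismatch: model expects %s, data is %s",
                  object$schema$normalization, norm))
  }
  x <- as.data.frame(new_data[, feats])
  p1 <- predict(object$stage1, data = x, num.threads = 1)$predictions
  p2 <- predict(object$stage2, data = x, num.threads = 1)$predictions
  abnormal <- unname(p1[, "abnormal"] > 0.5)
  sub <- STAGE2_LABELS[max.col(p2, ties.method = "first")]
  pred <- ifelse(abnormal, sub, "aa_aa")
  out <- tibble(.pred = pred, .stage1_abnormal = unname(p1[, "abnormal"]))
  for (cl in STAGE2_LABELS) out[[paste0(".stage2_", cl)]] <- unname(p2[, cl])
  if ("sample_id" %in% names(new_data)) {
    out <- dplyr::bind_cols(new_data["sample_id"], out)
  }
  out
}

#' Persist / restore a trained ensemble
#'
#' The file embeds the feature schema, seed, hyperparameters and a format
#' version; loading verifies the version and class so predictions round-trip
#' bit-exactly.
#'
#' @param model A `thal_ensemble`.
#' @param path File path (RDS).
#' @return `load_model()` returns the `thal_ensemble`.
#' @export
save_model <- function(model, path) {
  stopf(inherits(model, "thal_ensemble"), "model must be a thal_ensemble")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) abort(sprintf(
                      "cannot read model file %s: %s", path, conditionMessage(e))))
  stopf(inherits(model, "thal_ensemble"), "%s is not a saved ensemble", path)
  stopf(identical(model$format_version, MODEL_FORMAT_VERSION),
        "model format version %s does not match supported version %d",
        model$format_version %||% "<missing>", MODEL_FORMAT_VERSION)
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a trained ensemble
#'
#' @param x A `thal_ensemble`.
#' @param ... Unused.
#' @return One row per stage: training size, trees, mtry and out-of-bag
#'   prediction error.
#' @method tidy thal_ensemble
#' @export
tidy.thal_ensemble <- function(x, ...) {
  tibble(
    stage = c("stage1_binary", "stage2_subtype"),
    n_train = c(x$stage1$num.samples, x$stage2$num.samples),
    n_trees = c(x$stage1$num.trees, x$stage2$num.trees),
    mtry = c(x$stage1$mtry, x$stage2$mtry),
    oob_error = c(x$stage1$prediction.error, x$stage2$prediction.error)
  )
}

#' One-row overview of a trained ensemble
#'
#' @param x A `thal_ensemble`.
#' @param ... Unused.
#' @return Tibble with feature count, seed and (when a validation set was
#'   used) validation metrics.
#' @method glance thal_ensemble
#' @export
glance.thal_ensemble <- function(x, ...) {
  v <- x$meta$validation
  tibble(
    n_features = x$schema$n_features,
    normalization = x$schema$normalization,
    n_trees = x$hyper$n_trees,
    seed = x$meta$seed,
    val_stage1_abnormal_sensitivity = v$stage1_abnormal_sensitivity %||% NA_real_,
    val_ensemble_accuracy = v$ensemble_accuracy %||% NA_real_
  )
}
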