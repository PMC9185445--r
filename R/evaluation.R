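# Leave-one-out evaluation harness: register a cohort to a chosen template,
# reorder voltages, train per-channel classifiers on every leave-one-out
# split, pool the held-out predictions and compute accuracy, F1, ROC-AUC and
# PR-AUC; iterate over all templates x channels x labels for the full
# report.

#' Leave-one-out cross-validation splits
#'
#' @param n Cohort size (at least 2).
#' @return List of `n` folds, each `list(train, test)` with `n - 1` training
#'   indices and one test index; every index is tested exactly once.
#' @export
loocv_splits <- function(n) {
  if (n < 2L) stop("leave-one-out needs at least 2 examples", call. = FALSE)
  lapply(seq_len(n), function(k) list(train = setdiff(seq_len(n), k), test = k))
}

#' Binary classification metrics on pooled predictions
#'
#' Accuracy and positive-class F1 at the 0.5 probability threshold, ROC-AUC
#' by the rank (Mann-Whitney) formulation with ties counted one half, and
#' PR-AUC by the average-precision step integration. When the pooled truth
#' contains a single class the two areas are undefined and returned as `NA`
#' (F1 likewise when it is 0/0).
#'
#' @param y_true Binary 0/1 truth vector (length at least 2).
#' @param y_prob Positive-class probabilities in `[0, 1]`.
#' @return List with `accuracy`, `f1`, `roc_auc`, `pr_auc`.
#' @export
compute_metrics <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(y_prob)) {
    stop("`y_true` and `y_prob` must have equal length", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("need at least 2 predictions", call. = FALSE)
  stopifnot(all(y_true %in% c(0L, 1L)), all(y_prob >= 0 & y_prob <= 1))
  pred <- as.integer(y_prob > 0.5)
  accuracy <- mean(pred == y_true)

  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)

  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    roc_auc <- NA_real_
    pr_auc <- NA_real_
  } else {
    r <- rank(y_prob)  # midranks handle ties as one half
    roc_auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    pr_auc <- average_precision(y_true, y_prob)
  }
  list(accuracy = accuracy, f1 = f1, roc_auc = roc_auc, pr_auc = pr_auc)
}

# average precision: sum over decreasing unique thresholds of
# (recall step) x (precision at that threshold)
average_precision <- function(y_true, y_prob) {
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  p <- y_prob[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(p[-1] != p[-length(p)], TRUE)  # last index of each tied block
  tp <- tp[last]
  fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / sum(y_true)
  sum(diff(c(0, recall)) * precision)
}

# Register every non-template map to the template and reorder the whole
# cohort; returns per-channel feature matrices plus bookkeeping.
align_cohort <- function(cohort, template_index, encoder_weights,
                         max_iter = 20L, step = 0.01, max_step = 0.05,
                         register = TRUE, n_common = 406L) {
  n <- length(cohort)
  if (template_index < 1L || template_index > n) {
    stop("template index out of range", call. = FALSE)
  }
  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    if (!register || i == template_index) {
      aligned[[i]] <- cohort[[i]]
    } else {
      aligned[[i]] <- lk_register(cohort[[i]], cohort[[template_index]],
                                  encoder_weights, max_iter = max_iter,
                                  step = step, max_step = max_step)$aligned
    }
  }
  list(
    unipolar = build_feature_matrix(aligned, "unipolar", n_common),
    bipolar = build_feature_matrix(aligned, "bipolar", n_common)
  )
}

# Train on one fold's training rows and predict the held-out row. With
# balanced bagging and an imbalanced training set, the prediction is the
# average over the balanced subfits obtained by dropping each majority
# example in turn.
fold_predict <- function(X, labels, tr, te, config, fold_seed, patient_id) {
  fit_predict <- function(rows, fit_seed) {
    cfg <- config
    cfg$seed <- fit_seed
    w <- train_mlp(X[rows, , drop = FALSE], labels[rows], cfg)
    x <- X[te, ]
    attr(x, "patient_id") <- patient_id
    mlp_forward(x, w, cfg, training = FALSE)
  }
  ytr <- labels[tr]
  n1 <- sum(ytr == 1L)
  n0 <- length(ytr) - n1
  if (!isTRUE(config$balanced_bagging) || n1 == n0) {
    return(fit_predict(tr, fold_seed))
  }
  majority <- if (n1 > n0) 1L else 0L
  drop_idx <- tr[ytr == majority]
  probs <- rowMeans(vapply(seq_along(drop_idx), function(j) {
    fit_predict(setdiff(tr, drop_idx[j]), derive_seed(fold_seed, j))$probabilities
  }, numeric(2)))
  prediction(probs, patient_id)
}

# Run LOOCV for one template and one label. Only the requested base
# channels are trained; the ensemble averages the two channels' fold
# probabilities.
eval_template_label <- function(features, labels, patient_ids, config, seed,
                                ensemble_weight = 0.5,
                                channels = c("unipolar", "bipolar")) {
  n <- length(labels)
  folds <- loocv_splits(n)
  preds <- list(unipolar = vector("list", n), bipolar = vector("list", n),
                ensemble = vector("list", n))
  for (k in seq_len(n)) {
    tr <- folds[[k]]$train
    te <- folds[[k]]$test
    # one derived seed per fold, shared by the channels: identical channel
    # features then yield identical fits, so the ensemble collapses cleanly
    fold_seed <- derive_seed(seed, k)
    for (ch in channels) {
      preds[[ch]][[k]] <- fold_predict(features[[ch]], labels, tr, te,
                                       config, fold_seed, patient_ids[te])
    }
    if (all(c("unipolar", "bipolar") %in% channels)) {
      preds$ensemble[[k]] <- ensemble_predict(preds$unipolar[[k]],
                                              preds$bipolar[[k]],
                                              weight = ensemble_weight)
    }
  }
  preds
}

scenario_result <- function(template_index, channel, label, preds, labels,
                            patient_ids) {
  y_prob <- vapply(preds, function(p) p$probabilities[2], numeric(1))
  m <- compute_metrics(labels, y_prob)
  structure(
    list(template_index = template_index, channel = channel, label = label,
         accuracy = m$accuracy, f1 = m$f1, roc_auc = m$roc_auc,
         pr_auc = m$pr_auc,
         per_fold_predictions = Map(function(p, t) {
           p$true_label <- t
           p
         }, preds, labels),
         patient_ids = patient_ids),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> template %d, %s -> %s\n",
              x$template_index, x$channel, x$label))
  cat(sprintf("  accuracy %.3f, F1 %.3f, ROC-AUC %.3f, PR-AUC %.3f\n",
              x$accuracy, x$f1, x$roc_auc, x$pr_auc))
  invisible(x)
}

#' Evaluate one template / channel / label scenario
#'
#' Registers all non-template maps to the chosen template, canonically
#' reorders every map (template included), then runs leave-one-out
#' cross-validation: per fold the channel classifier(s) are trained on the
#' remaining maps and the held-out map is predicted (the ensemble averages
#' the two channel classifiers' probabilities). The held-out predictions
#' are pooled and the four metrics computed on the pooled set.
#'
#' @param cohort List of preprocessed `voltage_map`s with labels.
#' @param template_index Template position in `cohort` (1-based).
#' @param channel `"unipolar"`, `"bipolar"` or `"ensemble"`.
#' @param label `"af_type"` or `"recurrence_1y"`.
#' @param encoder_weights Trained `encoder_weights` for registration.
#' @param config `mlp_config` for the classifier.
#' @param seed Integer seed (classifier initialisation and dropout).
#' @param max_iter,step,max_step Registration settings (see
#'   [lk_register()]). Cross-patient alignment defaults to a trust region
#'   of 0.05 on the twist norm: distinct shapes leave a permanent feature
#'   residual, and unconstrained Gauss-Newton steps on that residual walk
#'   the source far from any meaningful pose.
#' @param register Set `FALSE` to skip registration (ablation).
#' @return A `scenario_result` with the pooled metrics and per-fold
#'   predictions.
#' @export
run_scenario <- function(cohort, template_index,
                         channel = c("unipolar", "bipolar", "ensemble"),
                         label = c("af_type", "recurrence_1y"),
                         encoder_weights, config = mlp_config(), seed = 1L,
                         max_iter = 20L, step = 0.01, max_step = 0.05,
                         register = TRUE) {
  channel <- match.arg(channel)
  label <- match.arg(label)
  n_common <- config$input_dim
  features <- align_cohort(cohort, template_index, encoder_weights,
                           max_iter = max_iter, step = step,
                           max_step = max_step, register = register,
                           n_common = n_common)
  labels <- vapply(cohort, function(m) m[[label]], integer(1))
  pids <- vapply(cohort, function(m) m$patient_id, character(1))
  needed <- if (channel == "ensemble") c("unipolar", "bipolar") else channel
  preds <- eval_template_label(features, labels, pids, config,
                               derive_seed(seed, template_index,
                                           match(label, c("af_type", "recurrence_1y"))),
                               ensemble_weight = config$ensemble_weight,
                               channels = needed)
  scenario_result(template_index, channel, label, preds[[channel]], labels, pids)
}

#' Full evaluation report over templates, channels and labels
#'
#' Iterates every template index x three channels (unipolar, bipolar,
#' ensemble) x two labels (AF type, 1-year recurrence), reusing one
#' registration pass and one pair of per-fold classifier fits per template,
#' and emits six tables with one row per template and columns Accuracy, F1,
#' ROC-AUC, PR-AUC.
#'
#' @param cohort List of preprocessed `voltage_map`s with labels.
#' @param encoder_weights Trained `encoder_weights`.
#' @param config `mlp_config`.
#' @param seed Master integer seed.
#' @param max_iter,step,max_step Registration settings (see
#'   [lk_register()]).
#' @param register Set `FALSE` to skip registration (ablation).
#' @param verbose Emit progress messages?
#' @return An `evaluation_report`: list with `tables` (six data frames named
#'   `<channel>_<label>`) and `scenarios` (all `scenario_result`s).
#' @export
full_report <- function(cohort, encoder_weights, config = mlp_config(),
                        seed = 1L, max_iter = 20L, step = 0.01,
                        max_step = 0.05, register = TRUE, verbose = FALSE) {
  n <- length(cohort)
  channels <- c("unipolar", "bipolar", "ensemble")
  label_names <- c("af_type", "recurrence_1y")
  pids <- vapply(cohort, function(m) m$patient_id, character(1))
  scenarios <- list()
  for (tpl in seq_len(n)) {
    if (verbose) message(sprintf("template %d/%d", tpl, n))
    features <- align_cohort(cohort, tpl, encoder_weights,
                             max_iter = max_iter, step = step,
                             max_step = max_step, register = register,
                             n_common = config$input_dim)
    for (lbl in label_names) {
      labels <- vapply(cohort, function(m) m[[lbl]], integer(1))
      preds <- eval_template_label(features, labels, pids, config,
                                   derive_seed(seed, tpl,
                                               match(lbl, label_names)),
                                   ensemble_weight = config$ensemble_weight)
      for (ch in channels) {
        scenarios[[paste(ch, lbl, tpl, sep = "_")]] <-
          scenario_result(tpl, ch, lbl, preds[[ch]], labels, pids)
      }
    }
  }
  tables <- list()
  for (ch in channels) {
    for (lbl in label_names) {
      rows <- lapply(seq_len(n), function(tpl) {
        s <- scenarios[[paste(ch, lbl, tpl, sep = "_")]]
        data.frame(template = tpl - 1L, accuracy = s$accuracy, f1 = s$f1,
                   roc_auc = s$roc_auc, pr_auc = s$pr_auc)
      })
      tables[[paste(ch, lbl, sep = "_")]] <- do.call(rbind, rows)
    }
  }
  structure(list(tables = tables, scenarios = scenarios,
                 n_templates = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d templates, %d tables\n",
              x$n_templates, length(x$tables)))
  for (nm in names(x$tables)) {
    cat("\n==", nm, "==\n")
    print(x$tables[[nm]], row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' One CSV per scenario table plus a JSON summary of mean metrics per table.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  summary <- lapply(report$tables, function(tb) {
    as.list(colMeans(tb[, c("accuracy", "f1", "roc_auc", "pr_auc")],
                     na.rm = TRUE))
  })
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
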