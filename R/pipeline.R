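# End-to-end orchestration: simulate -> preprocess -> encoder pretraining ->
# registration pretraining -> leave-one-out finetuning -> full evaluation
# report, reproducible from a single config and master seed.

#' Pipeline configuration
#'
#' Collects every stage's parameters with the method's published defaults
#' (minimum point count 100, common count 406, at most 20 registration
#' iterations, Jacobian step 0.01, 1024-dim global feature, hidden width
#' 300, dropout 0.4, batch size 16, perturbation ranges 0-45 degrees and
#' 0-0.8) plus the synthetic-cohort settings and a master seed from which
#' every stage and patient seed is derived. Training epochs default to
#' CPU-friendly values.
#'
#' @param seed Master integer seed.
#' @param n_patients Synthetic cohort size (default 8).
#' @param class_balance,effect_size,noise_sd,correlation_length Cohort
#'   generator settings (see [cohort_spec()]).
#' @param min_points Minimum point count per map (default 100).
#' @param n_points Common resampled point count (default 406).
#' @param max_iter Registration iteration cap (default 20).
#' @param jacobian_step Finite-difference step (default 0.01).
#' @param max_step Trust-region bound on the twist per iteration for
#'   cross-patient alignment (default 0.05; see [run_scenario()]).
#' @param feature_dim Global feature width (default 1024).
#' @param hidden_dim Classifier hidden width (default 300).
#' @param dropout Classifier dropout rate (default 0.4).
#' @param batch_size Encoder pretraining batch size (default 16).
#' @param max_rot_deg,max_trans Registration-pretraining perturbation ranges.
#' @param shape_pretrain_epochs,shape_clouds Encoder (shape-classification)
#'   pretraining size.
#' @param lk_pretrain_epochs,lk_pretrain_clouds Registration pretraining
#'   size.
#' @param finetune_epochs Leave-one-out finetuning epochs on the cohort.
#' @param classifier_epochs MLP training epochs (default 200).
#' @param register Run registration (set `FALSE` for the ablation)?
#' @param out_dir Optional directory for stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_patients = 8L,
                            class_balance = 0.5,
                            effect_size = 2,
                            noise_sd = 0.4,
                            correlation_length = 0.3,
                            min_points = 100L,
                            n_points = 406L,
                            max_iter = 20L,
                            jacobian_step = 0.01,
                            max_step = 0.05,
                            feature_dim = 1024L,
                            hidden_dim = 300L,
                            dropout = 0.4,
                            batch_size = 16L,
                            max_rot_deg = 45,
                            max_trans = 0.8,
                            shape_pretrain_epochs = 10L,
                            shape_clouds = 25L,
                            lk_pretrain_epochs = 5L,
                            lk_pretrain_clouds = 40L,
                            finetune_epochs = 2L,
                            classifier_epochs = 200L,
                            register = TRUE,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Generates a synthetic cohort (or loads one from `cohort_dir`),
#' preprocesses it, pretrains the encoder on synthetic shape classes,
#' pretrains the registration on synthetic shells with random ground-truth
#' twists, finetunes on the cohort by leave-one-out template rounds, and
#' produces the full evaluation report. Rerunning with the same config
#' reproduces the report exactly. With `config$out_dir` set, the cohort,
#' encoder summary and report tables are persisted.
#'
#' @param config A `pipeline_config`.
#' @param cohort_dir Optional directory of voltage CSVs plus `labels.csv`
#'   to use instead of simulation.
#' @param verbose Emit stage progress messages?
#' @return The `evaluation_report`, with the trained `encoder_weights` in
#'   attribute `"encoder_weights"` and the preprocessed cohort in
#'   attribute `"cohort"`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/6: cohort")
  if (is.null(cohort_dir)) {
    spec <- cohort_spec(n_patients = config$n_patients,
                        class_balance = config$class_balance,
                        effect_size = config$effect_size,
                        noise_sd = config$noise_sd,
                        correlation_length = config$correlation_length,
                        seed = derive_seed(config$seed, 1L))
    raw <- generate_cohort(spec)
  } else {
    raw <- read_cohort(cohort_dir, labels = file.path(cohort_dir, "labels.csv"))
  }
  if (!is.null(config$out_dir)) {
    write_cohort(raw, file.path(config$out_dir, "cohort_raw"))
  }

  kept <- filter_maps(raw, config$min_points)
  if (length(kept) < 2L) {
    stop("pipeline stage 'preprocess': fewer than 2 maps survived filtering",
         call. = FALSE)
  }
  # the common count is the configured target, capped at the cohort minimum
  # (the method's own rule: the resample count is the smallest map size)
  n_common <- min(config$n_points, min(vapply(kept, n_points, integer(1))))
  say("stage 2/6: preprocessing (filter >= %d, normalize, resample to %d)",
      config$min_points, n_common)
  cohort <- preprocess_maps(kept, min_points = config$min_points,
                            n_points = n_common,
                            seed = derive_seed(config$seed, 2L))
  config$n_points <- n_common

  say("stage 3/6: encoder pretraining on shape classes")
  shapes <- generate_shape_classes(n_per_class = config$shape_clouds,
                                   n_points = config$n_points,
                                   seed = derive_seed(config$seed, 3L))
  weights <- pretrain_encoder(shapes, epochs = config$shape_pretrain_epochs,
                              batch_size = config$batch_size,
                              seed = derive_seed(config$seed, 31L),
                              verbose = verbose)

  say("stage 4/6: registration pretraining on synthetic shells")
  shells <- lapply(seq_len(config$lk_pretrain_clouds), function(i) {
    # registration operates in the normalised unit frame
    normalize_unit_cube(
      generate_shell(config$n_points, derive_seed(config$seed, 4L, i)))
  })
  weights <- train_registration(shells, weights, mode = "pretrain",
                                epochs = config$lk_pretrain_epochs,
                                seed = derive_seed(config$seed, 41L),
                                step = config$jacobian_step,
                                max_rot_deg = config$max_rot_deg,
                                max_trans = config$max_trans,
                                verbose = verbose)

  say("stage 5/6: leave-one-out finetuning on the cohort")
  if (config$finetune_epochs > 0L) {
    weights <- train_registration(cohort, weights, mode = "finetune",
                                  epochs = config$finetune_epochs,
                                  seed = derive_seed(config$seed, 5L),
                                  step = config$jacobian_step,
                                  max_step = config$max_step,
                                  verbose = verbose)
  }

  say("stage 6/6: evaluation report")
  cfg <- mlp_config(input_dim = config$n_points,
                    hidden_dim = config$hidden_dim,
                    dropout = config$dropout,
                    epochs = config$classifier_epochs,
                    seed = derive_seed(config$seed, 6L))
  report <- full_report(cohort, weights, cfg,
                        seed = derive_seed(config$seed, 61L),
                        max_iter = config$max_iter,
                        step = config$jacobian_step,
                        max_step = config$max_step,
                        register = config$register,
                        verbose = verbose)
  if (!is.null(config$out_dir)) {
    write_report(report, file.path(config$out_dir, "report"))
  }
  attr(report, "encoder_weights") <- weights
  attr(report, "cohort") <- cohort
  report
}
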