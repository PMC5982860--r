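#' Run the full fall-detection pipeline on a labelled cohort
#'
#' Orchestrates the complete experimental scheme on a list of labelled
#' recordings:
#' 1. participant-wise hold-out (15% of participants per source dataset
#'    reserved for validation);
#' 2. peak-threshold tuning on the training/testing recordings (SA or GA,
#'    median best threshold over `tune_runs` runs);
#' 3. peak detection and feature extraction at the tuned threshold;
#' 4. SMOTE balancing of the event dataset;
#' 5. training one classifier per requested family (optionally after a
#'    participant-wise grid search);
#' 6. end-to-end recording-level validation on the held-out participants.
#'
#' @param recordings named list of labelled [accel_ts].
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param families classifier families to train.
#' @param config a `run_config` (see [default_run_config()]).
#' @param tune_runs number of tuning runs (median threshold is used).
#' @param grid if `TRUE`, run [grid_search()] over the configured grids on
#'   the balanced training data before the final fit; otherwise train at
#'   each family's default hyperparameters.
#' @param dataset optional per-participant source-dataset factor for the
#'   hold-out (defaults to a single dataset).
#' @return list with `threshold` (tuned), `tuning` (the [tune_threshold()]
#'   result), `holdout` (the fold plan), `features` (balanced training
#'   events), `models` (named list of `fd_model`), `confusions` (named list
#'   of [confusion_matrix]) and `metrics` (data.frame, one row per family).
#' @export
run_pipeline <- function(recordings, seed = 1L,
                         families = c("NN", "SVM", "TREE", "RULES"),
                         config = default_run_config(), tune_runs = 10,
                         grid = FALSE, dataset = NULL) {
  stopifnot(length(recordings) > 0L)
  participants <- unique(vapply(recordings, `[[`, character(1), "participant_id"))
  if (!is.null(dataset)) stopifnot(length(dataset) == length(participants))
  plan <- make_folds(participants, "holdout", seed = seed, dataset = dataset,
                     holdout_frac = config$cv$holdout_frac)
  split <- fold_splits(plan)[[1L]]
  rec_part <- vapply(recordings, `[[`, character(1), "participant_id")
  train_rec <- recordings[rec_part %in% split$train]
  valid_rec <- recordings[rec_part %in% split$test]

  ocfg <- do.call(opt_config, config$optimizer[intersect(
    names(config$optimizer), names(formals(opt_config)))])
  tuning <- tune_threshold(train_rec,
                           algorithm = config$optimizer$algorithm %||% "SA",
                           runs = tune_runs, seed = seed, config = ocfg,
                           quiet_ms = config$peak$quiet_ms)
  th <- tuning$median_threshold

  pcfg <- peak_config(th1 = th, quiet_ms = config$peak$quiet_ms,
                      burst = config$peak$burst)
  thr <- do.call(feature_thresholds, config$features[intersect(
    names(config$features), names(formals(feature_thresholds)))])
  events <- extract_cohort_features(train_rec, pcfg, thr)
  if (length(unique(events$label)) < 2L)
    stop("training events contain a single class; cannot train classifiers")
  balanced <- smote_balance(events, target = config$balancing$target,
                            k = config$balancing$k, seed = seed)

  models <- list(); confusions <- list(); metrics <- list()
  for (fam in families) {
    params <- list()
    if (grid) {
      ggrid <- expand.grid(config$grids[[fam]])
      inner <- make_folds(unique(events$participant_id), "five_two",
                          seed = seed)
      params <- grid_search(fam, ggrid, balanced, inner, seed = seed)$params
    }
    m <- train_classifier(fam, balanced, params, seed = seed)
    cm <- validate_end_to_end(m, valid_rec, pcfg, thr)
    models[[fam]] <- m
    confusions[[fam]] <- cm
    metrics[[fam]] <- cbind(family = fam,
                            suppressWarnings(classification_metrics(cm)))
  }
  met <- do.call(rbind, metrics)
  rownames(met) <- NULL
  list(threshold = th, tuning = tuning, holdout = plan, features = balanced,
       models = models, confusions = confusions, metrics = met)
}
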