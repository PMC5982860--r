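test_that("metrics handle degenerate confusion matrices with warnings", {
  m <- suppressWarnings(classification_metrics(confusion_matrix(0, 0, 0, 10)))
  expect_equal(m$Acc, 1)
  expect_equal(m$Sp, 1)
  expect_true(is.nan(m$Se))
  w <- capture_warnings(classification_metrics(confusion_matrix(0, 0, 0, 10)))
  expect_match(w, "sensitivity", all = FALSE)
  expect_match(w, "precision", all = FALSE)
  expect_error(confusion_matrix(-1, 0, 0, 2), "non-negative")
  expect_error(confusion_matrix(0, 0, 0, 0), "at least one")
  # G^2 = Se * Sp exactly
  m2 <- classification_metrics(confusion_matrix(7, 3, 2, 11))
  expect_equal(m2$G^2, m2$Se * m2$Sp)
})

test_that("fold plans never split a participant across train and test", {
  parts <- sprintf("P%02d", 1:20)
  ten <- make_folds(parts, "kfold10", seed = 4)
  expect_equal(as.vector(table(ten$assignments$fold)), rep(2L, 10))
  five2 <- make_folds(parts, "five_two", seed = 4)
  for (plan in list(ten, five2)) {
    for (sp in fold_splits(plan)) {
      expect_length(intersect(sp$train, sp$test), 0L)
      expect_setequal(c(sp$train, sp$test), parts)
    }
  }
  # each 5x2 repetition covers every participant exactly once per side
  a <- five2$assignments
  for (r in 1:5) expect_setequal(a$participant[a$rep == r], parts)
})

test_that("hold-out reserves the ceiling of 15% per source dataset", {
  parts <- sprintf("P%02d", 1:17)
  hold <- make_folds(parts, "holdout", seed = 1)
  expect_equal(sum(hold$assignments$role == "validation"), ceiling(0.15 * 17))
  # per-dataset reservation
  ds <- rep(c("A", "B"), c(10, 7))
  hold2 <- make_folds(parts, "holdout", seed = 1, dataset = ds)
  a <- hold2$assignments
  expect_equal(sum(a$role == "validation" & a$dataset == "A"), ceiling(0.15 * 10))
  expect_equal(sum(a$role == "validation" & a$dataset == "B"), ceiling(0.15 * 7))
  expect_error(make_folds(sprintf("P%d", 1:5), "kfold10"), "at least")
  expect_identical(make_folds(parts, "five_two", seed = 9)$assignments,
                   make_folds(parts, "five_two", seed = 9)$assignments)
})

sep_clusters <- function(n_per_class = 40, seed = 1) {
  rbind(random_feature_rows(n_per_class, "FALL", seed, shift = 3),
        random_feature_rows(n_per_class, "NOT_FALL", seed + 1, shift = -3))
}

test_that("all four families fit separable clusters perfectly", {
  ds <- sep_clusters(seed = 31)
  for (fam in c("NN", "SVM", "TREE", "RULES")) {
    m <- train_classifier(fam, ds, seed = 3)
    pred <- predict(m, ds)
    expect_equal(mean(pred == ds$label), 1.0, info = fam)
  }
  expect_error(train_classifier("NN", random_feature_rows(10, "FALL", 1)),
               "both classes")
})

test_that("tree and rule learners recover a one-feature rule on held-out points", {
  set.seed(17)
  n <- 120
  x <- random_feature_rows(n, "FALL", 17)
  x$MPI <- runif(n, 1, 5)
  x$label <- ifelse(x$MPI > 3, "FALL", "NOT_FALL")
  grid_rows <- x[1:40, ]
  grid_rows$MPI <- seq(1.05, 4.95, length.out = 40)
  grid_rows$label <- ifelse(grid_rows$MPI > 3, "FALL", "NOT_FALL")
  for (fam in c("TREE", "RULES")) {
    m <- train_classifier(fam, x, seed = 5)
    # away from the learned cut the rule must be reproduced exactly
    keep <- abs(grid_rows$MPI - 3) > 0.15
    expect_equal(mean(predict(m, grid_rows[keep, ]) == grid_rows$label[keep]),
                 1.0, info = fam)
  }
})

test_that("label-shuffled features give chance-level test performance", {
  ds <- sep_clusters(n_per_class = 60, seed = 41)
  set.seed(99)
  ds$label <- sample(ds$label)
  plan <- make_folds(unique(ds$participant_id), "five_two", seed = 7)
  gs <- vapply(fold_splits(plan), function(sp) {
    tr <- ds[ds$participant_id %in% sp$train, ]
    te <- ds[ds$participant_id %in% sp$test, ]
    m <- train_classifier("TREE", tr, seed = 1)
    cm <- tally_confusion(predict(m, te), te$label)
    se <- if (cm$tp + cm$fn == 0) 0 else cm$tp / (cm$tp + cm$fn)
    sp_ <- if (cm$tn + cm$fp == 0) 0 else cm$tn / (cm$tn + cm$fp)
    sqrt(se * sp_)
  }, numeric(1))
  expect_lt(abs(mean(gs) - 0.5), 0.2)
})

test_that("grid search picks the working configuration deterministically", {
  ds <- sep_clusters(seed = 51)
  plan <- make_folds(unique(ds$participant_id), "five_two", seed = 2)
  one <- grid_search("SVM", data.frame(sigma = 0.2, C = 1), ds, plan)
  expect_equal(one$params$C, 1)
  # a near-zero-capacity SVM loses to a reasonable one on separable data
  two <- grid_search("SVM", data.frame(sigma = c(0.2, 1e4), C = c(1, 1e-4)),
                     ds, plan, seed = 3)
  expect_equal(two$params$sigma, 0.2)
  expect_identical(
    grid_search("TREE", data.frame(trials = c(1, 3), cp = 0.01), ds, plan)$params,
    grid_search("TREE", data.frame(trials = c(1, 3), cp = 0.01), ds, plan)$params)
})

test_that("end-to-end validation reduces to peak detection under always-FALL", {
  coh <- generate_cohort(n_participants = 4, recordings_per_participant = 5,
                         fall_fraction = 0.4, rate_set = 50, seed = 13)
  cfg <- peak_config(th1 = 2.6)
  cm <- validate_end_to_end("always_fall", coh$recordings, cfg)
  # equivalent recording-level tally computed through the fitness path
  detected <- vapply(coh$recordings,
                     function(r) length(detect_peaks(r, cfg)) > 0, logical(1))
  truth <- vapply(coh$recordings, `[[`, character(1), "label")
  expect_equal(cm$tp, sum(detected & truth == "FALL"))
  expect_equal(cm$fp, sum(detected & truth == "NOT_FALL"))
  expect_equal(cm$fn, sum(!detected & truth == "FALL"))
  expect_equal(cm$tn, sum(!detected & truth == "NOT_FALL"))
  # no exceedance anywhere: everything predicted NOT_FALL
  quiet <- lapply(1:4, function(i)
    accel_ts(t = (0:99) * 20, a = rep(1, 100), sampling_hz = 50,
             participant_id = "Q", label = "NOT_FALL",
             recording_id = paste0("Q", i)))
  cmq <- validate_end_to_end("always_fall", quiet, cfg)
  expect_equal(cmq$tp + cmq$fp, 0L)
})

test_that("a ground-truth-fed model is limited only by detection", {
  coh <- generate_cohort(n_participants = 5, recordings_per_participant = 4,
                         fall_fraction = 0.5, rate_set = 100, seed = 23,
                         adl_kinds = c("JUMPING", "SITTING"), noise_sigma = 0)
  feats <- extract_cohort_features(coh$recordings, peak_config(th1 = 2.5))
  m <- train_classifier("TREE", feats, list(cp = 0.001, minsplit = 2), seed = 2)
  cm <- validate_end_to_end(m, coh$recordings, peak_config(th1 = 2.5))
  truth <- vapply(coh$recordings, `[[`, character(1), "label")
  maxima <- vapply(coh$recordings, function(r) max(r$a), numeric(1))
  expect_equal(cm$fn, sum(truth == "FALL" & maxima <= 2.5))
})
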