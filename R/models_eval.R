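#' Confusion matrix for recording- or event-level classification
#'
#' @param tp,fp,fn,tn non-negative integer counts (positive class = FALL).
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) < 1) stop("confusion matrix must contain at least one case")
  counts <- as.list(stats::setNames(as.integer(round(counts)), names(counts)))
  structure(counts, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c("FALL", "NOT_FALL"),
                              reference = c("FALL", "NOT_FALL")))
  print(m)
  invisible(x)
}

#' Tally predictions against truth
#'
#' @param predicted,truth character or factor vectors of `"FALL"` /
#'   `"NOT_FALL"` labels of equal length.
#' @return a [confusion_matrix].
#' @export
tally_confusion <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  confusion_matrix(tp = sum(predicted == "FALL" & truth == "FALL"),
                   fp = sum(predicted == "FALL" & truth == "NOT_FALL"),
                   fn = sum(predicted == "NOT_FALL" & truth == "FALL"),
                   tn = sum(predicted == "NOT_FALL" & truth == "NOT_FALL"))
}

#' Classification statistics from a confusion matrix
#'
#' Computes accuracy, Cohen's kappa, sensitivity, specificity, precision and
#' the geometric mean `G = sqrt(Se * Sp)`. Kappa uses the standard normalised
#' form `(p0 - pe) / (1 - pe)` with observed agreement `p0 = (TP + TN) / N`
#' and chance agreement
#' `pe = ((TP + FN)(TP + FP) + (TN + FP)(TN + FN)) / N^2`.
#' Any 0/0 ratio (e.g. sensitivity with no positive cases) is returned as
#' `NaN` with a warning rather than silently coerced.
#'
#' @param cm a [confusion_matrix].
#' @return data.frame with one row and columns `Acc`, `Kp`, `Se`, `Sp`,
#'   `Pr`, `G`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is undefined (0/0)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  acc <- (tp + tn) / n
  p0 <- acc
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kp <- if (pe == 1) NaN else (p0 - pe) / (1 - pe)
  se <- ratio(tp, tp + fn, "sensitivity")
  sp <- ratio(tn, tn + fp, "specificity")
  pr <- ratio(tp, tp + fp, "precision")
  data.frame(Acc = acc, Kp = kp, Se = se, Sp = sp, Pr = pr, G = sqrt(se * sp))
}

#' Participant-wise fold plans
#'
#' Builds cross-validation plans in which all recordings of a participant
#' stay on one side of every split, preventing identity leakage:
#' \describe{
#'   \item{holdout}{reserves `ceiling(holdout_frac * n)` participants per
#'     source dataset for validation (default 15%), the rest for
#'     training/testing.}
#'   \item{kfold10}{partitions participants into `k` near-equal folds.}
#'   \item{five_two}{5 repetitions of a random half/half participant split,
#'     yielding 10 (repetition, half) train/test pairs.}
#' }
#'
#' @param participants character vector of distinct participant ids.
#' @param scheme `"kfold10"`, `"five_two"` or `"holdout"`.
#' @param seed integer seed; plans are reproducible.
#' @param dataset optional factor of the same length as `participants`
#'   naming each participant's source dataset; the hold-out fraction is
#'   applied per dataset. Ignored by the other schemes.
#' @param holdout_frac fraction of participants reserved for validation.
#' @param k number of folds for `"kfold10"`.
#' @return an object of class `fold_plan` with an `assignments` data.frame:
#'   `participant` plus `fold` (kfold10), `rep`/`half` (five_two) or `role`
#'   (holdout).
#' @export
make_folds <- function(participants, scheme = c("kfold10", "five_two", "holdout"),
                       seed = 1L, dataset = NULL, holdout_frac = 0.15, k = 10) {
  scheme <- match.arg(scheme)
  participants <- as.character(participants)
  if (anyDuplicated(participants)) stop("participant ids must be distinct")
  n <- length(participants)
  assignments <- with_seed(seed, switch(
    scheme,
    holdout = {
      if (n < 2L) stop("holdout needs at least 2 participants")
      if (is.null(dataset)) dataset <- rep("all", n)
      stopifnot(length(dataset) == n)
      role <- rep("train_test", n)
      for (d in unique(dataset)) {
        idx <- which(dataset == d)
        n_val <- ceiling(holdout_frac * length(idx))
        role[sample(idx, n_val)] <- "validation"
      }
      data.frame(participant = participants, dataset = as.character(dataset),
                 role = role)
    },
    kfold10 = {
      if (n < k) stop(sprintf("kfold10 needs at least %d participants", k))
      perm <- sample(participants)
      # fold of a participant = its position in the shuffled order, round-robin
      fold <- rep_len(seq_len(k), n)[match(participants, perm)]
      data.frame(participant = participants, fold = fold)
    },
    five_two = {
      if (n < 2L) stop("five_two needs at least 2 participants")
      reps <- lapply(seq_len(5L), function(r) {
        perm <- sample(participants)
        half <- ifelse(match(participants, perm) <= n / 2, 1L, 2L)
        data.frame(participant = participants, rep = r, half = half)
      })
      do.call(rbind, reps)
    }))
  structure(list(scheme = scheme, assignments = assignments, seed = seed),
            class = "fold_plan")
}

#' Train/test participant pairs implied by a fold plan
#'
#' Expands a `fold_plan` into a list of splits, each a list with `train` and
#' `test` participant-id vectors. For `kfold10` fold *i* is tested against
#' the rest; for `five_two` each (repetition, half) is tested in turn; for
#' `holdout` the single split is train/test = `train_test`, test =
#' `validation`.
#'
#' @param plan a [make_folds()] result.
#' @return list of splits.
#' @export
fold_splits <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  a <- plan$assignments
  switch(plan$scheme,
    kfold10 = lapply(sort(unique(a$fold)), function(f)
      list(train = a$participant[a$fold != f], test = a$participant[a$fold == f])),
    five_two = {
      out <- list()
      for (r in sort(unique(a$rep))) for (h in 1:2) {
        sel <- a$rep == r
        out[[length(out) + 1L]] <-
          list(train = a$participant[sel & a$half != h],
               test = a$participant[sel & a$half == h],
               rep = r, half = h)
      }
      out
    },
    holdout = list(list(train = a$participant[a$role == "train_test"],
                        test = a$participant[a$role == "validation"])))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Train a fall/not-fall classifier on an event dataset
#'
#' Four families behind one contract:
#' \describe{
#'   \item{NN}{single-hidden-layer feed-forward network
#'     (\code{nnet::nnet}); hyperparameters `size` (default 20), `decay`
#'     (1e-4), `maxit` (500). Features are z-scored internally.}
#'   \item{SVM}{Gaussian-kernel support vector machine
#'     (\code{kernlab::ksvm}); hyperparameters `sigma` (0.2) and `C` (1).
#'     Features are z-scored internally.}
#'   \item{TREE}{committee of `trials` CART trees (\code{rpart}), the first
#'     grown on the full data and the rest on bootstrap resamples, predicting
#'     by majority vote; hyperparameters `trials` (1), `cp` (0.01),
#'     `minsplit` (5).}
#'   \item{RULES}{ordered rule list distilled from the same committee's
#'     trees: each leaf becomes a conjunctive rule, rules are ordered by
#'     training purity then brevity, and the first matching rule fires
#'     (majority-class default).}
#' }
#'
#' @param family one of `"NN"`, `"SVM"`, `"TREE"`, `"RULES"`.
#' @param features data.frame with the eight feature columns and a `label`
#'   column containing both classes.
#' @param params named list of family hyperparameters (see above).
#' @param seed integer seed controlling any stochastic part of training.
#' @return an object of class `fd_model` usable with [predict()].
#' @export
train_classifier <- function(family = c("NN", "SVM", "TREE", "RULES"),
                             features, params = list(), seed = 1L) {
  family <- match.arg(family)
  fn <- feature_names()
  stopifnot(all(fn %in% names(features)), "label" %in% names(features))
  y <- factor(as.character(features$label), levels = c("FALL", "NOT_FALL"))
  if (nlevels(droplevels(y)) < 2L)
    stop("training data must contain both classes")
  x <- as.matrix(features[, fn])
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")

  fit <- with_seed(seed, switch(
    family,
    NN = nnet::nnet(z, nnet::class.ind(y),
                    size = params$size %||% 20,
                    decay = params$decay %||% 1e-4,
                    maxit = params$maxit %||% 500,
                    softmax = TRUE, trace = FALSE),
    SVM = kernlab::ksvm(z, y, kernel = "rbfdot",
                        kpar = list(sigma = params$sigma %||% 0.2),
                        C = params$C %||% 1, scaled = FALSE),
    TREE = fit_tree_committee(x, y, params),
    RULES = {
      committee <- fit_tree_committee(x, y, params)
      lapply(committee, tree_to_rules)
    }))
  structure(list(family = family, fit = fit, center = ctr, scale = scl,
                 params = params, levels = c("FALL", "NOT_FALL")),
            class = "fd_model")
}

fit_tree_committee <- function(x, y, params) {
  trials <- params$trials %||% 1
  cp <- params$cp %||% 0.01
  minsplit <- params$minsplit %||% 5
  df <- data.frame(x, label = y, check.names = FALSE)
  lapply(seq_len(trials), function(i) {
    d <- if (i == 1L) df else {
      # bootstrap resample, retried (bounded) until both classes survive
      for (try in 1:25) {
        idx <- sample.int(nrow(df), replace = TRUE)
        if (length(unique(df$label[idx])) == 2L) break
      }
      df[idx, ]
    }
    rpart::rpart(label ~ ., data = d, method = "class",
                 control = rpart::rpart.control(cp = cp, minsplit = minsplit,
                                                xval = 0))
  })
}

# flatten an rpart tree into an ordered conjunctive rule list
tree_to_rules <- function(tree) {
  frame <- tree$frame
  leaves <- which(frame$var == "<leaf>")
  if (length(leaves) == 0L)
    return(list(default = levels(tree$y)[1L], rules = list()))
  ylev <- attr(tree, "ylevels")
  rules <- lapply(leaves, function(i) {
    node <- as.integer(rownames(frame)[i])
    path <- rpart::path.rpart(tree, node, print.it = FALSE)[[1L]][-1L]
    cls <- ylev[frame$yval[i]]
    n <- frame$n[i]
    purity <- max(frame$yval2[i, 4:5]) # class probabilities at the leaf
    list(conds = path, class = cls, n = n, purity = purity)
  })
  ord <- order(-vapply(rules, `[[`, numeric(1), "purity"),
               vapply(rules, function(r) length(r$conds), integer(1)),
               -vapply(rules, `[[`, numeric(1), "n"))
  default <- ylev[which.max(tabulate(as.integer(tree$y), nbins = length(ylev)))]
  list(default = default, rules = rules[ord])
}

apply_rule_list <- function(rl, newdata) {
  n <- nrow(newdata)
  pred <- rep(rl$default, n)
  undecided <- rep(TRUE, n)
  env <- as.list(newdata)
  for (r in rl$rules) {
    if (!any(undecided)) break
    match_all <- rep(TRUE, n)
    for (cond in r$conds) {
      ok <- try(eval(parse(text = cond), envir = env), silent = TRUE)
      if (inherits(ok, "try-error")) ok <- rep(FALSE, n)
      ok[is.na(ok)] <- FALSE
      match_all <- match_all & ok
    }
    hit <- undecided & match_all
    pred[hit] <- r$class
    undecided[hit] <- FALSE
  }
  pred
}

#' Predict FALL / NOT_FALL labels for feature rows
#'
#' @param object an `fd_model` from [train_classifier()].
#' @param newdata data.frame containing the eight feature columns.
#' @param ... unused.
#' @return factor of predictions with levels `FALL`, `NOT_FALL`.
#' @method predict fd_model
#' @export
predict.fd_model <- function(object, newdata, ...) {
  fn <- feature_names()
  x <- as.matrix(newdata[, fn, drop = FALSE])
  z <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  lev <- object$levels
  pred <- switch(
    object$family,
    NN = {
      p <- stats::predict(object$fit, z)
      colnames(p)[max.col(p, ties.method = "first")]
    },
    SVM = as.character(kernlab::predict(object$fit, z)),
    TREE = committee_vote(object$fit, as.data.frame(x), lev),
    RULES = {
      votes <- vapply(object$fit, function(rl)
        apply_rule_list(rl, as.data.frame(x)), character(nrow(x)))
      votes <- matrix(votes, nrow = nrow(x))
      apply(votes, 1L, function(v) lev[which.max(tabulate(match(v, lev),
                                                          nbins = 2L))])
    })
  factor(pred, levels = lev)
}

committee_vote <- function(trees, newdata, lev) {
  votes <- vapply(trees, function(tr)
    as.character(stats::predict(tr, newdata, type = "class")),
    character(nrow(newdata)))
  votes <- matrix(votes, nrow = nrow(newdata))
  apply(votes, 1L, function(v) lev[which.max(tabulate(match(v, lev), nbins = 2L))])
}

#' Grid search over classifier hyperparameters
#'
#' Trains one model per grid row per fold split and selects the row with the
#' highest mean test-fold geometric mean G (0/0 treated as 0 for ranking).
#' The grid is sorted ascending on its numeric columns before the search, so
#' ties are resolved in favour of the simpler model (fewer units, smaller C,
#' fewer trials).
#'
#' @param family classifier family, see [train_classifier()].
#' @param grid data.frame; each row a hyperparameter combination.
#' @param features event dataset with `participant_id` and `label`.
#' @param plan a participant-wise [make_folds()] plan over the participants
#'   present in `features`.
#' @param seed integer seed.
#' @return list with `params` (best row as a list), `mean_G`, and `table`
#'   (mean G per grid row).
#' @export
grid_search <- function(family, grid, features, plan, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  num_cols <- names(grid)[vapply(grid, is.numeric, logical(1))]
  if (length(num_cols))
    grid <- grid[do.call(order, grid[num_cols]), , drop = FALSE]
  splits <- fold_splits(plan)
  mean_g <- vapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    gs <- vapply(splits, function(sp) {
      tr <- features[features$participant_id %in% sp$train |
                       isTRUE_vec(features$synthetic), , drop = FALSE]
      te <- features[features$participant_id %in% sp$test, , drop = FALSE]
      if (nrow(te) == 0L || length(unique(tr$label)) < 2L) return(NA_real_)
      m <- train_classifier(family, tr, params, seed = seed)
      cm <- tally_confusion(predict(m, te), te$label)
      se <- if (cm$tp + cm$fn == 0L) 0 else cm$tp / (cm$tp + cm$fn)
      sp_ <- if (cm$tn + cm$fp == 0L) 0 else cm$tn / (cm$tn + cm$fp)
      sqrt(se * sp_)
    }, numeric(1))
    mean(gs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(mean_g)
  list(params = as.list(grid[best, , drop = FALSE]),
       mean_G = mean_g[best],
       table = cbind(grid, mean_G = mean_g))
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' End-to-end recording-level validation
#'
#' Runs the full detection pipeline on labelled recordings: a recording is
#' predicted FALL when at least one peak is detected at the chosen threshold
#' and any detected peak's feature vector is classified FALL by the model;
#' otherwise NOT_FALL. Tallied against the recording labels.
#'
#' @param model an `fd_model` (or the string `"always_fall"`, an oracle that
#'   labels every detected peak FALL, reducing the pipeline to pure peak
#'   detection).
#' @param recordings list of labelled [accel_ts].
#' @param config a [peak_config] carrying the chosen threshold.
#' @param thr a [feature_thresholds].
#' @return a [confusion_matrix].
#' @export
validate_end_to_end <- function(model, recordings, config = peak_config(),
                                thr = feature_thresholds()) {
  preds <- vapply(recordings, function(r) {
    feats <- extract_features(r, config, thr)
    if (nrow(feats) == 0L) return("NOT_FALL")
    if (identical(model, "always_fall")) return("FALL")
    if (any(predict(model, feats) == "FALL")) "FALL" else "NOT_FALL"
  }, character(1))
  truth <- vapply(recordings, function(r) r$label, character(1))
  tally_confusion(preds, truth)
}
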