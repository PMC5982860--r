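#' Balance an event dataset with SMOTE
#'
#' Synthetic minority oversampling: new minority rows are generated as
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of the `k`
#' nearest minority neighbours of `x` (Euclidean distance on the eight
#' features after z-scoring them on the minority rows, since the raw feature
#' scales differ by orders of magnitude — milliseconds versus g). The
#' interpolation itself is done on the raw feature scale, so every synthetic
#' row is a convex combination of two original minority rows. Rows are added
#' until the minority class reaches at least `target` of the dataset; a
#' dataset already at or past the target is returned unchanged.
#'
#' @param features data.frame of feature rows as produced by
#'   [extract_cohort_features()]; must contain the eight feature columns and
#'   a `label` column with both classes eventually present.
#' @param target minimum minority fraction, in (0, 0.5\]. Default 0.40,
#'   i.e. at least a 40/60 split.
#' @param k number of nearest minority neighbours considered, reduced to the
#'   available count when the minority class is small. Default 5, the
#'   classical SMOTE choice.
#' @param seed integer seed making the augmentation reproducible.
#' @return the input data.frame plus synthetic minority rows. A logical
#'   `synthetic` column marks generated rows; synthetic rows carry no
#'   recording provenance (`participant_id` and `recording_id` are `NA`) and
#'   `NA` anchor times and flags.
#' @export
smote_balance <- function(features, target = 0.40, k = 5, seed = 1L) {
  stopifnot(is.data.frame(features))
  if (!("label" %in% names(features))) stop("features must have a 'label' column")
  if (!is.numeric(target) || target <= 0 || target >= 1)
    stop("target must be a fraction in (0, 1); values above 0.5 invert the classes")
  if (k < 1) stop("k must be at least 1")
  if (!("synthetic" %in% names(features)))
    features$synthetic <- rep(FALSE, nrow(features))
  counts <- table(features$label)
  if (length(counts) < 2L) stop("both classes must be present to balance")
  minority <- names(counts)[which.min(counts)]
  n_min <- as.integer(min(counts))
  n_maj <- as.integer(sum(counts) - n_min)
  if (n_min / (n_min + n_maj) >= target) return(features)
  if (n_min < 2L) stop("minority class has a single row; no neighbour to interpolate with")

  need <- ceiling((target * (n_min + n_maj) - n_min) / (1 - target))
  fn <- feature_names()
  x <- as.matrix(features[features$label == minority, fn, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  d <- as.matrix(stats::dist(z))
  diag(d) <- Inf
  k_eff <- min(k, n_min - 1L)
  # k nearest minority neighbours per row; distance ties broken by row order
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d[i, ])[seq_len(k_eff)]))

  base <- rep_len(seq_len(n_min), need)
  syn <- with_seed(seed, {
    pick <- nn[cbind(base, sample.int(k_eff, need, replace = TRUE))]
    u <- stats::runif(need)
    x[base, , drop = FALSE] + u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
  })

  new_rows <- features[rep.int(1L, need), , drop = FALSE]
  new_rows[, fn] <- syn
  new_rows$label <- minority
  new_rows$synthetic <- TRUE
  for (col in intersect(c("pt", "is", "ie", "ps", "pe"), names(new_rows)))
    new_rows[[col]] <- NA_real_
  for (col in intersect(c("ie_defaulted", "is_defaulted", "ffi_defaulted",
                          "aamv_degenerate"), names(new_rows)))
    new_rows[[col]] <- NA
  for (col in intersect(c("participant_id", "recording_id"), names(new_rows)))
    new_rows[[col]] <- NA_character_
  out <- rbind(features, new_rows)
  rownames(out) <- NULL
  out
}
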