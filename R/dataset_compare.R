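#' Per-feature mean and standard deviation
#'
#' @param features data.frame with at least two rows containing the eight
#'   feature columns.
#' @return data.frame with columns `feature`, `mean`, `sd` (sample standard
#'   deviation, n - 1 denominator), one row per feature.
#' @export
feature_summary <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) < 2L) stop("need at least two rows to summarise")
  fn <- feature_names()
  stopifnot(all(fn %in% names(features)))
  data.frame(feature = fn,
             mean = vapply(features[fn], mean, numeric(1)),
             sd = vapply(features[fn], stats::sd, numeric(1)),
             row.names = NULL)
}

#' Compare two fall-feature collections feature by feature
#'
#' For each of the eight features: Shapiro-Wilk normality p-values within
#' each collection (the features are generally non-normal, which motivates a
#' rank test) and a two-sided Mann-Whitney-Wilcoxon test between the
#' collections. The rank test uses exact enumeration when both samples have
#' at most 20 observations and no ties, and the tie-corrected normal
#' approximation otherwise. A feature is flagged `different` when its
#' (optionally Holm-adjusted) rank-test p-value falls below `alpha`.
#'
#' @param a,b data.frames of feature rows, each with at least 3 rows.
#' @param alpha significance level for the per-feature verdict.
#' @param adjust `"none"` (default; raw per-feature p-values) or `"holm"`.
#' @return data.frame with one row per feature: means and standard
#'   deviations of both collections, `shapiro_p_a`, `shapiro_p_b` (NA with
#'   `constant_a`/`constant_b` flags when a collection is constant in that
#'   feature), `mww_p` and the logical `different`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05,
                                  adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("each collection needs at least 3 rows")
  fn <- feature_names()
  stopifnot(all(fn %in% names(a)), all(fn %in% names(b)))
  shapiro_p <- function(x) {
    if (length(unique(x)) == 1L || length(x) < 3L || length(x) > 5000L)
      return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  rows <- lapply(fn, function(f) {
    xa <- a[[f]]; xb <- b[[f]]
    exact <- length(xa) <= 20L && length(xb) <= 20L &&
      !anyDuplicated(c(xa, xb))
    p <- if (length(unique(c(xa, xb))) == 1L) 1 else suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
    data.frame(feature = f,
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               shapiro_p_a = shapiro_p(xa), shapiro_p_b = shapiro_p(xb),
               constant_a = length(unique(xa)) == 1L,
               constant_b = length(unique(xb)) == 1L,
               mww_p = p)
  })
  out <- do.call(rbind, rows)
  p_used <- if (adjust == "holm") stats::p.adjust(out$mww_p, "holm") else out$mww_p
  out$different <- !is.na(p_used) & p_used < alpha
  rownames(out) <- NULL
  out
}
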