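# Paired model comparison: two-sided Wilcoxon signed-rank tests per
# (metric, tissue), the star-annotation ladder, and the test-retest
# reliability protocol (the accuracy protocol with the second prediction
# in the ground-truth role).

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Classical conventions: zero differences are dropped, tied absolute
#' differences receive average ranks. For n <= 25 informative pairs the
#' p-value is exact, computed from the full null distribution of the
#' positive-rank sum over all 2^n sign assignments (evaluated by a
#' shift-convolution over doubled ranks, which enumerates the same
#' distribution without listing the assignments). For larger n a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n` (informative pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop_tabseg("wilcoxon_signed_rank: length mismatch")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_tabseg("wilcoxon_signed_rank: no informative pairs (all differences zero)")
  if (n < 5) stop_tabseg("wilcoxon_signed_rank: need >= 5 informative pairs, got %d", n)
  r <- rank(abs(d), ties.method = "average")
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # null distribution of 2*V over integer doubled ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    # f[w + 1] = #assignments with doubled positive-rank sum w
    f <- numeric(tot + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w <- round(2 * v)
    p_le <- sum(f[seq_len(w + 1)])
    p_ge <- sum(f[(w + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Significance star annotation
#'
#' The conventional ladder with strict inequalities: `ns` (p >= 0.05),
#' `*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001), `****` (p < 0.0001).
#'
#' @param p p-value in \[0, 1\].
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
stars <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop_tabseg("stars: p must be in [0, 1]")
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Pairwise comparison of two models' per-subject metrics
#'
#' One two-sided Wilcoxon signed-rank test per (metric, tissue) pair --
#' 18 tests for the 6 metrics x 3 tissues -- over the same subjects in the
#' same order. Comparisons where every paired difference is zero are
#' reported as `"ns (degenerate)"` with `NA` p-value. No multiple-testing
#' correction is applied by default (raw stars are reported across the 18
#' tests); set `holm = TRUE` to adjust with Holm's method.
#'
#' @param records_a,records_b lists of [evaluate_segmentation()] records
#'   for the same subjects under model A and model B.
#' @param holm apply Holm correction before assigning stars.
#' @return data.frame with columns `metric`, `tissue`, `statistic`,
#'   `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
compare_models <- function(records_a, records_b, holm = FALSE) {
  if (length(records_a) != length(records_b)) {
    stop_tabseg("compare_models: subject count mismatch (%d vs %d)",
                length(records_a), length(records_b))
  }
  rows_a <- do.call(rbind, lapply(records_a, metrics_as_row))
  rows_b <- do.call(rbind, lapply(records_b, metrics_as_row))
  out <- do.call(rbind, lapply(colnames(rows_a), function(cn) {
    parts <- strsplit(cn, "_")[[1]]
    a <- rows_a[, cn]; b <- rows_b[, cn]
    res <- tryCatch(wilcoxon_signed_rank(a, b), error = function(e) NULL)
    data.frame(metric = parts[1], tissue = parts[2],
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               stars = if (is.null(res)) "ns (degenerate)" else NA_character_,
               mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  p <- out$p_value
  if (holm) p[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "holm")
  need <- is.na(out$stars)
  out$stars[need] <- vapply(p[need], stars, "")
  out
}

#' Test-retest reliability of model outputs on repeated scans
#'
#' Applies the accuracy evaluation with the second prediction playing the
#' ground-truth role: the record quantifies agreement between the two
#' outputs on same-anatomy rescans, not accuracy. A reliable model yields
#' near-identical segmentations, i.e. retest Dice close to 1.
#'
#' @param pred_a,pred_b predicted [tissue_prob_map()]s for the two scans.
#' @param mask shared [brain_mask()].
#' @return a `metrics_record`, as [evaluate_segmentation()].
#' @export
retest_similarity <- function(pred_a, pred_b, mask) {
  evaluate_segmentation(pred_a, pred_b, mask)
}
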