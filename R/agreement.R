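#' Paired volume measurements
#'
#' Container for two paired sets of per-kidney volumes, e.g. two observers'
#' measurements of the same kidneys, used by the agreement statistics.
#'
#' @param a,b Numeric vectors of volumes in ml, same length, no missing
#'   values, n >= 3.
#' @param labels Optional per-kidney identifiers.
#' @return An object of class `paired_volumes`.
#' @export
paired_volumes <- function(a, b, labels = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    err("unithresh_pairs_error", "paired vectors differ in length (%d vs %d)",
        length(a), length(b))
  if (length(a) < 3L)
    err("unithresh_pairs_error", "need at least 3 pairs, got %d", length(a))
  if (anyNA(a) || anyNA(b))
    err("unithresh_pairs_error", "paired volumes contain missing values")
  if (is.null(labels)) labels <- as.character(seq_along(a))
  structure(list(labels = labels, a = a, b = b, n = length(a)),
            class = "paired_volumes")
}

#' Paired t test and mean absolute difference
#'
#' Classical paired t test on `d = a - b` (two-tailed, n - 1 degrees of
#' freedom), with the 95% confidence interval of the mean difference from
#' the t quantile, plus the mean absolute difference (MAD), the secondary
#' agreement measure.
#'
#' @param pairs A [paired_volumes()].
#' @return List: `mean_diff`, `ci95` (lo, hi), `t_stat`, `p_value`, `mad`,
#'   `n`.
#' @export
paired_stats <- function(pairs) {
  d <- pairs$a - pairs$b
  if (stats::sd(d) <= 0 || !is.finite(stats::sd(d)))
    err("unithresh_degenerate_sample_error",
        "paired differences have zero variance")
  tt <- stats::t.test(pairs$a, pairs$b, paired = TRUE, conf.level = 0.95)
  list(mean_diff = unname(tt$estimate), ci95 = as.numeric(tt$conf.int),
       t_stat = unname(tt$statistic), p_value = tt$p.value,
       mad = mean(abs(d)), n = pairs$n)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param pairs A [paired_volumes()].
#' @return List: `pearson_r`, `ci95` (lo, hi), `p_value`.
#' @export
volume_correlation <- function(pairs) {
  if (stats::sd(pairs$a) <= 0 || stats::sd(pairs$b) <= 0)
    err("unithresh_degenerate_sample_error",
        "correlation undefined for a constant volume set")
  ct <- stats::cor.test(pairs$a, pairs$b, method = "pearson",
                        conf.level = 0.95)
  list(pearson_r = unname(ct$estimate), ci95 = as.numeric(ct$conf.int),
       p_value = ct$p.value)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean paired difference; the 95% limits of agreement are
#' `bias +/- 1.96 sd(d)`.  The returned per-pair plot data are the pair
#' means against the differences.
#'
#' @param pairs A [paired_volumes()].
#' @return An object of class `bland_altman`: `bias`, `loa_lo`, `loa_hi`,
#'   `sd_diff`, and `data` (a data.frame with `mean` and `diff` columns).
#' @export
bland_altman <- function(pairs) {
  d <- pairs$a - pairs$b
  s <- stats::sd(d)
  bias <- mean(d)
  structure(list(bias = bias, loa_lo = bias - 1.96 * s,
                 loa_hi = bias + 1.96 * s, sd_diff = s,
                 data = data.frame(label = pairs$labels,
                                   mean = (pairs$a + pairs$b) / 2,
                                   diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.2f ml, 95%% limits of agreement [%.2f, %.2f] ml\n",
              x$bias, x$loa_lo, x$loa_hi))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of pair (ml)",
                              ylab = "Difference (ml)", ...) {
  graphics::plot(x$data$mean, x$data$diff, xlab = xlab, ylab = ylab,
                 pch = 19, ...)
  graphics::abline(h = c(x$bias, x$loa_lo, x$loa_hi),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Full observer-agreement report
#'
#' Bundles the paired t test, Pearson correlation and Bland-Altman analysis
#' for one comparison of volume result sets.
#'
#' @param pairs A [paired_volumes()].
#' @return An object of class `agreement_report` with elements `paired`,
#'   `correlation`, `bland_altman` and `n`.
#' @export
agreement_report <- function(pairs) {
  structure(list(paired = paired_stats(pairs),
                 correlation = volume_correlation(pairs),
                 bland_altman = bland_altman(pairs),
                 n = pairs$n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  p <- x$paired; r <- x$correlation; ba <- x$bland_altman
  cat(sprintf("Agreement over %d kidney pairs\n", x$n))
  cat(sprintf("  mean difference %.2f ml (95%% CI [%.2f, %.2f]), t = %.3f, p = %.3g\n",
              p$mean_diff, p$ci95[1], p$ci95[2], p$t_stat, p$p_value))
  cat(sprintf("  mean absolute difference %.2f ml\n", p$mad))
  cat(sprintf("  Pearson r = %.3f (95%% CI [%.3f, %.3f])\n",
              r$pearson_r, r$ci95[1], r$ci95[2]))
  cat(sprintf("  Bland-Altman bias %.2f ml, limits [%.2f, %.2f] ml\n",
              ba$bias, ba$loa_lo, ba$loa_hi))
  invisible(x)
}
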