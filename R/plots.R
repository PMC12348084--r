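# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_boxplot
#'   labs theme_minimal scale_colour_brewer
NULL

#' @export
ggplot2::autoplot

#' Plot principal-component scores
#'
#' @param object A `qc_pca`.
#' @param colour_by Optional vector (e.g. self-reported group) aligned with
#'   the score table.
#' @param components Two score columns to plot.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot qc_pca
#' @export
autoplot.qc_pca <- function(object, colour_by = NULL,
                            components = c("PC1", "PC2"), ...) {
  df <- object$scores
  pct <- 100 * object$var_explained
  idx <- as.integer(sub("PC", "", components))
  if (!is.null(colour_by)) df$group <- colour_by
  p <- ggplot(df, aes(x = .data[[components[1]]], y = .data[[components[2]]]))
  p <- if (is.null(colour_by)) p + geom_point(alpha = 0.7) else
    p + geom_point(aes(colour = .data$group), alpha = 0.7)
  p +
    labs(x = sprintf("%s (%.1f%%)", components[1], pct[idx[1]]),
         y = sprintf("%s (%.1f%%)", components[2], pct[idx[2]]),
         colour = NULL) +
    theme_minimal()
}

#' Plot total ROH against inbreeding F with flagged outliers
#'
#' @param object Output of [loess_outliers()] (or a `roh_profile` run through
#'   it).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot roh_outliers
#' @export
autoplot.roh_outliers <- function(object, ...) {
  ggplot(object, aes(x = .data$f_inbreeding, y = .data$total_kb)) +
    geom_point(aes(colour = .data$outlier), alpha = 0.7) +
    geom_line(aes(y = .data$fitted), colour = "steelblue") +
    labs(x = "inbreeding coefficient F", y = "total ROH (kb)",
         colour = "low-ROH outlier") +
    theme_minimal()
}

#' Plot ROH/F outlier diagnostics from a data frame
#'
#' Convenience wrapper: accepts the tibble from [loess_outliers()].
#' @param data Tibble with `f_inbreeding`, `total_kb`, `fitted`, `outlier`.
#' @return A ggplot.
#' @export
plot_roh_outliers <- function(data) {
  class(data) <- c("roh_outliers", class(data))
  autoplot(data)
}

#' Missing-rate distribution by sample grouping
#'
#' @param dataset A [geno_dataset()].
#' @param grouping Sample-table column (e.g. `"specimen"`, `"site"`).
#' @return A ggplot (boxplot of per-sample missing rates per group).
#' @export
plot_missingness <- function(dataset, grouping = "specimen") {
  cr <- sample_call_rates(dataset)
  df <- tibble(missing_rate = 1 - cr$call_rate,
               group = dataset$samples[[grouping]])
  ggplot(df, aes(x = .data$group, y = .data$missing_rate)) +
    geom_boxplot() +
    labs(x = grouping, y = "per-sample missing rate") +
    theme_minimal()
}

#' Plot the stratified imputation-quality summary
#'
#' @param object An `imputation_summary` from [summarize_imputation()].
#' @param ... Ignored.
#' @return A ggplot: fraction of variants above each R2 threshold, one line
#'   per MAF bin.
#' @method autoplot imputation_summary
#' @export
autoplot.imputation_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$r2_threshold, y = .data$fraction,
                     colour = .data$maf_bin)) +
    geom_point() + geom_line() +
    labs(x = expression("imputation" ~ R^2 ~ "threshold"),
         y = "fraction of variants at/above threshold", colour = "MAF bin") +
    theme_minimal()
}
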