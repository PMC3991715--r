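#' Plot an arm-level LOH burden profile
#'
#' Bar chart of length-adjusted LOH burden per chromosome arm, optionally
#' faceted by sample.
#'
#' @param profiles One or more row-bound [arm_profile()] tibbles.
#' @return A ggplot object.
#' @export
plot_arm_profile <- function(profiles) {
  profiles$arm_label <- factor(profiles$arm_label,
                               levels = unique(profiles$arm_label[
                                 order(profiles$chrom, profiles$arm)]))
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$arm_label,
                                    y = .data$adjusted)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "chromosome arm",
                  y = "LOH tract length / arm length") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if ("sample" %in% names(profiles) &&
      length(unique(profiles$sample)) > 1) {
    p <- p + ggplot2::facet_wrap(~sample, ncol = 1)
  }
  p
}

#' Plot a stratified cohort arm summary
#'
#' Bars at the per-stratum median adjusted burden with first/third quartile
#' error bars, mirroring stage-stratified cohort displays.
#'
#' @param summary Output of [cohort_arm_summary()].
#' @return A ggplot object.
#' @export
plot_cohort_arm_summary <- function(summary) {
  summary$arm_label <- factor(summary$arm_label,
                              levels = unique(summary$arm_label[
                                order(summary$chrom, summary$arm)]))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$arm_label, y = .data$median,
                               fill = .data$stratum)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3) +
    ggplot2::labs(x = "chromosome arm",
                  y = "median LOH tract length / arm length",
                  fill = "stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot overlap-pattern class counts
#'
#' @param records Output of [classify_overlap()].
#' @return A ggplot object.
#' @export
plot_overlap_classes <- function(records) {
  counts <- dplyr::count(records, .data$class, .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "overlap class", y = "concurrent tract pairs") +
    ggplot2::theme_minimal()
}

#' Autoplot method for permutation test results
#'
#' Histogram of the null concurrence-rate distribution per direction, with
#' the observed rate marked.
#'
#' @param object An object of class `loh_permutation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.loh_permutation <- function(object, ...) {
  null_long <- tidyr::pivot_longer(object$null, -"iteration",
                                   names_to = "direction",
                                   values_to = "rate")
  obs <- object$observed
  ggplot2::ggplot(null_long, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey60") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$rate),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~direction, scales = "free") +
    ggplot2::labs(x = "concurrence rate", y = "permutations",
                  title = "Observed vs permutation null") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
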