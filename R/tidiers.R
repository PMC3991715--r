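#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test result
#'
#' @param x An object of class `loh_permutation`.
#' @param ... Unused.
#' @return Tibble with one row per direction: observed rate, null
#'   mean/min/max, and the empirical p-value.
#' @export
tidy.loh_permutation <- function(x, ...) {
  x$observed |>
    dplyr::mutate(
      null_mean = vapply(.data$direction, function(d) mean(x$null[[d]]),
                         numeric(1)),
      null_min = vapply(.data$direction, function(d) min(x$null[[d]]),
                        numeric(1)),
      null_max = vapply(.data$direction, function(d) max(x$null[[d]]),
                        numeric(1)),
      p_value = unname(x$p_value[.data$direction]))
}

#' Glance at a permutation test result
#'
#' @inheritParams tidy.loh_permutation
#' @return One-row tibble: permutation count, seed, shuffle mode and mean
#'   merge losses.
#' @export
glance.loh_permutation <- function(x, ...) {
  tibble::tibble(n_perm = x$config$n_perm,
                 seed = x$config$seed,
                 shuffle_which = x$config$shuffle_which,
                 merge_loss_low = x$merge_loss[["low"]],
                 merge_loss_high = x$merge_loss[["high"]])
}

#' Tidy an enrichment test result
#'
#' @param x An object of class `loh_enrichment`.
#' @param ... Unused.
#' @return One-row tibble with counts, proportions, the chi-square
#'   statistic and p-value.
#' @export
tidy.loh_enrichment <- function(x, ...) {
  tibble::tibble(category = x$category,
                 n_top = x$n_top, k_top = x$k_top,
                 observed_prop = x$observed_prop,
                 baseline_prop = x$baseline_prop,
                 baseline_mode = x$baseline_mode,
                 statistic = x$statistic, p_value = x$p_value,
                 unreliable = x$unreliable)
}

#' @rdname tidy.loh_enrichment
#' @export
glance.loh_enrichment <- function(x, ...) tidy.loh_enrichment(x)
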