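#' Configuration for the arm-constrained permutation test
#'
#' Tract locations are shuffled along their own autosomal arm, excluding a
#' 3 Mb zone adjacent to the centromere and a 10 kb zone at the telomeric
#' end of each arm; tracts that land overlapping are merged into one.
#'
#' @param n_perm Number of permutations (default 5000).
#' @param centromere_exclusion_bp Exclusion on the centromeric edge of each
#'   arm (default 3,000,000 bp).
#' @param arm_end_exclusion_bp Exclusion at the telomeric end of each arm
#'   (default 10,000 bp).
#' @param shuffle_which Which tract set(s) to shuffle each iteration:
#'   `"both"` (default), `"low_only"` or `"high_only"`.
#' @param seed Integer seed; all randomness in the test flows from it.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_perm = 5000, centromere_exclusion_bp = 3e6,
                        arm_end_exclusion_bp = 1e4,
                        shuffle_which = c("both", "low_only", "high_only"),
                        seed = 1L) {
  shuffle_which <- match.arg(shuffle_which)
  stopifnot(n_perm >= 1, centromere_exclusion_bp >= 0,
            arm_end_exclusion_bp >= 0)
  structure(list(n_perm = as.integer(n_perm),
                 centromere_exclusion_bp = centromere_exclusion_bp,
                 arm_end_exclusion_bp = arm_end_exclusion_bp,
                 shuffle_which = shuffle_which,
                 seed = as.integer(seed)),
            class = "perm_config")
}

#' Eligible placement interval of an arm
#'
#' The arm interval minus the centromere exclusion on its centromeric edge
#' (the edge nearer `centromere_boundary`) and the arm-end exclusion on its
#' telomeric edge.
#'
#' @param arms Arm table (see [assign_arm()]); `centromere_boundary` is
#'   required here.
#' @param config A [perm_config()].
#' @return `arms` with added columns `eligible_start`, `eligible_end`.
#'   Errors if any arm is exhausted by the exclusions.
#' @export
#' @examples
#' arms <- tibble::tibble(chrom = 1, arm = "p", start = 1, end = 5e7,
#'                        centromere_boundary = 5e7)
#' eligible_interval(arms, perm_config())[, c("eligible_start", "eligible_end")]
eligible_interval <- function(arms, config = perm_config()) {
  check_arm_table(arms)
  stopifnot("centromere_boundary" %in% names(arms))
  cent_at_end <- abs(arms$end - arms$centromere_boundary) <=
    abs(arms$start - arms$centromere_boundary)
  arms$eligible_start <- ifelse(cent_at_end,
                                arms$start + config$arm_end_exclusion_bp,
                                arms$start + config$centromere_exclusion_bp)
  arms$eligible_end <- ifelse(cent_at_end,
                              arms$end - config$centromere_exclusion_bp,
                              arms$end - config$arm_end_exclusion_bp)
  bad <- arms$eligible_start > arms$eligible_end
  if (any(bad)) {
    stop("exclusion zones exhaust arm(s): ",
         paste0(arms$chrom[bad], arms$arm[bad], collapse = ", "),
         call. = FALSE)
  }
  arms
}

#' Shuffle tract locations along their arms
#'
#' Each tract keeps its arm and its length; a new start is drawn uniformly
#' so the tract lies wholly inside the arm's eligible interval.  Tracts
#' placed overlapping are merged into their union.  A tract longer than its
#' arm's eligible interval is kept at its original location with a warning.
#'
#' @param tracts Tract tibble with columns `chrom`, `arm`, `start`, `end`.
#' @param arms Arm table with eligible intervals (computed here if absent).
#' @param config A [perm_config()] (exclusion zones only; the caller owns
#'   the RNG state).
#' @return Tibble of placed (merged) tracts: `chrom`, `arm`, `start`, `end`.
#' @export
shuffle_tracts <- function(tracts, arms, config = perm_config()) {
  if (!"eligible_start" %in% names(arms)) {
    arms <- eligible_interval(arms, config)
  }
  key <- paste0(arms$chrom, arms$arm)
  ti <- match(paste0(tracts$chrom, tracts$arm), key)
  if (anyNA(ti)) stop("tract on unannotated arm", call. = FALSE)
  len <- tracts$end - tracts$start + 1
  lo <- arms$eligible_start[ti]
  hi <- arms$eligible_end[ti] - len + 1
  too_long <- hi < lo
  if (any(too_long)) {
    warning(sum(too_long),
            " tract(s) longer than their eligible interval; kept in place")
  }
  n <- nrow(tracts)
  new_start <- tracts$start
  ok <- !too_long
  # uniform integer start in [lo, hi]
  new_start[ok] <- lo[ok] + floor(stats::runif(sum(ok)) * (hi[ok] - lo[ok] + 1))
  placed <- tibble::tibble(chrom = tracts$chrom, arm = tracts$arm,
                           start = new_start, end = new_start + len - 1)
  merge_tracts(placed)
}

# merge overlapping intervals within (chrom, arm) into their union
merge_tracts <- function(tracts) {
  if (nrow(tracts) < 2) return(tracts)
  tracts |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble::tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Permutation test of LOH concurrence
#'
#' Builds the null distribution of per-direction concurrence rates by
#' repeatedly shuffling tract locations along their arms
#' (see [shuffle_tracts()]) and recomputing the rates, then compares the
#' observed rates against it.  The one-sided empirical p-value uses the
#' standard `(b + 1) / (n_perm + 1)` estimator, where `b` counts null rates
#' at or above the observed.
#'
#' @param low,high Tract tibbles for the two samples of one patient.
#' @param arms Arm table with `centromere_boundary`.
#' @param config A [perm_config()]; `config$seed` makes the test
#'   reproducible.
#' @return Object of class `loh_permutation`: a list with `observed`
#'   (tibble from [concurrence_rate()]), `null` (tibble of per-iteration
#'   rates, `n_perm` rows), `p_value` (named vector per direction),
#'   `merge_loss` (mean fraction of tracts lost to merging per iteration,
#'   per set), and `config`.
#' @export
permutation_test <- function(low, high, arms, config = perm_config()) {
  if (nrow(low) == 0 || nrow(high) == 0) {
    stop("permutation test undefined for empty tract sets", call. = FALSE)
  }
  arms <- eligible_interval(arms, config)
  obs <- concurrence_rate(low, high)
  null_lo <- numeric(config$n_perm)
  null_hi <- numeric(config$n_perm)
  lost_lo <- numeric(config$n_perm)
  lost_hi <- numeric(config$n_perm)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(config$seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  for (i in seq_len(config$n_perm)) {
    a <- if (config$shuffle_which %in% c("both", "low_only")) {
      shuffle_tracts(low, arms, config)
    } else low
    b <- if (config$shuffle_which %in% c("both", "high_only")) {
      shuffle_tracts(high, arms, config)
    } else high
    pr <- overlap_pairs(a, b)
    null_lo[i] <- length(unique(pr$idx_low)) / nrow(a)
    null_hi[i] <- length(unique(pr$idx_high)) / nrow(b)
    lost_lo[i] <- 1 - nrow(a) / nrow(low)
    lost_hi[i] <- 1 - nrow(b) / nrow(high)
  }
  p_lo <- (1 + sum(null_lo >= obs$rate[obs$direction == "low_to_high"])) /
    (config$n_perm + 1)
  p_hi <- (1 + sum(null_hi >= obs$rate[obs$direction == "high_to_low"])) /
    (config$n_perm + 1)
  structure(list(
    observed = obs,
    null = tibble::tibble(iteration = seq_len(config$n_perm),
                          low_to_high = null_lo, high_to_low = null_hi),
    p_value = c(low_to_high = p_lo, high_to_low = p_hi),
    merge_loss = c(low = mean(lost_lo), high = mean(lost_hi)),
    config = config
  ), class = "loh_permutation")
}

#' @export
print.loh_permutation <- function(x, ...) {
  cat("Arm-constrained permutation test of LOH concurrence\n")
  cat("  permutations:", x$config$n_perm, " seed:", x$config$seed, "\n")
  for (d in x$observed$direction) {
    nr <- x$null[[d]]
    cat(sprintf(
      "  %s: observed %.4f | null mean %.4f [min %.4f, max %.4f] | p = %.3g\n",
      d, x$observed$rate[x$observed$direction == d],
      mean(nr), min(nr), max(nr), x$p_value[[d]]))
  }
  cat(sprintf("  mean tract loss to merging: low %.2f%%, high %.2f%%\n",
              100 * x$merge_loss[["low"]], 100 * x$merge_loss[["high"]]))
  invisible(x)
}
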