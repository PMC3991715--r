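#' Overlap length of two tract intervals
#'
#' Inclusive-coordinate overlap: 0 for different chromosomes or disjoint
#' intervals, else `min(ends) - max(starts) + 1`, so tracts sharing a single
#' position overlap by 1 bp.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Vectors describing the
#'   two interval sets (recycled to common length).
#' @return Numeric vector of overlap lengths in bp.
#' @export
#' @examples
#' overlap_length(1, 100, 200, 1, 200, 300)  # 1
overlap_length <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ov <- pmin(end_a, end_b) - pmax(start_a, start_b) + 1
  ifelse(chrom_a == chrom_b, pmax(ov, 0), 0)
}

#' Find concurrent LOH between two tract sets of one patient
#'
#' Concurrent LOH is a pair of tracts, one per set, with genomic overlap of
#' at least 1 bp.  Returns every overlapping pair plus per-tract concurrence
#' flags (a tract is concurrent iff it overlaps at least one tract of the
#' other set, regardless of how many).
#'
#' @param low,high Tract tibbles (as from [call_loh()]) for the lower- and
#'   higher-stage sample of one patient.  Must share a `patient` value when
#'   both carry one.
#' @return List with elements `pairs` (tibble of index pairs `idx_low`,
#'   `idx_high` and `overlap_bp`), `concurrent_low` and `concurrent_high`
#'   (logical vectors parallel to the input rows).
#' @export
find_concurrent <- function(low, high) {
  pl <- unique(stats::na.omit(low$patient))
  ph <- unique(stats::na.omit(high$patient))
  if (length(pl) == 1 && length(ph) == 1 && pl != ph) {
    stop("tract sets belong to different patients: ", pl, " vs ", ph,
         call. = FALSE)
  }
  pairs <- overlap_pairs(low, high)
  list(
    pairs = pairs,
    concurrent_low = seq_len(nrow(low)) %in% pairs$idx_low,
    concurrent_high = seq_len(nrow(high)) %in% pairs$idx_high
  )
}

# all index pairs with >=1 bp overlap, via IRanges per chromosome
overlap_pairs <- function(low, high) {
  if (nrow(low) == 0 || nrow(high) == 0) {
    return(tibble::tibble(idx_low = integer(), idx_high = integer(),
                          overlap_bp = numeric()))
  }
  res <- list()
  for (ch in intersect(unique(low$chrom), unique(high$chrom))) {
    il <- which(low$chrom == ch)
    ih <- which(high$chrom == ch)
    rl <- IRanges::IRanges(low$start[il], low$end[il])
    rh <- IRanges::IRanges(high$start[ih], high$end[ih])
    hits <- IRanges::findOverlaps(rl, rh, minoverlap = 1L)
    if (length(hits) == 0) next
    qi <- il[S4Vectors::queryHits(hits)]
    si <- ih[S4Vectors::subjectHits(hits)]
    res[[length(res) + 1]] <- tibble::tibble(
      idx_low = qi, idx_high = si,
      overlap_bp = overlap_length(low$chrom[qi], low$start[qi], low$end[qi],
                                  high$chrom[si], high$start[si],
                                  high$end[si]))
  }
  if (length(res) == 0) {
    return(tibble::tibble(idx_low = integer(), idx_high = integer(),
                          overlap_bp = numeric()))
  }
  dplyr::bind_rows(res) |> dplyr::arrange(.data$idx_low, .data$idx_high)
}

#' Per-direction LOH concurrence rates
#'
#' The A->B rate is the fraction of A-tracts that overlap at least one
#' B-tract; denominators count tracts, not pairs.
#'
#' @inheritParams find_concurrent
#' @return Tibble with columns `direction` (`"low_to_high"`,
#'   `"high_to_low"`), `n_tracts`, `n_concurrent`, `rate`.  The rate for an
#'   empty set is `NA` (undefined).
#' @export
concurrence_rate <- function(low, high) {
  fc <- find_concurrent(low, high)
  tibble::tibble(
    direction = c("low_to_high", "high_to_low"),
    n_tracts = c(nrow(low), nrow(high)),
    n_concurrent = c(sum(fc$concurrent_low), sum(fc$concurrent_high)),
  ) |>
    dplyr::mutate(rate = ifelse(.data$n_tracts > 0,
                                .data$n_concurrent / .data$n_tracts,
                                NA_real_))
}

#' Overlap pattern classes
#'
#' Concurrent tract pairs partition into six classes.  `EQUAL`: identical
#' start and end.  `EXA_S` / `EXB_S`: one shared endpoint, with the low- /
#' high-stage tract longer (single-end extension).  `EXA_D` / `EXB_D`: the
#' low- / high-stage tract strictly contains the other with both endpoints
#' differing (double-end extension).  `PARTIAL`: staggered overlap — both
#' endpoints differ and neither tract contains the other.
#'
#' @return Character vector of the six class labels.
#' @export
overlap_classes <- function() {
  c("EQUAL", "EXA_S", "EXA_D", "EXB_S", "EXB_D", "PARTIAL")
}

#' Classify overlapping tract pairs
#'
#' Classifies each concurrent pair into one of the six [overlap_classes()]
#' and decomposes its length: `extension_low` / `extension_high` are the
#' total bp by which the longer tract extends beyond the shared region;
#' `PARTIAL` pairs additionally record the combined non-shared footprint
#' `nonoverlap_bp`.
#'
#' @param low,high Tract tibbles, or one-row tibbles for a single pair.
#' @param pairs Optional tibble of index pairs (`idx_low`, `idx_high`) as
#'   returned by [find_concurrent()]; defaults to all overlapping pairs.
#' @return Tibble, one row per pair: indices, coordinates of both tracts,
#'   `class`, `overlap_bp`, `extension_low`, `extension_high`,
#'   `nonoverlap_bp`.
#' @export
#' @examples
#' a <- tibble::tibble(patient = "p", chrom = 1, start = 100, end = 250)
#' b <- tibble::tibble(patient = "p", chrom = 1, start = 100, end = 200)
#' classify_overlap(a, b)
classify_overlap <- function(low, high, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- overlap_pairs(low, high)
  }
  if (nrow(pairs) == 0) {
    return(tibble::tibble(idx_low = integer(), idx_high = integer(),
                          chrom = numeric(), start_low = numeric(),
                          end_low = numeric(), start_high = numeric(),
                          end_high = numeric(),
                          class = character(), overlap_bp = numeric(),
                          extension_low = numeric(),
                          extension_high = numeric(),
                          nonoverlap_bp = numeric()))
  }
  sl <- low$start[pairs$idx_low];  el <- low$end[pairs$idx_low]
  sh <- high$start[pairs$idx_high]; eh <- high$end[pairs$idx_high]
  ov <- pmin(el, eh) - pmax(sl, sh) + 1
  if (any(ov < 1)) {
    stop("classify_overlap requires overlapping pairs", call. = FALSE)
  }
  len_l <- el - sl + 1
  len_h <- eh - sh + 1
  s_eq <- sl == sh
  e_eq <- el == eh
  cls <- dplyr::case_when(
    s_eq & e_eq ~ "EQUAL",
    xor(s_eq, e_eq) & len_l > len_h ~ "EXA_S",
    xor(s_eq, e_eq) & len_h > len_l ~ "EXB_S",
    sl < sh & el > eh ~ "EXA_D",
    sh < sl & eh > el ~ "EXB_D",
    TRUE ~ "PARTIAL"
  )
  ext_l <- ifelse(cls %in% c("EXA_S", "EXA_D"), len_l - ov, 0)
  ext_h <- ifelse(cls %in% c("EXB_S", "EXB_D"), len_h - ov, 0)
  nov <- ifelse(cls == "PARTIAL", len_l + len_h - 2 * ov, 0)
  tibble::tibble(
    idx_low = pairs$idx_low, idx_high = pairs$idx_high,
    chrom = low$chrom[pairs$idx_low],
    start_low = sl, end_low = el, start_high = sh, end_high = eh,
    class = factor(cls, levels = overlap_classes()),
    overlap_bp = ov, extension_low = ext_l, extension_high = ext_h,
    nonoverlap_bp = nov)
}

#' Summarise overlap-pattern records
#'
#' Tallies overlap records by class and computes the change statistic
#' `prop_of_change = (Total - Equal) / Total`: the fraction of concurrent
#' pairs whose tract boundaries differ between the two samples.  Extension
#' totals are also expressed as fractions of each sample's total tract
#' length when those totals are supplied.
#'
#' @param records Output of [classify_overlap()].
#' @param total_length_low,total_length_high Optional total LOH tract
#'   lengths (bp) of the two samples, for the extension-fraction columns.
#' @return One-row tibble: per-class counts (`equal`, `exa_s`, `exa_d`,
#'   `exb_s`, `exb_d`, `partial`), `total`, `prop_of_change`, extension
#'   length sums (`exa_length_bp`, `exb_length_bp`) and fractions, and the
#'   partial-overlap decomposition (`pa_overlap_bp`, `pa_nonoverlap_bp`).
#'   `prop_of_change` is `NA` when there are no records.
#' @export
overlap_summary <- function(records, total_length_low = NA_real_,
                            total_length_high = NA_real_) {
  cls <- as.character(records$class)
  n <- nrow(records)
  n_equal <- sum(cls == "EQUAL")
  exa_len <- sum(records$extension_low)
  exb_len <- sum(records$extension_high)
  tibble::tibble(
    equal = n_equal,
    exa_s = sum(cls == "EXA_S"), exa_d = sum(cls == "EXA_D"),
    exb_s = sum(cls == "EXB_S"), exb_d = sum(cls == "EXB_D"),
    partial = sum(cls == "PARTIAL"),
    total = n,
    prop_of_change = if (n > 0) (n - n_equal) / n else NA_real_,
    exa_length_bp = exa_len,
    exb_length_bp = exb_len,
    exa_length_frac = exa_len / total_length_low,
    exb_length_frac = exb_len / total_length_high,
    pa_overlap_bp = sum(records$overlap_bp[cls == "PARTIAL"]),
    pa_nonoverlap_bp = sum(records$nonoverlap_bp))
}

#' Change statistic from printed per-class counts
#'
#' Convenience for recomputing `(Total - Equal) / Total` from category
#' counts alone, e.g. when checking published per-patient tallies.
#'
#' @param equal,exa_s,exa_d,exb_s,exb_d,partial Class counts.
#' @return List with `total` and `prop_of_change`.
#' @export
#' @examples
#' prop_of_change(equal = 2595, exa_s = 53, exa_d = 0,
#'                exb_s = 460, exb_d = 93, partial = 3)
prop_of_change <- function(equal, exa_s = 0, exa_d = 0, exb_s = 0,
                           exb_d = 0, partial = 0) {
  total <- equal + exa_s + exa_d + exb_s + exb_d + partial
  list(total = total, prop_of_change = (total - equal) / total)
}
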