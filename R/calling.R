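#' Parameters for LOH tract calling
#'
#' @param min_events Minimum number of supporting HET->HOM events per tract:
#'   2 is the stringent criterion, 1 the loose one.
#' @param gap_threshold_bp Copy-neutral tracts whose consecutive supporting
#'   events are separated by strictly more than this many base pairs are
#'   split, and the gap called unaffected.  Default 40,000 bp, the
#'   upper outer fence (Q3 + 3 IQR) of heterozygous-marker spacing on the
#'   genotyping array; see [derive_gap_threshold()].
#' @param platform `"array"` or `"sequencing"`.  Sets the defaults for
#'   `apply_sparsity_split` (on for arrays, whose markers are sparse; off
#'   for sequencing) and `apply_cnv_min_filter` (read-depth CNV calls below
#'   `cnv_min_length_bp` are unreliable and dropped; array CNV segments are
#'   taken as given).
#' @param apply_sparsity_split Override the platform default for sparsity
#'   splitting.
#' @param qc_monoallelic_max,qc_nocall_max QC bounds: a tract is excluded if
#'   its monoallelic-mutation fraction, or the germline or tissue no-call
#'   fraction over the loci it spans, strictly exceeds the bound.
#'   Defaults 0.20.
#' @param cnv_min_length_bp Minimum CNV segment length retained when
#'   `apply_cnv_min_filter` is on.  Default 100,000 bp.
#' @param apply_cnv_min_filter Override the platform default for the CNV
#'   minimum-length filter.
#' @return A list of class `loh_params`.
#' @export
#' @examples
#' loh_params(min_events = 1, platform = "sequencing")
loh_params <- function(min_events = 2,
                       gap_threshold_bp = 40000,
                       platform = c("array", "sequencing"),
                       apply_sparsity_split = NULL,
                       qc_monoallelic_max = 0.20,
                       qc_nocall_max = 0.20,
                       cnv_min_length_bp = 100000,
                       apply_cnv_min_filter = NULL) {
  platform <- match.arg(platform)
  stopifnot(min_events >= 1, gap_threshold_bp > 0, cnv_min_length_bp > 0,
            qc_monoallelic_max >= 0, qc_nocall_max >= 0)
  if (is.null(apply_sparsity_split)) {
    apply_sparsity_split <- platform == "array"
  }
  if (is.null(apply_cnv_min_filter)) {
    apply_cnv_min_filter <- platform == "sequencing"
  }
  structure(list(
    min_events = as.integer(min_events),
    gap_threshold_bp = gap_threshold_bp,
    platform = platform,
    apply_sparsity_split = isTRUE(apply_sparsity_split),
    qc_monoallelic_max = qc_monoallelic_max,
    qc_nocall_max = qc_nocall_max,
    cnv_min_length_bp = cnv_min_length_bp,
    apply_cnv_min_filter = isTRUE(apply_cnv_min_filter)
  ), class = "loh_params")
}

#' Derive the sparsity-split gap threshold from marker spacings
#'
#' Returns the upper outer fence, Q3 + 3 (Q3 - Q1), of the distribution of
#' base-pair distances between consecutive germline-heterozygous loci.
#' Quantiles use the standard linear-interpolation definition
#' (`stats::quantile`, type 7).
#'
#' @param het_spacings Numeric vector of distances (bp); at least 4 values.
#' @return The fence in bp (numeric scalar).
#' @export
#' @examples
#' derive_gap_threshold(seq(0, 100, by = 10))  # Q1 = 25, Q3 = 75 -> 225
derive_gap_threshold <- function(het_spacings) {
  if (length(het_spacings) < 4) {
    stop("need at least 4 spacing values to derive a fence", call. = FALSE)
  }
  q <- stats::quantile(het_spacings, c(0.25, 0.75), names = FALSE, type = 7)
  unname(q[2] + 3 * (q[2] - q[1]))
}

# terminating transitions: carry evidence against LOH continuity
terminator_types <- function() {
  c("HET_TO_HET", "HET_TO_UNK", "UNK_TO_UNK", "UNK_TO_HET",
    "BIALLELIC_MUTATION")
}

#' Stratify a locus panel by copy-number state
#'
#' Assigns each locus the state of the CNV segment covering it (default
#' `"neutral"` where none does) and groups consecutive same-state loci into
#' maximal blocks, so tracts are called separately per copy-number state.
#' Segments shorter than `cnv_min_length_bp` are dropped first when the
#' params request it.
#'
#' @param loci Tibble with columns `chrom`, `pos`, sorted by position within
#'   chromosome, plus any other columns (carried through).
#' @param cnv CNV segments for one sample: tibble with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `state` among
#'   `"loss"/"neutral"/"gain"`; `NULL` for none.
#' @param params An [loh_params()] object.
#' @return `loci` with added columns `copy_state` and `block` (integer id of
#'   the maximal same-state run within each chromosome-arm group already
#'   present in `loci`).
#' @export
stratify_by_cnv <- function(loci, cnv = NULL, params = loh_params()) {
  state <- rep("neutral", nrow(loci))
  if (!is.null(cnv) && nrow(cnv) > 0) {
    stopifnot(all(c("chrom", "start", "end", "state") %in% names(cnv)))
    if (params$apply_cnv_min_filter) {
      cnv <- cnv[cnv$end - cnv$start + 1 >= params$cnv_min_length_bp, ,
                 drop = FALSE]
    }
    for (ch in unique(cnv$chrom)) {
      seg <- cnv[cnv$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
        stop("overlapping CNV segments on chromosome ", ch, call. = FALSE)
      }
      on_ch <- which(loci$chrom == ch)
      if (length(on_ch) == 0) next
      idx <- findInterval(loci$pos[on_ch], seg$start)
      inside <- idx >= 1 & idx <= nrow(seg) &
        loci$pos[on_ch] <= seg$end[pmax(idx, 1)]
      state[on_ch[inside]] <- seg$state[idx[inside]]
    }
  }
  loci$copy_state <- state
  key <- paste(loci$chrom, if ("arm" %in% names(loci)) loci$arm else "",
               state)
  loci$block <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  loci
}

#' Scan one locus block for LOH tracts
#'
#' Finds maximal runs of HET->HOM events within a block.  Interior loci may
#' be HOM->HOM, monoallelic mutations, or one-sided no-calls involving a
#' homozygote (HOM->UNK, UNK->HOM); runs are broken by HET->HET, HET->UNK,
#' UNK->UNK, UNK->HET, biallelic mutations, and block boundaries.  Tract
#' endpoints are the outermost supporting events, so a single-event tract
#' has length 1 bp.
#'
#' @param block Tibble with columns `pos` (sorted ascending) and
#'   `transition` (values among [transition_types()]).
#' @param min_events Minimum supporting events per tract.
#' @return Tibble with columns `start`, `end`, `n_events` and a list-column
#'   `events` of supporting event positions.
#' @export
scan_tracts <- function(block, min_events = 2) {
  pos <- block$pos
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("block positions must be strictly increasing", call. = FALSE)
  }
  trans <- as.character(block$transition)
  is_event <- trans == "HET_TO_HOM"
  is_term <- trans %in% terminator_types()
  if (!any(is_event)) {
    return(empty_scan())
  }
  run <- cumsum(is_term)[is_event]
  ev_pos <- pos[is_event]
  out <- tibble::tibble(run = run, pos = ev_pos) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                     n_events = dplyr::n(),
                     events = list(.data$pos), .by = "run") |>
    dplyr::select(-"run") |>
    dplyr::filter(.data$n_events >= min_events)
  out
}

empty_scan <- function() {
  tibble::tibble(start = numeric(), end = numeric(),
                 n_events = integer(), events = list())
}

#' Split copy-neutral tracts at sparse event gaps
#'
#' Within each copy-neutral tract, any two consecutive supporting events
#' separated by strictly more than `gap_threshold_bp` start separate tracts
#' (the region between is called unaffected); the fragments are re-filtered
#' by `min_events`.  Copy-loss and copy-gain tracts are left unchanged.
#'
#' @param tracts Output of [scan_tracts()] with a `copy_state` column and
#'   the `events` list-column.
#' @param params An [loh_params()] object.
#' @return Tracts tibble of the same shape.
#' @export
split_sparse <- function(tracts, params = loh_params()) {
  if (nrow(tracts) == 0) return(tracts)
  thr <- params$gap_threshold_bp
  pieces <- lapply(seq_len(nrow(tracts)), function(i) {
    row <- tracts[i, ]
    if (!identical(row$copy_state, "neutral")) return(row)
    ev <- row$events[[1]]
    if (length(ev) < 2) return(row)
    grp <- cumsum(c(0, diff(ev) > thr))
    if (max(grp) == 0) return(row)
    sub <- tibble::tibble(grp = grp, pos = ev) |>
      dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                       n_events = dplyr::n(), events = list(.data$pos),
                       .by = "grp") |>
      dplyr::select(-"grp")
    extra <- row[, setdiff(names(row), names(sub)), drop = FALSE]
    dplyr::bind_cols(sub, extra[rep(1, nrow(sub)), , drop = FALSE])
  })
  dplyr::bind_rows(pieces)[names(tracts)] |>
    dplyr::filter(.data$n_events >= params$min_events)
}

#' QC metrics and exclusion decision for tracts
#'
#' Over all panel loci a tract spans (informative or not), computes the
#' monoallelic-mutation fraction and the germline and tissue no-call
#' fractions.  A tract is excluded when any metric strictly exceeds its
#' bound (default 20%); a tract at exactly the bound is retained.
#'
#' @param tracts Tract tibble with columns `chrom`, `start`, `end`.
#' @param loci Panel tibble with columns `chrom`, `pos`, `transition`,
#'   `germline`, `tissue` (call codes).
#' @param params An [loh_params()] object.
#' @return `tracts` with added columns `qc_monoallelic`,
#'   `qc_nocall_germline`, `qc_nocall_tissue`, `qc_pass`.
#' @export
qc_filter <- function(tracts, loci, params = loh_params()) {
  if (nrow(tracts) == 0) {
    return(dplyr::mutate(tracts, qc_monoallelic = numeric(0),
                         qc_nocall_germline = numeric(0),
                         qc_nocall_tissue = numeric(0),
                         qc_pass = logical(0)))
  }
  trans <- as.character(loci$transition)
  mono <- numeric(nrow(tracts))
  ncg <- numeric(nrow(tracts))
  nct <- numeric(nrow(tracts))
  # per chromosome: cumulative counts over the sorted panel, then a pair of
  # findInterval lookups per tract
  for (ch in unique(tracts$chrom)) {
    on_ch <- loci$chrom == ch
    pos <- loci$pos[on_ch]
    cum_mono <- cumsum(trans[on_ch] == "MONOALLELIC_MUTATION")
    cum_ncg <- cumsum(loci$germline[on_ch] == "NC")
    cum_nct <- cumsum(loci$tissue[on_ch] == "NC")
    ti <- which(tracts$chrom == ch)
    lo <- findInterval(tracts$start[ti] - 1, pos)
    hi <- findInterval(tracts$end[ti], pos)
    n_span <- hi - lo
    at <- function(cum, i) ifelse(i >= 1, cum[pmax(i, 1)], 0)
    mono[ti] <- (at(cum_mono, hi) - at(cum_mono, lo)) / n_span
    ncg[ti] <- (at(cum_ncg, hi) - at(cum_ncg, lo)) / n_span
    nct[ti] <- (at(cum_nct, hi) - at(cum_nct, lo)) / n_span
  }
  tracts$qc_monoallelic <- mono
  tracts$qc_nocall_germline <- ncg
  tracts$qc_nocall_tissue <- nct
  tracts$qc_pass <- mono <= params$qc_monoallelic_max &
    ncg <= params$qc_nocall_max &
    nct <= params$qc_nocall_max
  tracts
}

#' Call LOH tracts for one germline/tissue pairing
#'
#' The full caller: classifies transitions at every locus, assigns arms,
#' stratifies by copy-number state, scans each block for tracts, applies
#' copy-neutral sparsity splitting, and excludes low-quality tracts.
#'
#' @param genotypes Genotype table: tibble with columns `chrom`, `pos`,
#'   `variant_id`, and one call column per sample (values `AA/AB/BB/NC`),
#'   sorted by (`chrom`, `pos`).
#' @param germline,tissue Names of the germline and tissue call columns.
#' @param arms Arm table (see [assign_arm()]).
#' @param cnv CNV segments for the tissue sample, or `NULL`.
#' @param params An [loh_params()] object.
#' @param patient Patient identifier recorded on the output.
#' @param keep_failed Keep QC-failing tracts (flagged by `qc_pass = FALSE`)
#'   instead of dropping them?  Default `FALSE`.
#' @return Tibble of called tracts, one row per tract, sorted by
#'   (`chrom`, `start`): columns `patient`, `sample`, `chrom`, `arm`,
#'   `start`, `end`, `length`, `n_events`, `copy_state` and QC metrics.
#'   Tract length is inclusive, `end - start + 1`, so a single-event tract
#'   has length 1.
#' @export
#' @examples
#' arms <- tibble::tibble(chrom = 1, arm = "p", start = 1, end = 1e6,
#'                        centromere_boundary = 1e6)
#' gt <- tibble::tibble(chrom = 1, pos = c(100, 200, 300),
#'                      variant_id = paste0("rs", 1:3),
#'                      blood = c("AB", "AB", "AB"),
#'                      tumor = c("AA", "BB", "AB"))
#' call_loh(gt, "blood", "tumor", arms, params = loh_params(min_events = 1))
call_loh <- function(genotypes, germline, tissue, arms, cnv = NULL,
                     params = loh_params(), patient = NA_character_,
                     keep_failed = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(genotypes)),
            germline %in% names(genotypes), tissue %in% names(genotypes))
  loci <- tibble::tibble(
    chrom = genotypes$chrom,
    pos = genotypes$pos,
    germline = genotypes[[germline]],
    tissue = genotypes[[tissue]]
  )
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, ]
  loci$transition <- classify_transitions(loci$germline, loci$tissue)
  # bare arm ("p"/"q"), matching the arm-table convention
  loci$arm <- sub("^\\d+", "", assign_arm(loci, arms))
  loci <- stratify_by_cnv(loci, cnv, params)

  tracts <- loci |>
    dplyr::group_by(.data$block) |>
    dplyr::group_map(function(blk, key) {
      tr <- scan_tracts(blk, min_events = params$min_events)
      if (nrow(tr) == 0) return(NULL)
      tr$chrom <- blk$chrom[1]
      tr$arm <- blk$arm[1]
      tr$copy_state <- blk$copy_state[1]
      tr
    }) |>
    dplyr::bind_rows()
  if (nrow(tracts) == 0) {
    return(empty_tract_set(patient, tissue))
  }
  if (params$apply_sparsity_split) {
    tracts <- split_sparse(tracts, params)
  }
  if (nrow(tracts) == 0) {
    return(empty_tract_set(patient, tissue))
  }
  tracts <- qc_filter(tracts, loci, params)
  if (!keep_failed) {
    tracts <- tracts[tracts$qc_pass, , drop = FALSE]
  }
  tracts |>
    dplyr::mutate(patient = patient, sample = tissue,
                  length = .data$end - .data$start + 1) |>
    dplyr::select("patient", "sample", "chrom", "arm", "start", "end",
                  "length", "n_events", "copy_state", "qc_monoallelic",
                  "qc_nocall_germline", "qc_nocall_tissue", "qc_pass") |>
    dplyr::arrange(.data$chrom, .data$start)
}

empty_tract_set <- function(patient, sample) {
  tibble::tibble(patient = character(), sample = character(),
                 chrom = numeric(), arm = character(), start = numeric(),
                 end = numeric(), length = numeric(), n_events = integer(),
                 copy_state = character(), qc_monoallelic = numeric(),
                 qc_nocall_germline = numeric(), qc_nocall_tissue = numeric(),
                 qc_pass = logical())
}

#' Summarise a called tract set
#'
#' @param tracts Output of [call_loh()].
#' @return One-row tibble per (`patient`, `sample`): tract count, total
#'   tract length, and counts by copy-number state.
#' @export
tract_summary <- function(tracts) {
  tracts |>
    dplyr::summarise(
      n_tracts = dplyr::n(),
      total_length = sum(.data$length),
      n_neutral = sum(.data$copy_state == "neutral"),
      n_loss = sum(.data$copy_state == "loss"),
      n_gain = sum(.data$copy_state == "gain"),
      .by = c("patient", "sample"))
}
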