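# Shared fixtures and independent oracles used across test files.

toy_arms <- function(chroms = 1, p_len = 5e7, q_len = 5e7) {
  dplyr::bind_rows(
    tibble::tibble(chrom = chroms, arm = "p", start = 1, end = p_len,
                   centromere_boundary = p_len),
    tibble::tibble(chrom = chroms, arm = "q", start = p_len + 1,
                   end = p_len + q_len, centromere_boundary = p_len + 1)
  ) |> dplyr::arrange(chrom, start)
}

make_gt <- function(pos, germ, tiss, chrom = 1,
                    germline = "blood", tissue = "tumor") {
  out <- tibble::tibble(chrom = chrom, pos = pos,
                        variant_id = paste0("rs", seq_along(pos)))
  out[[germline]] <- germ
  out[[tissue]] <- tiss
  out
}

make_tracts <- function(chrom, start, end, patient = "p", sample = "s",
                        arm = "p") {
  tibble::tibble(patient = patient, sample = sample, chrom = chrom,
                 arm = arm, start = start, end = end,
                 length = end - start + 1)
}

# Brute-force tract enumeration, independent of scan_tracts: enumerate every
# pair (i, j) of HET->HOM event indices such that no terminating transition
# lies between them in the panel, and keep the maximal such runs.
oracle_scan <- function(pos, trans, min_events) {
  terminators <- c("HET_TO_HET", "HET_TO_UNK", "UNK_TO_UNK", "UNK_TO_HET",
                   "BIALLELIC_MUTATION")
  trans <- as.character(trans)
  ev <- which(trans == "HET_TO_HOM")
  if (length(ev) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          n_events = integer()))
  }
  term <- which(trans %in% terminators)
  legal <- function(i, j) {
    !any(term > ev[i] & term < ev[j])
  }
  runs <- list()
  for (i in seq_along(ev)) {
    for (j in i:length(ev)) {
      if (!legal(i, j)) next
      left_max <- i == 1 || !legal(i - 1, j)
      right_max <- j == length(ev) || !legal(i, j + 1)
      if (left_max && right_max) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  out <- tibble::tibble(
    start = vapply(runs, function(r) pos[ev[r[1]]], numeric(1)),
    end = vapply(runs, function(r) pos[ev[r[2]]], numeric(1)),
    n_events = vapply(runs, function(r) r[2] - r[1] + 1L, integer(1)))
  out[out$n_events >= min_events, ]
}

# random paired genotype vectors for property tests
random_calls <- function(n, p_het = 0.35, p_nc = 0.1) {
  codes <- c("AA", "AB", "BB", "NC")
  probs <- c((1 - p_het - p_nc) / 2, p_het, (1 - p_het - p_nc) / 2, p_nc)
  sample(codes, n, replace = TRUE, prob = probs)
}

# Exhaustive overlap probability for two intervals of lengths l and m placed
# uniformly (integer starts) on an axis of e positions.
enum_overlap_prob <- function(l, m, e) {
  na <- e - l + 1
  nb <- e - m + 1
  hits <- 0
  for (a in seq_len(na)) {
    lo <- max(1, a - m + 1)
    hi <- min(nb, a + l - 1)
    if (hi >= lo) hits <- hits + (hi - lo + 1)
  }
  hits / (na * nb)
}
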