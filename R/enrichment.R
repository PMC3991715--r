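#' Arm-level LOH burden profile
#'
#' Sums tract lengths per chromosome arm and adjusts for arm length
#' (total tract bp / arm bp), giving a dimensionless burden comparable
#' across arms.  Arms with no tracts appear with zeros.
#'
#' @param tracts Tract tibble from [call_loh()] (non-overlapping within the
#'   sample).
#' @param arms Arm table (see [assign_arm()]).
#' @return Tibble with one row per arm: `chrom`, `arm`, `arm_label`,
#'   `arm_length`, `total_length`, `adjusted`, plus `patient` and `sample`
#'   carried from the tracts when unambiguous.
#' @export
arm_profile <- function(tracts, arms) {
  check_arm_table(arms)
  if (nrow(tracts) > 0 &&
      any(!paste0(tracts$chrom, tracts$arm) %in%
            paste0(arms$chrom, arms$arm))) {
    stop("tract on an arm absent from the annotation", call. = FALSE)
  }
  base <- arms |>
    dplyr::mutate(arm_label = paste0(.data$chrom, .data$arm),
                  arm_length = .data$end - .data$start + 1) |>
    dplyr::select("chrom", "arm", "arm_label", "arm_length")
  burden <- tracts |>
    dplyr::summarise(total_length = sum(.data$length),
                     .by = c("chrom", "arm"))
  out <- base |>
    dplyr::left_join(burden, by = c("chrom", "arm")) |>
    dplyr::mutate(total_length = dplyr::coalesce(.data$total_length, 0),
                  adjusted = .data$total_length / .data$arm_length)
  if (nrow(tracts) > 0) {
    out$patient <- tracts$patient[1]
    out$sample <- tracts$sample[1]
  }
  out
}

#' Stratified cohort summary of arm profiles
#'
#' Per-arm, per-stratum distributional summary (median and quartiles) of
#' adjusted LOH burden across patients, e.g. stratified by tumor T stage.
#'
#' @param profiles Row-bound [arm_profile()] outputs with a `patient`
#'   column.
#' @param groups Tibble mapping `patient` to `stratum`.
#' @return Tibble with one row per (`arm_label`, `stratum`): `n_patients`,
#'   `median`, `q1`, `q3` of the adjusted burden.  Strata with no patients
#'   are omitted with a warning.
#' @export
cohort_arm_summary <- function(profiles, groups) {
  stopifnot(all(c("patient", "stratum") %in% names(groups)))
  missing_strata <- setdiff(groups$stratum, groups$stratum[
    groups$patient %in% profiles$patient])
  if (length(missing_strata) > 0) {
    warning("strata with no profiles omitted: ",
            paste(missing_strata, collapse = ", "))
  }
  profiles |>
    dplyr::inner_join(groups, by = "patient") |>
    dplyr::summarise(
      n_patients = dplyr::n_distinct(.data$patient),
      median = stats::median(.data$adjusted),
      q1 = stats::quantile(.data$adjusted, 0.25, names = FALSE),
      q3 = stats::quantile(.data$adjusted, 0.75, names = FALSE),
      .by = c("chrom", "arm", "arm_label", "stratum"))
}

#' Correlation between two arm profiles
#'
#' Pearson correlation of per-arm adjusted LOH burden between two profiles
#' (e.g. cohort-mean distant-normal vs tumor), with a two-sided p-value
#' from the t transform on `#arms - 2` degrees of freedom.  Arms missing
#' from either profile are dropped pairwise.
#'
#' @param profile_a,profile_b [arm_profile()] tibbles (or any tibbles with
#'   `arm_label` and `adjusted`).
#' @return Tibble with `r`, `p_value`, `n_arms`.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  m <- dplyr::inner_join(
    dplyr::select(profile_a, "arm_label", a = "adjusted"),
    dplyr::select(profile_b, "arm_label", b = "adjusted"),
    by = "arm_label") |>
    dplyr::filter(!is.na(.data$a), !is.na(.data$b))
  if (nrow(m) < 3) stop("need at least 3 shared arms", call. = FALSE)
  if (stats::sd(m$a) == 0 || stats::sd(m$b) == 0) {
    stop("zero variance in an arm profile; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(m$a, m$b, method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_arms = nrow(m))
}

#' Gene-level cross-patient concurrence table
#'
#' For every gene, counts patients in three nested categories.
#' *Concurrent (no overlap required)*: both samples have a qualifying tract
#' overlapping the gene region by at least 1 bp, not necessarily the same
#' region of it.  *Concurrent with overlap*: additionally some low-stage
#' tract, high-stage tract and the gene share at least 1 bp.
#' *Informative*: the patient's germline has at least one heterozygous
#' locus inside the gene, so LOH there is detectable at all.  Only
#' informative patients contribute to the two concurrence columns, so the
#' three counts are nested per gene.
#'
#' @param tracts_low,tracts_high Cohort tract tibbles (with `patient`),
#'   called under the stringent criterion (>= 2 events).
#' @param genes Gene table with columns `gene`, `chrom`, `start`, `end`,
#'   and optional logical flags `fragile_site`, `cancer_census`.
#' @param germline_het Tibble of germline-heterozygous locus positions per
#'   patient: columns `patient`, `chrom`, `pos`.
#' @return Tibble, one row per gene: `n_concurrent` (no overlap required),
#'   `n_concurrent_overlap`, `n_informative`, any flag columns, sorted by
#'   `n_concurrent_overlap` descending.
#' @export
gene_concurrence <- function(tracts_low, tracts_high, genes, germline_het) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  stopifnot(all(c("patient", "chrom", "pos") %in% names(germline_het)))
  patients <- union(unique(tracts_low$patient), unique(tracts_high$patient))
  ng <- nrow(genes)
  n_conc <- integer(ng); n_ov <- integer(ng); n_inf <- integer(ng)
  for (p in patients) {
    tl <- tracts_low[tracts_low$patient == p, , drop = FALSE]
    th <- tracts_high[tracts_high$patient == p, , drop = FALSE]
    het <- germline_het[germline_het$patient == p, , drop = FALSE]
    inf <- vapply(seq_len(ng), function(g) {
      any(het$chrom == genes$chrom[g] & het$pos >= genes$start[g] &
            het$pos <= genes$end[g])
    }, logical(1))
    hit_l <- gene_tract_hits(genes, tl)
    hit_h <- gene_tract_hits(genes, th)
    # concurrence is only counted for patients informative in the gene:
    # without a heterozygous marker there, LOH in the gene is undetectable
    # and the patient contributes to no column
    both <- hit_l & hit_h & inf
    n_conc <- n_conc + both
    # triple overlap: some low x high pair shares >=1 bp inside the gene
    ov <- logical(ng)
    check <- which(both)
    if (length(check) > 0 && nrow(tl) > 0 && nrow(th) > 0) {
      pairs <- overlap_pairs(tl, th)
      if (nrow(pairs) > 0) {
        for (g in check) {
          sl <- pmax(tl$start[pairs$idx_low], th$start[pairs$idx_high],
                     genes$start[g])
          el <- pmin(tl$end[pairs$idx_low], th$end[pairs$idx_high],
                     genes$end[g])
          same_chr <- tl$chrom[pairs$idx_low] == genes$chrom[g]
          ov[g] <- any(same_chr & el - sl + 1 >= 1)
        }
      }
    }
    n_ov <- n_ov + ov
    n_inf <- n_inf + inf
  }
  genes |>
    dplyr::mutate(n_concurrent = n_conc, n_concurrent_overlap = n_ov,
                  n_informative = n_inf) |>
    dplyr::arrange(dplyr::desc(.data$n_concurrent_overlap))
}

# per-gene flag: any tract overlaps the gene region by >=1 bp
gene_tract_hits <- function(genes, tracts) {
  if (nrow(tracts) == 0) return(rep(FALSE, nrow(genes)))
  vapply(seq_len(nrow(genes)), function(g) {
    any(tracts$chrom == genes$chrom[g] &
          tracts$start <= genes$end[g] & tracts$end >= genes$start[g])
  }, logical(1))
}

#' Category enrichment among top-concurrence genes
#'
#' One-sample chi-square goodness-of-fit test (df = 1) asking whether a
#' gene category (e.g. fragile-site-collocated, cancer-census) is
#' over-represented among genes with high cross-patient LOH concurrence,
#' relative to a baseline proportion.
#'
#' @param gene_table Output of [gene_concurrence()].
#' @param flag Name of the logical membership column to test.
#' @param min_patients Genes with at least this many patients in the
#'   overlap-required column count as "top" (default 6).
#' @param baseline `"all_genes"` (category proportion over every gene) or
#'   `"concurrent_genes"` (over genes with >= 1 concurrent patient).
#' @return Object of class `loh_enrichment` (see [gof_enrichment()]).
#' @export
category_enrichment <- function(gene_table, flag, min_patients = 6,
                                baseline = c("all_genes",
                                             "concurrent_genes")) {
  baseline <- match.arg(baseline)
  stopifnot(flag %in% names(gene_table))
  top <- gene_table$n_concurrent_overlap >= min_patients
  universe <- if (baseline == "all_genes") {
    rep(TRUE, nrow(gene_table))
  } else {
    gene_table$n_concurrent_overlap >= 1
  }
  p0 <- mean(gene_table[[flag]][universe])
  gof_enrichment(n_top = sum(top), k_top = sum(gene_table[[flag]][top]),
                 baseline_prop = p0, baseline_mode = baseline,
                 category = flag)
}

#' Chi-square goodness-of-fit enrichment test
#'
#' Core test behind [category_enrichment()]: compares the observed number
#' of category members among `n_top` genes to the expectation under a
#' baseline proportion, via a one-degree-of-freedom chi-square
#' goodness-of-fit statistic (no continuity correction).
#'
#' @param n_top Number of top genes.
#' @param k_top Observed category members among them.
#' @param baseline_prop Baseline category proportion in (0, 1).
#' @param baseline_mode,category Labels recorded on the result.
#' @return Object of class `loh_enrichment`: list with `n_top`, `k_top`,
#'   `observed_prop`, `baseline_prop`, `statistic`, `p_value`,
#'   `baseline_mode`, `category`, and `unreliable` (`TRUE` when an expected
#'   count falls below 1).
#' @export
#' @examples
#' gof_enrichment(429, 49, 0.084)  # chi-square ~ 5.1, p ~ 0.02
gof_enrichment <- function(n_top, k_top, baseline_prop,
                           baseline_mode = "all_genes",
                           category = NA_character_) {
  stopifnot(baseline_prop > 0, baseline_prop < 1, k_top <= n_top)
  expected <- n_top * c(baseline_prop, 1 - baseline_prop)
  observed <- c(k_top, n_top - k_top)
  stat <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(
    n_top = n_top, k_top = k_top,
    observed_prop = k_top / n_top,
    baseline_prop = baseline_prop,
    statistic = stat, p_value = p,
    baseline_mode = baseline_mode, category = category,
    unreliable = any(expected < 1)
  ), class = "loh_enrichment")
}

#' @export
print.loh_enrichment <- function(x, ...) {
  cat("Goodness-of-fit enrichment test (df = 1)\n")
  if (!is.na(x$category)) cat("  category:", x$category, "\n")
  cat(sprintf("  observed: %d of %d (%.1f%%) vs baseline %.1f%% [%s]\n",
              x$k_top, x$n_top, 100 * x$observed_prop,
              100 * x$baseline_prop, x$baseline_mode))
  cat(sprintf("  chi-square = %.3f, p = %.3g\n", x$statistic, x$p_value))
  if (x$unreliable) cat("  warning: an expected count is below 1\n")
  invisible(x)
}
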