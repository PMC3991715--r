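# run code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% 2147483587)
}

#' Configuration of the synthetic paired-cohort generator
#'
#' Describes a small diploid genome, an array-like marker panel, and the
#' LOH process the generator plants: distant-normal (low-stage, "Td")
#' tracts drawn per arm, each inherited by the tumor (high-stage, "Tt")
#' sample with probability `inherit_prob` and extended at each end by a
#' geometric number of bp, plus independent tumor-only tracts.  Genotyping
#' noise (no-calls, monoallelic and biallelic mutations) and copy-number
#' segments are injected at the stated rates.
#'
#' @param n_chromosomes Number of autosomes to simulate.
#' @param arm_length_p,arm_length_q Arm lengths in bp.
#' @param marker_spacing_bp Mean spacing between markers; positions are a
#'   Poisson process (exponential gaps), so heterozygous-marker spacings
#'   have a well-defined outer fence.
#' @param het_rate Germline heterozygosity rate per marker (array SNP
#'   panels are ascertained for common variants, so this is high).
#' @param nocall_rate_blood,nocall_rate_tissue Per-marker no-call rates;
#'   defaults 0.0044 and 0.0165 (blood vs tumor array no-call rates).
#' @param monoallelic_rate,biallelic_rate Per-marker rates of germline-HOM
#'   loci appearing as AB (monoallelic) or the opposite HOM (biallelic) in
#'   tissue.
#' @param n_tracts_low Planted low-stage tracts per patient (before stage
#'   scaling).
#' @param tract_length_bounds Log-uniform bounds (bp) on planted tract
#'   length.
#' @param arm_weights Optional named vector of per-arm planting weights
#'   (names are arm labels like `"1p"`); uniform when `NULL`.
#' @param inherit_prob Probability a low-stage tract recurs in the
#'   high-stage sample (default 2/3).
#' @param extension_mean_bp Mean per-end geometric extension of inherited
#'   tracts.
#' @param n_tracts_high_indep Independent high-stage-only tracts.
#' @param cnv_n_segments,cnv_length_bounds CNV segments per tissue sample
#'   and their log-uniform length bounds.
#' @param n_genes,gene_length_bp Genes tiled into the annotation.
#' @param fragile_frac,census_frac Fractions of genes flagged as
#'   fragile-site-collocated / cancer-census (defaults mirror genome-wide
#'   category proportions of roughly 8.4% and 1.9%).
#' @param n_patients Cohort size.
#' @param stage_probs Named probabilities of T-stage strata.
#' @param stage_multipliers Named per-stratum multipliers on planted tract
#'   counts (LOH burden grows with stage).
#' @param seed Base seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4,
                       arm_length_p = 3e7,
                       arm_length_q = 5e7,
                       marker_spacing_bp = 3000,
                       het_rate = 0.30,
                       nocall_rate_blood = 0.0044,
                       nocall_rate_tissue = 0.0165,
                       monoallelic_rate = 0.002,
                       biallelic_rate = 5e-4,
                       n_tracts_low = 40,
                       tract_length_bounds = c(5e4, 2e6),
                       arm_weights = NULL,
                       inherit_prob = 2 / 3,
                       extension_mean_bp = 1e5,
                       n_tracts_high_indep = 20,
                       cnv_n_segments = 3,
                       cnv_length_bounds = c(1e5, 2e6),
                       n_genes = 200,
                       gene_length_bp = 2e5,
                       fragile_frac = 0.084,
                       census_frac = 0.019,
                       n_patients = 12,
                       stage_probs = c(T1 = 0.281, T2 = 0.606,
                                       `T3&4` = 0.113),
                       stage_multipliers = c(T1 = 1, T2 = 2, `T3&4` = 3),
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, arm_length_p > 0, arm_length_q > 0,
            marker_spacing_bp > 0,
            het_rate >= 0, het_rate <= 1,
            inherit_prob >= 0, inherit_prob <= 1,
            tract_length_bounds[1] <= tract_length_bounds[2])
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate a genome annotation
#'
#' Builds a non-overlapping arm table (p arm, then q arm, centromere at
#' their junction), tiles genes into the arms, and flags configurable
#' fractions as fragile-site-collocated and cancer-census members.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `arms` and `genes` tibbles.
#' @export
simulate_annotation <- function(config = sim_config(), seed = config$seed) {
  with_seed(seed, {
    chroms <- seq_len(config$n_chromosomes)
    arms <- dplyr::bind_rows(
      tibble::tibble(chrom = chroms, arm = "p", start = 1,
                     end = config$arm_length_p,
                     centromere_boundary = config$arm_length_p),
      tibble::tibble(chrom = chroms, arm = "q",
                     start = config$arm_length_p + 1,
                     end = config$arm_length_p + config$arm_length_q,
                     centromere_boundary = config$arm_length_p + 1)
    ) |>
      dplyr::arrange(.data$chrom, .data$start)
    n_genes <- config$n_genes
    gi <- sample(nrow(arms), n_genes, replace = TRUE)
    gstart <- floor(arms$start[gi] +
                      stats::runif(n_genes) *
                        (arms$end[gi] - arms$start[gi] -
                           config$gene_length_bp))
    genes <- tibble::tibble(
      gene = sprintf("G%03d", seq_len(n_genes)),
      chrom = arms$chrom[gi],
      start = gstart,
      end = gstart + config$gene_length_bp - 1,
      fragile_site = FALSE, cancer_census = FALSE)
    genes$fragile_site[sample(n_genes,
                              round(config$fragile_frac * n_genes))] <- TRUE
    genes$cancer_census[sample(n_genes,
                               round(config$census_frac * n_genes))] <- TRUE
    list(arms = arms, genes = dplyr::arrange(genes, .data$chrom,
                                             .data$start))
  })
}

# draw planted tract intervals on the arm table
plant_tracts <- function(n, arms, config, weights = NULL) {
  if (n == 0) {
    return(tibble::tibble(chrom = numeric(), arm = character(),
                          start = numeric(), end = numeric()))
  }
  lab <- paste0(arms$chrom, arms$arm)
  w <- if (is.null(weights)) rep(1, nrow(arms)) else {
    stopifnot(all(lab %in% names(weights)) || all(names(weights) %in% lab))
    out <- rep(1, nrow(arms))
    out[match(names(weights), lab)] <- weights
    out
  }
  ai <- sample(nrow(arms), n, replace = TRUE, prob = w)
  b <- log(config$tract_length_bounds)
  len <- floor(exp(stats::runif(n, b[1], b[2])))
  alen <- arms$end[ai] - arms$start[ai] + 1
  len <- pmin(len, alen)
  start <- floor(arms$start[ai] + stats::runif(n) * (alen - len + 1))
  tibble::tibble(chrom = arms$chrom[ai], arm = arms$arm[ai],
                 start = start, end = start + len - 1)
}

# random non-overlapping CNV segments for one sample
draw_cnv <- function(arms, config, sample_id) {
  n <- config$cnv_n_segments
  if (n == 0) {
    return(tibble::tibble(chrom = numeric(), start = numeric(),
                          end = numeric(), state = character(),
                          sample = character()))
  }
  seg <- plant_tracts(n, arms, config = list(
    tract_length_bounds = config$cnv_length_bounds))
  seg$state <- sample(c("loss", "gain"), n, replace = TRUE)
  seg$sample <- sample_id
  seg <- dplyr::arrange(seg, .data$chrom, .data$start)
  # drop later segments that collide within a chromosome
  keep <- rep(TRUE, nrow(seg))
  for (ch in unique(seg$chrom)) {
    i <- which(seg$chrom == ch)
    if (length(i) > 1) {
      hi <- cummax(seg$end[i])
      keep[i[-1]] <- seg$start[i[-1]] > hi[-length(i)]
    }
  }
  dplyr::select(seg[keep, ], "chrom", "start", "end", "state", "sample")
}

# apply LOH to a tissue call vector: germline HETs inside tracts become HOM
apply_loh <- function(germline, chrom, pos, tracts) {
  tissue <- germline
  if (nrow(tracts) == 0) return(tissue)
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(tracts))) {
    inside <- inside | (chrom == tracts$chrom[i] & pos >= tracts$start[i] &
                          pos <= tracts$end[i])
  }
  target <- inside & germline == "AB"
  tissue[target] <- sample(c("AA", "BB"), sum(target), replace = TRUE)
  tissue
}

# inject genotyping noise into a tissue call vector
apply_noise <- function(tissue, germline, config) {
  hom <- germline %in% c("AA", "BB")
  mono <- hom & stats::runif(length(tissue)) < config$monoallelic_rate
  tissue[mono] <- "AB"
  bi <- hom & !mono & stats::runif(length(tissue)) < config$biallelic_rate
  tissue[bi] <- ifelse(germline[bi] == "AA", "BB", "AA")
  nc <- stats::runif(length(tissue)) < config$nocall_rate_tissue
  tissue[nc] <- "NC"
  tissue
}

#' Simulate one patient's paired genotype tables
#'
#' Draws an array-like marker panel (Poisson-process positions), germline
#' genotypes, planted low-stage (Td) LOH tracts, high-stage (Tt) tracts
#' built by inheritance-with-extension plus independents, genotyping noise,
#' and CNV segments.  The truth set records every planted tract and the
#' inheritance links.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()]; generated from
#'   `config` when `NULL`.
#' @param seed Seed (defaults to `config$seed`).
#' @param patient Patient id recorded in outputs.
#' @param stage_multiplier Multiplier on planted tract counts.
#' @return List with `genotypes` (tibble `chrom`, `pos`, `variant_id`,
#'   `germline`, `Td`, `Tt`), `cnv` (segments for both tissue samples),
#'   `truth` (list of `tracts_low`, `tracts_high`, merged planted
#'   intervals with inheritance provenance), and `annotation`.
#' @export
simulate_patient <- function(config = sim_config(), annotation = NULL,
                             seed = config$seed, patient = "P1",
                             stage_multiplier = 1) {
  if (is.null(annotation)) {
    annotation <- simulate_annotation(config, seed = derive_seed(seed, 1))
  }
  arms <- annotation$arms
  with_seed(seed, {
    # marker panel: exponential gaps per chromosome
    loci <- lapply(unique(arms$chrom), function(ch) {
      chrom_end <- max(arms$end[arms$chrom == ch])
      n_guess <- ceiling(chrom_end / config$marker_spacing_bp * 1.25) + 50
      pos <- cumsum(ceiling(stats::rexp(n_guess,
                                        1 / config$marker_spacing_bp)))
      while (pos[length(pos)] < chrom_end) {
        pos <- c(pos, pos[length(pos)] +
                   cumsum(ceiling(stats::rexp(n_guess,
                                              1 / config$marker_spacing_bp))))
      }
      pos <- pos[pos <= chrom_end]
      tibble::tibble(chrom = ch, pos = pos)
    }) |> dplyr::bind_rows()
    # drop loci inside centromeric gaps (none by construction here, but a
    # user-supplied annotation may leave gaps)
    keep <- !is.na(assign_arm(loci, arms, strict = FALSE))
    loci <- loci[keep, ]
    n <- nrow(loci)
    loci$variant_id <- sprintf("v%d_%d", loci$chrom, seq_len(n))

    germ <- ifelse(stats::runif(n) < config$het_rate, "AB",
                   sample(c("AA", "BB"), n, replace = TRUE))

    n_low <- round(config$n_tracts_low * stage_multiplier)
    low <- plant_tracts(n_low, arms, config, config$arm_weights) |>
      merge_tracts()
    low$tract_id <- seq_len(nrow(low))

    inherited <- low[stats::runif(nrow(low)) < config$inherit_prob, ,
                     drop = FALSE]
    if (nrow(inherited) > 0) {
      p_geom <- 1 / (config$extension_mean_bp + 1)
      ext_l <- stats::rgeom(nrow(inherited), p_geom)
      ext_r <- stats::rgeom(nrow(inherited), p_geom)
      ai <- match(paste0(inherited$chrom, inherited$arm),
                  paste0(arms$chrom, arms$arm))
      inherited$start <- pmax(arms$start[ai], inherited$start - ext_l)
      inherited$end <- pmin(arms$end[ai], inherited$end + ext_r)
      inherited$source <- "inherited"
    }
    n_indep <- round(config$n_tracts_high_indep * stage_multiplier)
    indep <- plant_tracts(n_indep, arms, config, config$arm_weights)
    if (nrow(indep) > 0) indep$source <- "independent"
    high_all <- dplyr::bind_rows(inherited, indep)
    high <- merge_tracts(high_all[, c("chrom", "arm", "start", "end")])

    td <- apply_loh(germ, loci$chrom, loci$pos, low)
    tt <- apply_loh(germ, loci$chrom, loci$pos, high)
    td <- apply_noise(td, germ, config)
    tt <- apply_noise(tt, germ, config)
    germ[stats::runif(n) < config$nocall_rate_blood] <- "NC"

    cnv <- dplyr::bind_rows(
      draw_cnv(arms, config, "Td"),
      draw_cnv(arms, config, "Tt"))

    list(
      genotypes = tibble::tibble(chrom = loci$chrom, pos = loci$pos,
                                 variant_id = loci$variant_id,
                                 germline = germ, Td = td, Tt = tt),
      cnv = cnv,
      truth = list(
        tracts_low = dplyr::mutate(low, patient = patient, sample = "Td"),
        tracts_high = dplyr::mutate(high, patient = patient,
                                    sample = "Tt"),
        tracts_high_components = if (nrow(high_all) > 0) {
          dplyr::mutate(high_all, patient = patient)
        } else high_all,
        inherit_prob = config$inherit_prob),
      annotation = annotation,
      patient = patient)
  })
}

#' Simulate a stratified cohort
#'
#' Patients share one annotation and arm-weight vector; each is assigned a
#' T-stage stratum and its planted LOH burden is scaled by the stratum
#' multiplier.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `annotation`, `patients` (named list of
#'   [simulate_patient()] outputs) and `stages` (tibble `patient`,
#'   `stratum`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  annotation <- simulate_annotation(config, seed = derive_seed(seed, 1))
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  # proportional allocation of strata (largest remainder), order shuffled,
  # so no stratum drops out of a small cohort by sampling accident
  p <- config$stage_probs / sum(config$stage_probs)
  counts <- floor(p * config$n_patients)
  rem <- config$n_patients - sum(counts)
  if (rem > 0) {
    extra <- order(p * config$n_patients - counts, decreasing = TRUE)[
      seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  strata <- with_seed(derive_seed(seed, 2), {
    sample(rep(names(config$stage_probs), counts))
  })
  patients <- lapply(seq_along(ids), function(i) {
    simulate_patient(config, annotation,
                     seed = derive_seed(seed, 10 + i),
                     patient = ids[i],
                     stage_multiplier = config$stage_multipliers[[strata[i]]])
  })
  names(patients) <- ids
  list(annotation = annotation,
       patients = patients,
       stages = tibble::tibble(patient = ids, stratum = strata))
}
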