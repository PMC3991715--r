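test_that("arm profiles conserve totals and adjust for arm length", {
  arms <- toy_arms(p_len = 1000, q_len = 4000)
  tr <- make_tracts(1, c(1, 201), c(100, 300), arm = "p")
  prof <- arm_profile(tr, arms)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$total_length[prof$arm == "p"], 200)
  expect_equal(prof$adjusted[prof$arm == "p"], 0.2)
  expect_equal(prof$total_length[prof$arm == "q"], 0)
  expect_equal(sum(prof$total_length), sum(tr$length))
  empty <- arm_profile(tr[0, ], arms)
  expect_true(all(empty$adjusted == 0))
  stray <- make_tracts(3, 1, 100, arm = "p")
  expect_error(arm_profile(stray, arms), "absent from the annotation")
})

test_that("cohort arm summaries give per-stratum quartiles", {
  arms <- toy_arms(p_len = 1000, q_len = 1000)
  prof <- function(pt, val) {
    tibble::tibble(chrom = 1, arm = c("p", "q"),
                   arm_label = c("1p", "1q"), arm_length = 1000,
                   total_length = val * 1000, adjusted = val,
                   patient = pt)
  }
  profs <- dplyr::bind_rows(prof("a", 1), prof("b", 2), prof("c", 3))
  groups <- tibble::tibble(patient = c("a", "b", "c"), stratum = "T1")
  s <- cohort_arm_summary(profs, groups)
  expect_equal(s$median[s$arm_label == "1p"], 2)
  expect_equal(s$q1[s$arm_label == "1p"], 1.5)
  identical3 <- dplyr::bind_rows(prof("a", 2), prof("b", 2), prof("c", 2))
  s2 <- cohort_arm_summary(identical3, groups)
  expect_true(all(s2$median == 2 & s2$q1 == 2 & s2$q3 == 2))
  expect_warning(
    cohort_arm_summary(profs, tibble::tibble(patient = c("a", "b", "c",
                                                         "zz"),
                                             stratum = c("T1", "T1", "T1",
                                                         "T2"))),
    "omitted")
})

test_that("profile correlation recovers exact linear relations", {
  pa <- tibble::tibble(arm_label = paste0(1:8, "p"),
                       adjusted = c(0.1, 0.3, 0.2, 0.5, 0.05, 0.4, 0.25,
                                    0.15))
  pb <- dplyr::mutate(pa, adjusted = 2 * adjusted)
  expect_equal(profile_correlation(pa, pb)$r, 1)
  pc <- dplyr::mutate(pa, adjusted = 1 - adjusted)
  expect_equal(profile_correlation(pa, pc)$r, -1)
  flat <- dplyr::mutate(pa, adjusted = 0.3)
  expect_error(profile_correlation(pa, flat), "zero variance")
  # p-value matches the t-transform with n - 2 degrees of freedom
  pd <- dplyr::mutate(pa, adjusted = adjusted + c(0.01, -0.03, 0.02, 0,
                                                  -0.01, 0.05, 0.01,
                                                  -0.02))
  got <- profile_correlation(pa, pd)
  r <- stats::cor(pa$adjusted, pd$adjusted)
  tstat <- r * sqrt((8 - 2) / (1 - r^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df = 6))
})

test_that("gene concurrence distinguishes overlap from co-occurrence", {
  genes <- tibble::tibble(gene = "G1", chrom = 1, start = 1000, end = 2000)
  het <- tibble::tibble(patient = c("p1", "p2", "p3"), chrom = 1,
                        pos = c(1500, 1500, 500))
  # p1: tracts overlap inside the gene; p2: disjoint tracts both in gene;
  # p3: concurrent but no germline heterozygote inside the gene
  low <- dplyr::bind_rows(
    make_tracts(1, 1500, 1600, patient = "p1"),
    make_tracts(1, 1100, 1200, patient = "p2"),
    make_tracts(1, 1500, 1600, patient = "p3"))
  high <- dplyr::bind_rows(
    make_tracts(1, 1550, 1650, patient = "p1"),
    make_tracts(1, 1500, 1600, patient = "p2"),
    make_tracts(1, 1550, 1650, patient = "p3"))
  tab <- gene_concurrence(low, high, genes, het)
  # p3 overlaps the gene but is uninformative there, so counts nowhere
  expect_equal(tab$n_concurrent, 2)
  expect_equal(tab$n_concurrent_overlap, 1)
  expect_equal(tab$n_informative, 2)
})

test_that("gene concurrence counts are nested cohort-wide", {
  cfg <- sim_config(n_chromosomes = 2, arm_length_p = 5e6,
                    arm_length_q = 8e6, marker_spacing_bp = 4000,
                    n_tracts_low = 10, n_tracts_high_indep = 5,
                    tract_length_bounds = c(1e5, 1e6),
                    cnv_n_segments = 0, n_genes = 40,
                    n_patients = 4, seed = 31)
  sim <- simulate_cohort(cfg)
  arms <- sim$annotation$arms
  params <- loh_params(min_events = 2, platform = "sequencing")
  low <- high <- list(); het <- list()
  for (p in names(sim$patients)) {
    gt <- sim$patients[[p]]$genotypes
    low[[p]] <- call_loh(gt, "germline", "Td", arms, params = params,
                         patient = p)
    high[[p]] <- call_loh(gt, "germline", "Tt", arms, params = params,
                          patient = p)
    het[[p]] <- tibble::tibble(patient = p,
                               chrom = gt$chrom[gt$germline == "AB"],
                               pos = gt$pos[gt$germline == "AB"])
  }
  tab <- gene_concurrence(dplyr::bind_rows(low), dplyr::bind_rows(high),
                          sim$annotation$genes, dplyr::bind_rows(het))
  expect_true(all(tab$n_concurrent_overlap <= tab$n_concurrent))
  expect_true(all(tab$n_concurrent <= tab$n_informative))
  expect_true(all(tab$n_informative <= length(sim$patients)))
})

test_that("goodness-of-fit enrichment matches a brute-force chi-square", {
  brute <- function(k, n, p0) {
    obs <- c(k, n - k)
    exp <- c(n * p0, n * (1 - p0))
    stat <- sum((obs - exp)^2 / exp)
    list(stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
  }
  withr::local_seed(17)
  for (i in 1:25) {
    n <- sample(50:1000, 1)
    k <- sample(0:n, 1)
    p0 <- stats::runif(1, 0.01, 0.6)
    got <- gof_enrichment(n, k, p0)
    want <- brute(k, n, p0)
    expect_equal(got$statistic, want$stat)
    expect_equal(got$p_value, want$p)
  }
  # observed exactly at expectation: statistic 0, p = 1
  flat <- gof_enrichment(100, 10, 0.1)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
})

test_that("published fragile-site and cancer-census tests reproduce", {
  fs <- gof_enrichment(429, 49, 0.084)
  expect_equal(round(fs$p_value, 2), 0.02)
  expect_equal(fs$statistic, 5.12, tolerance = 0.01)
  cc <- gof_enrichment(429, 12, 0.019)
  expect_equal(round(cc$p_value, 1), 0.2)
})

test_that("category_enrichment applies thresholds and baseline modes", {
  gene_table <- tibble::tibble(
    gene = sprintf("G%02d", 1:50),
    n_concurrent_overlap = c(rep(8, 10), rep(2, 20), rep(0, 20)),
    fragile_site = c(rep(TRUE, 5), rep(FALSE, 25), rep(TRUE, 5),
                     rep(FALSE, 15)))
  res <- category_enrichment(gene_table, "fragile_site", min_patients = 6,
                             baseline = "all_genes")
  expect_equal(res$n_top, 10)
  expect_equal(res$k_top, 5)
  expect_equal(res$baseline_prop, 10 / 50)
  res2 <- category_enrichment(gene_table, "fragile_site",
                              min_patients = 6,
                              baseline = "concurrent_genes")
  expect_equal(res2$baseline_prop, 5 / 30)
  td <- tidy(res)
  expect_equal(td$statistic, res$statistic)
})
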