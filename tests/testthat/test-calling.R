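scan_from_calls <- function(pos, germ, tiss, min_events) {
  scan_tracts(tibble::tibble(pos = pos,
                             transition = classify_transitions(germ, tiss)),
              min_events = min_events)
}

test_that("HOM->HOM separates but does not terminate a run", {
  tr <- scan_from_calls(c(100, 200, 300),
                        c("AB", "AA", "AB"), c("AA", "AA", "BB"),
                        min_events = 2)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 100)
  expect_equal(tr$end, 300)
  expect_equal(tr$n_events, 2L)
  expect_equal(tr$end - tr$start + 1, 201)
})

test_that("HET->HET terminates a run", {
  pos <- c(100, 200, 300)
  germ <- c("AB", "AB", "AB")
  tiss <- c("AA", "AB", "BB")
  expect_equal(nrow(scan_from_calls(pos, germ, tiss, 2)), 0)
  loose <- scan_from_calls(pos, germ, tiss, 1)
  expect_equal(nrow(loose), 2)
  expect_equal(loose$end - loose$start + 1, c(1, 1))
})

test_that("a single event under the loose criterion is a 1 bp tract", {
  tr <- scan_from_calls(5000, "AB", "AA", min_events = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$end - tr$start + 1, 1)
})

test_that("scan_tracts matches the brute-force run enumeration", {
  withr::local_seed(42)
  for (rep in 1:300) {
    n <- sample(2:50, 1)
    pos <- sort(sample(1:10000, n))
    germ <- random_calls(n)
    tiss <- random_calls(n)
    trans <- classify_transitions(germ, tiss)
    for (me in c(1, 2)) {
      got <- scan_tracts(tibble::tibble(pos = pos, transition = trans), me)
      want <- oracle_scan(pos, trans, me)
      expect_equal(got[c("start", "end", "n_events")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("stringent tracts are a subset of loose tracts", {
  withr::local_seed(7)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    pos <- sort(sample(1:10000, n))
    trans <- classify_transitions(random_calls(n), random_calls(n))
    blk <- tibble::tibble(pos = pos, transition = trans)
    strict <- scan_tracts(blk, 2)
    loose <- scan_tracts(blk, 1)
    expect_true(all(strict$start %in% loose$start))
    expect_true(all(strict$end %in% loose$end))
    total_events <- sum(trans == "HET_TO_HOM")
    expect_lte(sum(loose$n_events), total_events)
  }
})

test_that("gap threshold derivation reproduces the Tukey outer fence", {
  expect_equal(derive_gap_threshold(seq(0, 100, by = 10)), 225)
  expect_equal(derive_gap_threshold(rep(40000, 10)), 40000)
  expect_error(derive_gap_threshold(c(1, 2, 3)), "at least 4")
  expect_equal(loh_params()$gap_threshold_bp, 40000)
})

test_that("sparse gaps split copy-neutral tracts only, strictly above 40 kb", {
  base <- tibble::tibble(start = 10000, end = 60000, n_events = 2L,
                         events = list(c(10000, 60000)),
                         copy_state = "neutral", chrom = 1, arm = "p")
  # 50 kb gap: split, fragments fall below the stringent criterion
  out <- split_sparse(base, loh_params(min_events = 2))
  expect_equal(nrow(out), 0)
  out1 <- split_sparse(base, loh_params(min_events = 1))
  expect_equal(nrow(out1), 2)
  expect_equal(out1$start, c(10000, 60000))
  # gap exactly at the threshold: not split
  at <- dplyr::mutate(base, end = 50000, events = list(c(10000, 50000)))
  expect_equal(nrow(split_sparse(at, loh_params(min_events = 2))), 1)
  # copy-loss tracts are untouched
  loss <- dplyr::mutate(base, copy_state = "loss")
  expect_equal(split_sparse(loss, loh_params(min_events = 2)), loss)
})

test_that("splitting never lengthens tracts nor changes the event total", {
  withr::local_seed(11)
  for (rep in 1:30) {
    n_ev <- sample(2:20, 1)
    ev <- sort(sample(1:500000, n_ev))
    tr <- tibble::tibble(start = min(ev), end = max(ev),
                         n_events = n_ev, events = list(ev),
                         copy_state = "neutral", chrom = 1, arm = "p")
    out <- split_sparse(tr, loh_params(min_events = 1))
    expect_lte(max(out$end - out$start + 1), tr$end - tr$start + 1)
    expect_equal(sum(out$n_events), n_ev)
  }
})

test_that("QC excludes on strict 20% bounds over span loci", {
  pos <- seq(1000, 10000, by = 1000)
  germ <- c("AB", rep("AA", 8), "AB")
  make_loci <- function(tiss) {
    tibble::tibble(chrom = 1, pos = pos, germline = germ, tissue = tiss,
                   transition = classify_transitions(germ, tiss))
  }
  tracts <- tibble::tibble(chrom = 1, start = 1000, end = 10000)
  # 3 of 10 span loci monoallelic: dropped
  t3 <- c("AA", "AB", "AB", "AB", rep("AA", 5), "BB")
  expect_false(qc_filter(tracts, make_loci(t3))$qc_pass)
  # exactly 20%: retained
  t2 <- c("AA", "AB", "AB", rep("AA", 6), "BB")
  qc <- qc_filter(tracts, make_loci(t2))
  expect_true(qc$qc_pass)
  expect_equal(qc$qc_monoallelic, 0.2)
  # tissue no-call above 20% with everything else clean: dropped
  tnc <- c("AA", "NC", "NC", "NC", rep("AA", 5), "BB")
  qcn <- qc_filter(tracts, make_loci(tnc))
  expect_false(qcn$qc_pass)
  expect_equal(qcn$qc_nocall_tissue, 0.3)
})

test_that("QC decisions are invariant to allele relabeling", {
  withr::local_seed(3)
  relabel <- function(x) {
    dplyr::recode(x, AA = "BB", BB = "AA", AB = "AB", NC = "NC")
  }
  for (rep in 1:20) {
    pos <- seq(1000, 20000, by = 1000)
    germ <- random_calls(length(pos))
    tiss <- random_calls(length(pos))
    loci <- tibble::tibble(chrom = 1, pos = pos, germline = germ,
                           tissue = tiss,
                           transition = classify_transitions(germ, tiss))
    loci2 <- tibble::tibble(chrom = 1, pos = pos,
                            germline = relabel(germ),
                            tissue = relabel(tiss),
                            transition = classify_transitions(
                              relabel(germ), relabel(tiss)))
    tracts <- tibble::tibble(chrom = 1, start = 3000, end = 17000)
    expect_equal(qc_filter(tracts, loci)$qc_pass,
                 qc_filter(tracts, loci2)$qc_pass)
  }
})

test_that("CNV stratification assigns states and drops short segments", {
  arms <- toy_arms(p_len = 1e6, q_len = 1e6)
  pos <- seq(1e5, 1e6, by = 1e5)
  loci <- tibble::tibble(chrom = 1, pos = pos,
                         arm = assign_arm(tibble::tibble(chrom = 1,
                                                         pos = pos), arms))
  cnv <- tibble::tibble(chrom = 1, start = 450000, end = 820000,
                        state = "loss")
  out <- stratify_by_cnv(loci, cnv, loh_params(platform = "sequencing"))
  expect_equal(out$copy_state,
               c(rep("neutral", 4), rep("loss", 4), rep("neutral", 2)))
  expect_equal(length(unique(out$block)), 3)
  # an 80 kb segment is dropped under the sequencing-mode length filter
  short <- tibble::tibble(chrom = 1, start = 450000, end = 529999,
                          state = "loss")
  out2 <- stratify_by_cnv(loci, short, loh_params(platform = "sequencing"))
  expect_true(all(out2$copy_state == "neutral"))
  # ... but kept as given in array mode
  out3 <- stratify_by_cnv(loci, short, loh_params(platform = "array"))
  expect_true(any(out3$copy_state == "loss"))
  # overlapping segments are rejected
  bad <- tibble::tibble(chrom = 1, start = c(1e5, 2e5), end = c(3e5, 4e5),
                        state = c("loss", "gain"))
  expect_error(stratify_by_cnv(loci, bad, loh_params()), "overlapping CNV")
})

test_that("the full caller composes the stages", {
  arms <- toy_arms(p_len = 1e6, q_len = 1e6)
  # no informative germline loci: empty tract set
  gt0 <- make_gt(seq(1000, 9000, 1000), rep("AA", 9), rep("AA", 9))
  expect_equal(nrow(call_loh(gt0, "blood", "tumor", arms)), 0)
  # two events over a loss segment inherit the loss state
  pos <- c(1000, 2000, 3000, 4000)
  gt <- make_gt(pos, c("AB", "AB", "AA", "AB"),
                c("AA", "BB", "AA", "AB"))
  cnv <- tibble::tibble(chrom = 1, start = 500, end = 2500, state = "loss")
  tr <- call_loh(gt, "blood", "tumor", arms, cnv = cnv,
                 params = loh_params(min_events = 2, platform = "array"))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$copy_state, "loss")
  expect_equal(tr$start, 1000)
  expect_equal(tr$end, 2000)
  expect_equal(tr$length, 1001)
})
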