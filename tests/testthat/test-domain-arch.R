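test_that("segment extraction agrees with the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    x <- ifelse(runif(n) < runif(1, 0.2, 0.6), 1, -0.25)
    got <- rtarch:::extract_segments(x)
    want <- oracle_segments(x)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("broad caller: block in flat background, zero track, gap split", {
  mk <- function(v) binned_track(list(c1 = v), 1000)
  v <- rep(0, 200); v[81:120] <- 2  # 40-bin block in a ±0 background
  dom <- call_broad_domains(mk(v), n_perm = 200, seed = 1)
  expect_equal(length(dom), 1)
  expect_equal(BiocGenerics::start(dom) - 1, 80 * 1000)
  expect_equal(BiocGenerics::end(dom), 120 * 1000)
  # featureless track: no significant domains
  expect_equal(length(call_broad_domains(mk(rnorm(200, 0, 0.1)),
                                         n_perm = 200, seed = 1)), 0)
  # 20 depleted bins between two blocks cost 20 * 2.5 = 50 > 40, so the
  # bridge never pays and two maximal segments are called, not one
  v2 <- rep(0, 200); v2[41:80] <- 2; v2[101:140] <- 2
  dom2 <- call_broad_domains(mk(v2), gap_penalty = 2.5, n_perm = 200,
                             seed = 1)
  expect_equal(length(dom2), 2)
  expect_error(call_broad_domains(mk(v), n_perm = 50), "n_perm")
  expect_error(call_broad_domains(binned_track(list(c1 = rnorm(50)), 1000)),
               "informative")
})

test_that("planted RAD boundaries are recovered at depth 50", {
  spec <- synthetic_genome_spec(seed = 1, depth = 50)
  sim <- simulate_genome(spec, with_sequence = FALSE)
  assays <- simulate_replication_assays(spec, sim$truth)
  enr <- compute_enrichment(assays$chip_rif1, assays$input, 1)
  called <- call_broad_domains(enr, n_perm = 300, seed = 2)
  truth <- sim$truth$rads
  bs <- spec$bin_size
  ok <- 0; tot <- 0
  for (i in seq_along(truth)) {
    ch <- as.character(GenomicRanges::seqnames(truth))[i]
    cand <- called[as.character(GenomicRanges::seqnames(called)) == ch]
    if (!length(cand)) { tot <- tot + 2; next }
    ds <- min(abs(BiocGenerics::start(cand) - BiocGenerics::start(truth)[i]))
    de <- min(abs(BiocGenerics::end(cand) - BiocGenerics::end(truth)[i]))
    ok <- ok + (ds <= 2 * bs) + (de <= 2 * bs); tot <- tot + 2
  }
  expect_gte(ok / tot, 0.9)
})

test_that("overlap_venn: arithmetic cases and conservation", {
  a <- intervals("chr1", 0, 100); b <- intervals("chr1", 50, 150)
  v <- overlap_venn(a, b)
  expect_equal(v$unique_a, 50); expect_equal(v$unique_b, 50)
  expect_equal(v$shared, 50); expect_equal(v$jaccard, 1 / 3)
  v2 <- overlap_venn(a, a)
  expect_equal(v2$unique_a, 0); expect_equal(v2$jaccard, 1)
  # commutativity up to label swap + bp conservation on random sets
  set.seed(33)
  for (rep in 1:25) {
    A <- random_interval_set(12); B <- random_interval_set(9)
    v <- overlap_venn(A, B); w <- overlap_venn(B, A)
    expect_equal(v$shared, w$shared)
    expect_equal(v$unique_a, w$unique_b)
    expect_equal(v$unique_a + v$shared, sum(BiocGenerics::width(A)))
  }
})

test_that("overlap_venn matches the per-base boolean-mask oracle", {
  set.seed(34)
  for (rep in 1:100) {
    A <- random_interval_set(sample(3:15, 1))
    B <- random_interval_set(sample(3:15, 1))
    v <- overlap_venn(A, B); o <- oracle_venn(A, B)
    expect_identical(as.integer(v$unique_a), o$unique_a)
    expect_identical(as.integer(v$unique_b), o$unique_b)
    expect_identical(as.integer(v$shared), o$shared)
  }
})

test_that("partition_rads thresholds and order stability", {
  rads <- intervals("c1", c(0, 1000, 2000), c(500, 1500, 2500))
  lads <- intervals("c1", c(0, 1200), c(500, 1400))  # covers 100%, 40%, 0%
  p <- partition_rads(rads, lads, 0.5)
  expect_equal(BiocGenerics::start(p$lb_pos) - 1, 0)
  expect_equal(sort(BiocGenerics::start(p$lb_neg) - 1), c(1000, 2000))
  p2 <- partition_rads(rads, lads, 0.3)
  expect_equal(length(p2$lb_pos), 2)  # 40%-covered RAD crosses at 0.3
  expect_equal(length(p$lb_pos) + length(p$lb_neg), length(rads))
  # stable under input permutation
  perm <- c(3, 1, 2)
  pp <- partition_rads(rads[perm], lads, 0.5)
  expect_equal(sort(BiocGenerics::start(pp$lb_pos)),
               sort(BiocGenerics::start(p$lb_pos)))
  expect_error(partition_rads(rads, lads, 0), "min_lamin_frac")
})

test_that("late_genome_coverage adds up", {
  late <- intervals("c1", 0, 1000)
  rads <- intervals("c1", 0, 300)    # 30%
  lads <- intervals("c1", 300, 730)  # 43%, disjoint
  cov <- late_genome_coverage(late, rads, lads)
  expect_equal(unname(cov), c(0.30, 0.43, 0.73))
  # union fraction 1.0 when the covers contain the late set
  cov2 <- late_genome_coverage(late, intervals("c1", 0, 2000),
                               intervals("c1", 500, 600))
  expect_equal(unname(cov2["by_union"]), 1)
  expect_gte(cov["by_union"], max(cov["by_rads"], cov["by_lads"]))
  expect_error(late_genome_coverage(GenomicRanges::GRanges(), rads, lads),
               "empty")
})

test_that("planted coverage is recovered from called domains", {
  sim <- get_sim(1); assays <- get_assays(1)
  rt <- loess_smooth(compute_rt(assays$early_wt, assays$late_wt, 1), 3e5)
  dom <- segment_rt_domains(rt)
  late <- dom[S4Vectors::mcols(dom)$class == "late"]
  cov <- late_genome_coverage(late, sim$truth$rads, sim$truth$lads)
  planted <- late_genome_coverage(
    sim$truth$domains[S4Vectors::mcols(sim$truth$domains)$class == "late"],
    sim$truth$rads, sim$truth$lads)
  expect_lt(abs(cov["by_union"] - planted["by_union"]), 0.03)
})

test_that("switch-class enrichment separates LB- switchers", {
  sim <- get_sim(1); assays <- get_assays(1)
  rt_wt <- compute_rt(assays$early_wt, assays$late_wt, 1)
  rt_ko <- compute_rt(assays$early_ko, assays$late_ko, 1)
  sw <- classify_switches(rt_wt, rt_ko, sim$truth$domains)
  enr_r <- compute_enrichment(assays$chip_rif1, assays$input, 1)
  enr_l <- compute_enrichment(assays$chip_lamin, assays$input, 1)
  res <- enrichment_by_switch_class(sw, enr_r, enr_l)
  s <- res$summary
  med <- function(cl, fac) s$median[s$class == cl & s$factor == fac]
  # LtoE switches are planted only in lamin-free RADs
  expect_lt(med("LtoE", "lamin"), med("LtoL", "lamin"))
  expect_gt(med("LtoE", "rif1"), med("EtoE", "rif1"))
  # identical tracks for both factors give identical summaries
  res2 <- enrichment_by_switch_class(sw, enr_r, enr_r)
  expect_equal(res2$summary$median[res2$summary$factor == "rif1"],
               res2$summary$median[res2$summary$factor == "lamin"])
})
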