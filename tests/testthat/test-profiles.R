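test_that("meta-domain matrix: constant, step, and identity rescaling", {
  tr <- binned_track(list(c1 = rep(3.5, 200)), 1000)
  dom <- intervals("c1", c(40000, 120000), c(80000, 160000))
  mm <- meta_domain_matrix(dom, tr, n_body_bins = 10, flank_bp = 10000,
                           n_flank_bins = 5)
  expect_true(all(mm$matrix == 3.5))
  # +1 inside domains, 0 outside: body 1, outer flanks 0
  v <- rep(0, 200); v[41:80] <- 1
  tr2 <- binned_track(list(c1 = v), 1000)
  d2 <- intervals("c1", 40000, 80000)
  m2 <- meta_domain_matrix(d2, tr2, 10, 10000, 5)$matrix[1, ]
  expect_true(all(m2[6:15] == 1))       # body columns
  expect_true(all(m2[1:5] == 0))        # 5' flank
  expect_true(all(m2[16:20] == 0))      # 3' flank
  # a domain of exactly n_body_bins source bins reproduces the source
  set.seed(41)
  vals <- rnorm(50)
  tr3 <- binned_track(list(c1 = vals), 1000)
  d3 <- intervals("c1", 10000, 20000)
  m3 <- meta_domain_matrix(d3, tr3, 10, 5000, 5)$matrix[1, 6:15]
  expect_equal(unname(m3), vals[11:20], tolerance = 1e-9)
})

test_that("rescaling conserves the domain mean to 1e-9", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 120
    tr <- binned_track(list(c1 = rnorm(n)), 1000)
    len <- sample(c(20, 30, 40, 60), 1)  # exact multiples of 20 slots
    s <- sample.int(n - len - 1, 1)
    dom <- intervals("c1", s * 1000, (s + len) * 1000)
    mm <- meta_domain_matrix(dom, tr, n_body_bins = 20, flank_bp = 5000,
                             n_flank_bins = 5)
    body <- mm$matrix[1, mm$col_type == "body"]
    expect_equal(mean(body), mean(track_values(tr)$c1[(s + 1):(s + len)]),
                 tolerance = 1e-9)
  }
})

test_that("matrices are shift-equivariant", {
  set.seed(43)
  v <- rnorm(300)
  shift_bins <- 37
  tr <- binned_track(list(c1 = v), 500)
  tr_shift <- binned_track(list(c1 = c(rep(NA, shift_bins), v)), 500)
  loci <- intervals("c1", c(40000, 70000), c(40001, 70001))
  loci_shift <- GenomicRanges::shift(loci, shift_bins * 500)
  a <- point_signal_matrix(loci, tr, 5000)$matrix
  b <- point_signal_matrix(loci_shift, tr_shift, 5000)$matrix
  expect_equal(a, b)
})

test_that("point matrix: delta peak, flat track, strand flip, edge mask", {
  v <- rep(0, 100); v[51] <- 9
  tr <- binned_track(list(c1 = v), 100)
  loci <- intervals("c1", 5050, 5051)
  m <- point_signal_matrix(loci, tr, 1000)$matrix[1, ]
  expect_equal(which.max(m), 11)  # offset 0 of 21 columns
  # constant track: all rows identical regardless of position
  trc <- binned_track(list(c1 = rep(2, 100)), 100)
  loci2 <- intervals("c1", c(3000, 6000, 7000), c(3001, 6001, 7001))
  mc <- point_signal_matrix(loci2, trc, 500)$matrix
  expect_true(all(mc == 2))
  # minus-strand locus flips the window
  ramp <- binned_track(list(c1 = 1:100), 100)
  lp <- intervals("c1", 5050, 5051); BiocGenerics::strand(lp) <- "-"
  lm <- intervals("c1", 5050, 5051)
  expect_equal(point_signal_matrix(lp, ramp, 500)$matrix[1, ],
               rev(point_signal_matrix(lm, ramp, 500)$matrix[1, ]))
  # near-edge locus is masked outside the chromosome
  me <- point_signal_matrix(intervals("c1", 100, 101), tr, 1000)$matrix[1, ]
  expect_true(all(is.na(me[1:9])))
  expect_false(anyNA(me[10:21]))
})

test_that("k-means recovers planted archetypes (ARI > 0.95 at sigma 0.3)", {
  set.seed(44)
  ari <- function(a, b) {  # adjusted Rand index, contingency form
    tab <- table(a, b)
    sc <- function(x) sum(choose(x, 2))
    n <- length(a)
    e <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
    (sc(tab) - e) / ((sc(rowSums(tab)) + sc(colSums(tab))) / 2 - e)
  }
  arch <- rbind(c(rep(2, 10), rep(0, 10)), c(rep(0, 10), rep(2, 10)))
  res <- replicate(10, {
    lab <- sample(1:2, 60, replace = TRUE)
    m <- arch[lab, ] + rnorm(60 * 20, 0, 0.3)
    sol <- cluster_rows(m, k = 2, seed = 7)
    ari(lab, sol$assignment)
  })
  expect_true(all(res > 0.95))
})

test_that("clustering is label-deterministic and permutation-invariant", {
  set.seed(45)
  m <- rbind(matrix(rnorm(200, 5), 10), matrix(rnorm(200, 0), 10))
  a <- cluster_rows(m, 2, seed = 3)
  b <- cluster_rows(m, 2, seed = 99)
  expect_equal(a$assignment, b$assignment)  # labels fixed by mean signal
  expect_true(all(a$assignment[1:10] == 1))  # strongest cluster is label 1
  perm <- sample(20)
  p <- cluster_rows(m[perm, ], 2, seed = 3)
  expect_equal(p$assignment, a$assignment[perm])
  # degenerate identical rows collapse into one flagged cluster
  d <- cluster_rows(matrix(1, 10, 5), 3, seed = 1)
  expect_true(d$degenerate)
  expect_equal(d$sizes, c(10L, 0L, 0L))
  expect_error(cluster_rows(m, 25), "rows")
})

test_that("cluster RT summary preserves cluster structure", {
  sol <- structure(list(k = 2, assignment = c(1, 1, 2, 2), seed = 1),
                   class = "ClusterSolution")
  s <- cluster_rt_summary(sol, c(-2, -2, 2, 2), c(0, 0, 2, 2))
  expect_equal(s$median[s$cluster == 1 & s$genotype == "wt"], -2)
  expect_equal(s$median[s$cluster == 1 & s$genotype == "ko"], 0)
  expect_equal(s$median[s$cluster == 2 & s$genotype == "wt"], 2)
  expect_error(cluster_rt_summary(sol, 1:3, 1:3), "align")
  # clusters built from RT separate within/between variance
  set.seed(46)
  rtv <- c(rnorm(20, -2, 0.2), rnorm(20, 2, 0.2))
  sol2 <- cluster_rows(cbind(rtv, rtv), 2, seed = 1)
  within <- stats::var(rtv[sol2$assignment == 1]) +
    stats::var(rtv[sol2$assignment == 2])
  expect_lt(within, stats::var(rtv))
})

test_that("planted Rif1 peaks appear only in the CpG-rich TSS stratum", {
  sim <- get_sim(1); assays <- get_assays(1)
  enr_fine <- compute_enrichment(assays$chip_rif1_fine, assays$input_fine, 1)
  tss <- sim$truth$tss
  m <- point_signal_matrix(tss, enr_fine, 5000)
  rich <- sim$truth$cpg_rich_tss
  prof_rich <- colMeans(m$matrix[rich, ], na.rm = TRUE)
  prof_poor <- colMeans(m$matrix[!rich, ], na.rm = TRUE)
  centre <- which(m$col_coord == 0)
  expect_gt(prof_rich[centre], 2)                   # focal peak present
  expect_lt(max(abs(prof_poor)), 0.5)               # other strata flat
  # planted peak is a ±1-kb plateau; its maximum lies within it
  expect_true(which.max(prof_rich) %in% (centre - 2):(centre + 2))
  expect_lt(max(abs(prof_rich[c(1:4, 18:21)])), 0.5)  # distal flanks flat
})
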