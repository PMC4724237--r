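test_that("digestion: hand fixture, motif-free case, counting oracle", {
  # motifs at 100 and 200; HindIII-style cut offset 1 => cuts at 101, 201
  s <- paste0(strrep("T", 100), "AAGCTT", strrep("T", 94), "AAGCTT",
              strrep("T", 94))
  fm <- digest_sequence(c(c1 = s))
  expect_equal(fm$fragments$start, c(0, 101, 201))
  expect_equal(fm$fragments$end, c(101, 201, 300))
  expect_equal(nrow(digest_sequence(c(c1 = strrep("A", 500)))$fragments), 1)
  set.seed(61)
  r <- random_dna(1e6, gc = 0.5)
  n_motif <- length(gregexpr("AAGCTT", r, fixed = TRUE)[[1]])
  if (gregexpr("AAGCTT", r, fixed = TRUE)[[1]][1] == -1) n_motif <- 0
  fm2 <- digest_sequence(c(c1 = r))
  expect_equal(nrow(fm2$fragments), n_motif + 1)
  expect_error(digest_sequence(c(c1 = r), motif = "AC"), "motif")
  # viewpoint-to-fragment lookup
  vp <- intervals("c1", 150, 151)
  expect_equal(viewpoint_fragments(fm, vp), 2L)
  expect_error(viewpoint_fragments(
    structure(list(fragments = fm$fragments[0, ]), class = "FragmentMap"),
    vp), "no fragment")
})

test_that("RPM normalisation: definition, scale invariance, exclusion", {
  cnt <- data.frame(chrom = "c1", start = (0:9) * 100, end = (1:10) * 100,
                    count = c(500, 400, 50, 10, 10, 10, 10, 5, 3, 2))
  # viewpoint at 150: fragment midpoints within ±200 bp (inclusive) are
  # excluded, i.e. mids 50, 150, 250, 350
  r <- rpm_normalize(cnt, "c1", 150, exclude_bp = 200)
  expect_true(all(is.na(r$rpm[1:4])))
  total <- sum(cnt$count[5:10])
  expect_equal(r$rpm[5], 10 * 1e6 / total)
  expect_equal(sum(r$rpm, na.rm = TRUE), 1e6, tolerance = 1e-6)
  # doubling counts leaves RPM unchanged
  cnt2 <- cnt; cnt2$count <- cnt2$count * 2
  expect_equal(rpm_normalize(cnt2, "c1", 150, 200)$rpm, r$rpm)
  cnt0 <- cnt; cnt0$count[4:10] <- 0
  expect_error(rpm_normalize(cnt0, "c1", 150, 200), "zero library")
})

test_that("contact calling: agreement, consistency, monotonicity", {
  set.seed(62)
  n <- 400
  frag <- data.frame(chrom = "c1", start = (0:(n - 1)) * 4000,
                     end = (1:n) * 4000)
  vp_pos <- 200 * 4000
  mk_rep <- function(extra_idx, extra_rpm) {
    d <- abs((frag$start + frag$end) / 2 - vp_pos)
    lam <- 3e5 * (d + 2000)^-2 / sum((d + 2000)^-2)
    lam[extra_idx] <- lam[extra_idx] + extra_rpm * 0.3
    cnt <- frag; cnt$count <- rpois(n, lam)
    rpm_normalize(cnt, "c1", vp_pos, 10000)
  }
  planted <- c(40, 100, 340)
  r1 <- mk_rep(planted, 300); r2 <- mk_rep(planted, 300)
  cs <- call_contacts(r1, r2, "c1", vp_pos)
  expect_true(all(cs$table$consistent[planted]))
  # symmetric in replicate order
  cs_swap <- call_contacts(r2, r1, "c1", vp_pos)
  expect_equal(cs$table$consistent, cs_swap$table$consistent)
  # called in one replicate only is not consistent
  r3 <- mk_rep(integer(0), 0)
  cs2 <- call_contacts(r1, r3, "c1", vp_pos)
  expect_false(any(cs2$table$consistent[planted] &
                     !cs2$table$called2[planted]))
  expect_true(all(cs2$table$consistent == (cs2$table$called1 &
                                             cs2$table$called2)))
  # raising min_rpm never increases the consistent count
  counts <- vapply(c(10, 20, 50, 100), function(mr)
    sum(call_contacts(r1, r2, "c1", vp_pos, min_rpm = mr)$table$consistent),
    0)
  expect_true(all(diff(counts) <= 0))
  expect_error(call_contacts(r1, r2[1:10, ], "c1", vp_pos), "grids")
})

test_that("RPM-range comparison: identity and constructed gain fixture", {
  set.seed(63)
  mk_set <- function(rpms) {
    tab <- data.frame(chrom = "c1", start = seq_along(rpms) * 1000,
                      end = seq_along(rpms) * 1000 + 999,
                      mid = seq_along(rpms) * 1000 + 500,
                      distance = seq_along(rpms) * 1000,
                      rpm1 = rpms, rpm2 = rpms, rpm = rpms,
                      called1 = TRUE, called2 = TRUE, consistent = TRUE)
    structure(list(table = tab, viewpoint = list(chrom = "c1", pos = 0),
                   min_rpm = 10, call_factor = 3), class = "ContactSet")
  }
  wt <- list(a = mk_set(c(50, 60, 300)), b = mk_set(c(40, 70, 500)),
             c = mk_set(c(30, 80, 250)))
  cmp <- rpm_bin_compare(wt, wt)
  expect_true(all(cmp$fold == 1))
  # knockout adds 50 contacts at RPM 15: low-mid range grows, high does not
  ko <- lapply(wt, function(s) {
    extra <- mk_set(rep(15, 50))$table
    s$table <- rbind(s$table, extra); s
  })
  cmp2 <- rpm_bin_compare(wt, ko)
  expect_gt(cmp2$fold[["[10,200)"]], 1)
  expect_equal(cmp2$fold[["[200,Inf)"]], 1)
  expect_error(rpm_bin_compare(wt[1], wt[1]), "viewpoints")
  # degenerate variance flagged, not computed
  expect_equal(cmp$tests$flag[1], "degenerate")
})

test_that("scope classification counts cis and intra-domain contacts", {
  mk_tab <- function(chrom, mid) {
    data.frame(chrom = chrom, start = mid - 500, end = mid + 500, mid = mid,
               distance = NA, rpm1 = 50, rpm2 = 50, rpm = 50,
               called1 = TRUE, called2 = TRUE, consistent = TRUE)
  }
  tab <- rbind(mk_tab("c1", 5e5), mk_tab("c1", 9e5 - 1), mk_tab("c1", 9e5 + 1),
               mk_tab("c2", 5e5))
  cs <- structure(list(table = tab, viewpoint = list(chrom = "c1", pos = 5e5),
                       min_rpm = 10, call_factor = 3), class = "ContactSet")
  dom <- intervals("c1", 1e5, 9e5)
  sc <- classify_scope(cs, dom)
  # fragment midpoints decide domain membership: 9e5-1 in, 9e5+1 out
  expect_equal(unname(sc), c(3, 2, 4))
  expect_error(classify_scope(
    structure(list(table = tab, viewpoint = list(chrom = "c2", pos = 5e5)),
              class = "ContactSet"), dom), "inside")
  # all contacts inside the domain: intra == cis
  cs2 <- cs; cs2$table <- mk_tab("c1", 5e5)
  expect_equal(unname(classify_scope(cs2, dom)[c("cis", "intra")]), c(1, 1))
})

test_that("TAD RT specificity separates shared from gained", {
  tads <- intervals("c1", c(0, 1e6, 2e6, 3e6), c(1e6, 2e6, 3e6, 4e6))
  rt <- binned_track(list(c1 = c(rep(-2, 40), rep(2, 40))), 50000)
  mk_cs <- function(mids) {
    tab <- data.frame(chrom = "c1", start = mids - 100, end = mids + 100,
                      mid = mids, distance = NA, rpm1 = 50, rpm2 = 50,
                      rpm = 50, called1 = TRUE, called2 = TRUE,
                      consistent = TRUE)
    structure(list(table = tab, viewpoint = list(chrom = "c1", pos = 5e5),
                   min_rpm = 10, call_factor = 3), class = "ContactSet")
  }
  wt <- mk_cs(c(5e5, 15e5))
  ko <- mk_cs(c(5e5, 15e5, 25e5, 35e5))
  res <- tad_rt_specificity(wt, ko, tads, rt)
  expect_equal(length(res$shared_tads), 2)
  expect_equal(length(res$gained_tads), 2)
  expect_equal(res$median_shared, -2)  # shared TADs lie in the late half
  expect_equal(res$median_gained, 2)   # gained lie in the early half
  # knockout identical to wild type: nothing gained
  res2 <- tad_rt_specificity(wt, wt, tads, rt)
  expect_equal(length(res2$gained_tads), 0)
  # single shared TAD: median equals that TAD's contact RT
  res3 <- tad_rt_specificity(mk_cs(5e5), mk_cs(5e5), tads, rt)
  expect_equal(res3$median_shared, -2)
  expect_error(tad_rt_specificity(wt, ko, c(tads, tads[1]), rt),
               "non-overlapping")
})
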