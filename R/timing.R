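#' Replication timing score from early/late fraction counts
#'
#' RT is the per-bin log2 ratio of early-fraction to late-fraction reads,
#' `log2((early + p) / (late + p))`; positive values replicate early. With
#' pseudocount 0, bins where either count is 0 are masked (the ratio is
#' undefined or infinite).
#'
#' @param early,late `BinnedTrack`s of fraction read counts on one grid.
#' @param pseudocount non-negative value added to both counts.
#' @return a `BinnedTrack` of RT scores.
#' @examples
#' e <- binned_track(c(40, 10)); l <- binned_track(c(10, 10))
#' track_values(compute_rt(e, l))$chr1  # 2, 0
#' @export
compute_rt <- function(early, late, pseudocount = 0) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  track_map(function(e, l) {
    v <- log2((e + pseudocount) / (l + pseudocount))
    if (pseudocount == 0) v[e == 0 | l == 0] <- NA_real_
    v[!is.finite(v)] <- NA_real_
    v
  }, early, late)
}

#' @rdname compute_rt
#' @param chip,input ChIP and input coverage tracks; enrichment is the same
#'   log2 ratio, `log2((chip + p) / (input + p))`.
#' @export
compute_enrichment <- function(chip, input, pseudocount = 0)
  compute_rt(chip, input, pseudocount)

#' Loess-smooth a binned profile
#'
#' Locally weighted regression (degree-1 loess) per chromosome, with the
#' span expressed in base pairs. Masked bins are excluded from the fits;
#' output bins are masked where the smoothing window holds fewer than 5
#' informative bins.
#'
#' @param rt a `BinnedTrack`.
#' @param span_bp smoothing span in bp; must cover at least 5 bins.
#' @return a smoothed `BinnedTrack` on the same grid.
#' @export
loess_smooth <- function(rt, span_bp = 300000) {
  if (span_bp < 5 * rt$bin_size)
    stop("span too small: must cover at least 5 bins (>= ",
         5 * rt$bin_size, " bp)")
  half <- span_bp / 2
  vals <- lapply(rt$values, function(v) {
    n <- length(v)
    x <- (seq_len(n) - 0.5) * rt$bin_size
    ok <- !is.na(v)
    out <- rep(NA_real_, n)
    if (sum(ok) >= 5) {
      fit <- stats::loess(v[ok] ~ x[ok], degree = 1,
                          span = min(1, span_bp / (diff(range(x[ok])) +
                                                     rt$bin_size)),
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      pred <- stats::predict(fit, newdata = x)
      ## mask where too few informative bins fall in the local window
      cnt <- vapply(x, function(xx) sum(ok & abs(x - xx) <= half), 0L)
      pred[cnt < 5] <- NA_real_
      out <- pred
    }
    out
  })
  binned_track(vals, rt$bin_size)
}

#' Genome-wide RT distribution and bimodality
#'
#' Resamples RT values onto fixed-width tiles (each bin contributes
#' `bin_size / tile_bp` tiles) and summarises the genome-wide score
#' distribution with a histogram and Sarle's bimodality coefficient
#' `b = (skewness^2 + 1) / (kurtosis + 3 (n-1)^2 / ((n-2)(n-3)))`. Values
#' of `b` above 5/9 indicate departure from unimodality, so loss of the
#' early/late bimodal structure shows up as a coefficient drop.
#'
#' @param tracks a `BinnedTrack` or list of them (values pooled).
#' @param tile_bp tile width in bp (60 by default).
#' @param breaks histogram breaks passed to [graphics::hist()] semantics.
#' @return list with `histogram` (counts + mids), `bimodality` and `n`.
#' @export
rt_distribution <- function(tracks, tile_bp = 60, breaks = 80) {
  if (inherits(tracks, "BinnedTrack")) tracks <- list(tracks)
  if (length(tracks) == 0) stop("empty input: need at least one track")
  pooled <- unlist(lapply(tracks, function(tr) {
    k <- max(1L, round(tr$bin_size / tile_bp))
    v <- unlist(tr$values, use.names = FALSE)
    rep(v[!is.na(v)], each = k)
  }), use.names = FALSE)
  n <- length(pooled)
  if (n < 4) stop("too few informative values")
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  m <- mean(pooled); s <- stats::sd(pooled)
  if (s == 0) {
    b <- NA_real_
  } else {
    z <- (pooled - m) / s
    skew <- mean(z^3) * n^2 / ((n - 1) * (n - 2))
    kurt <- sum(z^4) * n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3))
    b <- (skew^2 + 1) / (kurt + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  }
  list(histogram = list(counts = h$counts, mids = h$mids, breaks = h$breaks),
       bimodality = b, n = n)
}

#' Segment an RT profile into early/late/intermediate domains
#'
#' Bins are classified against the thresholds (`early` when
#' `rt > early_thr`, `late` when `rt < late_thr`, `intermediate`
#' otherwise); gaps shorter than `min_len_bp` inside an early or late run
#' are closed (early first, then late on the remaining bins); maximal runs
#' become domains.
#'
#' @param rt a `BinnedTrack` (typically loess-smoothed).
#' @param early_thr,late_thr class thresholds; `early_thr > late_thr`.
#' @param min_len_bp gaps shorter than this inside a class run are
#'   absorbed into the run.
#' @return a `GRanges` of domains with mcols `class` and `mean_rt`, plus a
#'   `summary` attribute (domain count and size quantiles per class) used
#'   as the fragmentation readout.
#' @export
segment_rt_domains <- function(rt, early_thr = 0.5, late_thr = -0.5,
                               min_len_bp = 200000) {
  if (!(early_thr > late_thr)) stop("early_thr must exceed late_thr")
  min_bins <- max(1L, round(min_len_bp / rt$bin_size))
  close_gaps <- function(flag) {
    r <- rle(flag)
    cs <- cumsum(r$lengths)
    for (i in seq_along(r$values)) {
      if (!r$values[i] && r$lengths[i] < min_bins &&
          i > 1 && i < length(r$values))
        flag[(cs[i] - r$lengths[i] + 1):cs[i]] <- TRUE
    }
    flag
  }
  rows <- list()
  for (ch in names(rt$values)) {
    v <- rt$values[[ch]]
    is_early <- close_gaps(!is.na(v) & v > early_thr)
    is_late <- close_gaps(!is.na(v) & v < late_thr) & !is_early
    cls <- rep("intermediate", length(v))
    cls[is_early] <- "early"; cls[is_late] <- "late"
    r <- rle(cls)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    rows[[ch]] <- data.frame(
      chrom = ch, start = (starts - 1) * rt$bin_size,
      end = ends * rt$bin_size, class = r$values,
      mean_rt = vapply(seq_along(starts), function(i)
        mean(v[starts[i]:ends[i]], na.rm = TRUE), 0),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- intervals(df$chrom, df$start, df$end, class = df$class,
                  mean_rt = df$mean_rt)
  size <- df$end - df$start
  attr(gr, "summary") <- lapply(split(size, df$class), function(s)
    c(n = length(s), total_bp = sum(s), median_bp = stats::median(s)))
  gr
}

#' Classify RT switches between genotypes
#'
#' Per baseline domain, the switch score is the mean RT difference
#' `mean(rt_ko) - mean(rt_wt)` over the domain's bins (unsmoothed tracks).
#' Domains changing RT by more than `delta_thr` in the direction opposite
#' their baseline class switch (`LtoE` when baseline late and change >
#' +`delta_thr`; `EtoL` when baseline early and change < -`delta_thr`);
#' the rest keep their class (`LtoL`, `EtoE`); baseline-intermediate
#' domains are `unclassified`.
#'
#' @param rt_wt,rt_ko RT `BinnedTrack`s on one grid.
#' @param baseline_domains `GRanges` from [segment_rt_domains()] on the
#'   wild-type profile (mcol `class` required).
#' @param delta_thr switch threshold on the mean RT change (default 1).
#' @return a `GRanges` copy of the baseline domains with mcols
#'   `delta_rt` and `switch_class`; the per-bin RT-change track is attached
#'   as attribute `delta_track` (for scatter displays).
#' @export
classify_switches <- function(rt_wt, rt_ko, baseline_domains, delta_thr = 1) {
  check_same_grid(rt_wt, rt_ko)
  delta <- track_map(function(a, b) b - a, rt_wt, rt_ko)
  gr <- baseline_domains
  n <- length(gr)
  dmean <- domain_track_mean(gr, delta)
  cls <- as.character(S4Vectors::mcols(gr)$class)
  sw <- character(n)
  for (i in seq_len(n)) {
    sw[i] <- if (is.na(dmean[i]) || cls[i] == "intermediate") "unclassified"
    else if (cls[i] == "late" && dmean[i] > delta_thr) "LtoE"
    else if (cls[i] == "early" && dmean[i] < -delta_thr) "EtoL"
    else if (cls[i] == "late") "LtoL" else "EtoE"
  }
  S4Vectors::mcols(gr)$delta_rt <- dmean
  S4Vectors::mcols(gr)$switch_class <- sw
  attr(gr, "delta_track") <- delta
  gr
}

#' Mean track value over each interval
#'
#' Length-weighted mean of the bins overlapped by each interval; `NA` bins
#' are excluded, all-masked intervals give `NA`.
#' @param gr a `GRanges`.
#' @param track a `BinnedTrack`.
#' @return numeric vector along `gr`.
#' @export
domain_track_mean <- function(gr, track) {
  bs <- track$bin_size
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- BiocGenerics::start(gr) - 1
  e <- BiocGenerics::end(gr)
  vapply(seq_along(gr), function(i) {
    v <- track$values[[chrom[i]]]
    if (is.null(v)) return(NA_real_)
    b0 <- floor(s[i] / bs) + 1
    b1 <- min(length(v), ceiling(e[i] / bs))
    if (b1 < b0) return(NA_real_)
    mean(v[b0:b1], na.rm = TRUE)
  }, 0)
}

#' Fraction of switch-region edges near reference boundaries
#'
#' For every edge (start and end) of the switching regions, the distance to
#' the nearest reference boundary is computed; the concordance is the
#' fraction of edges within `tol_bp`.
#'
#' @param switch_calls `GRanges` with mcol `switch_class`; only `LtoE` and
#'   `EtoL` regions contribute edges (all regions when the mcol is absent).
#' @param reference `GRanges` whose starts/ends define reference
#'   boundaries.
#' @param tol_bp distance tolerance in bp.
#' @return fraction in [0, 1].
#' @export
boundary_concordance <- function(switch_calls, reference, tol_bp) {
  if (length(switch_calls) == 0 || length(reference) == 0)
    stop("empty input")
  mc <- S4Vectors::mcols(switch_calls)
  if ("switch_class" %in% names(mc))
    switch_calls <- switch_calls[mc$switch_class %in% c("LtoE", "EtoL")]
  if (length(switch_calls) == 0) return(NA_real_)
  edge_pos <- function(gr) {
    data.frame(chrom = rep(as.character(GenomicRanges::seqnames(gr)), 2),
               pos = c(BiocGenerics::start(gr) - 1, BiocGenerics::end(gr)))
  }
  edges <- edge_pos(switch_calls)
  refs <- edge_pos(reference)
  hit <- vapply(seq_len(nrow(edges)), function(i) {
    d <- abs(refs$pos[refs$chrom == edges$chrom[i]] - edges$pos[i])
    length(d) > 0 && min(d) <= tol_bp
  }, TRUE)
  mean(hit)
}
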