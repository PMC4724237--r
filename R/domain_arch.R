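## Maximal positive-scoring segment machinery.
##
## Bin scores are +1 (enriched: above the chromosome median) or
## -gap_penalty (depleted). Disjoint positive segments are extracted
## greedily: the best-scoring segment (ties: leftmost start, then longest)
## is taken, its bins are excluded, and the extraction recurses left and
## right. Scores are sums of +1 and -gap_penalty terms, exact in binary
## floating point for dyadic penalties such as the default 4.

## best segment of x in [lo, hi]: list(start, end, score) or NULL
best_segment <- function(x, lo, hi) {
  if (hi < lo) return(NULL)
  best_s <- -Inf; best_i <- NA; best_j <- NA
  run <- 0; run_start <- lo
  min_p <- 0; min_idx <- lo - 1
  p <- 0
  for (j in lo:hi) {
    p <- p + x[j]
    s <- p - min_p
    i <- min_idx + 1
    if (s > best_s ||
        (s == best_s && (i < best_i || (i == best_i && j > best_j)))) {
      best_s <- s; best_i <- i; best_j <- j
    }
    if (p < min_p) { min_p <- p; min_idx <- j }
  }
  if (best_s <= 0) return(NULL)
  list(start = best_i, end = best_j, score = best_s)
}

## all disjoint maximal positive segments, greedy order-independent form
extract_segments <- function(x) {
  out <- list()
  stack <- list(c(1L, length(x)))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    seg <- best_segment(x, rng[1], rng[2])
    if (is.null(seg)) next
    out[[length(out) + 1]] <- seg
    if (seg$start - 1 >= rng[1])
      stack[[length(stack) + 1]] <- c(rng[1], seg$start - 1L)
    if (seg$end + 1 <= rng[2])
      stack[[length(stack) + 1]] <- c(seg$end + 1L, rng[2])
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      score = numeric(0)))
  df <- data.frame(start = vapply(out, `[[`, 0, "start"),
                   end = vapply(out, `[[`, 0, "end"),
                   score = vapply(out, `[[`, 0, "score"))
  df[order(df$start), , drop = FALSE]
}

#' Call broad enrichment domains (RAD/LAD-style)
#'
#' A simplified broad-domain caller in the spirit of enriched-domain
#' detection from log-ratio tracks: bins are binarized against the
#' chromosome-wide median of informative bins (+1 enriched,
#' `-gap_penalty` depleted; masked bins count as depleted), maximal
#' disjoint positive-scoring segments are extracted per chromosome, and
#' segment significance is assessed by permuting the binarized labels
#' within each chromosome (`n_perm` draws): the permutation p-value of a
#' segment is the fraction of null segment scores (pooled over all
#' permutations) reaching its observed score. Benjamini-Hochberg control
#' across segments at
#' `fdr`; called domains separated by fewer than `merge_gap_bins` bins are
#' merged.
#'
#' @param enrichment a `BinnedTrack` of log2 ChIP/input values.
#' @param gap_penalty positive score charged to depleted bins (default
#'   4; smaller values bridge longer depleted gaps). Values below 1 make
#'   the expected segment drift positive under median binarization (half
#'   of all bins are enriched by construction) and degenerate to
#'   chromosome-scale segments; keep `gap_penalty > 1`.
#' @param n_perm number of label permutations (>= 100).
#' @param fdr Benjamini-Hochberg threshold.
#' @param seed RNG seed for the permutations.
#' @param merge_gap_bins called domains closer than this many bins merge.
#' @return a `GRanges` of domains with mcols `score` (segment score),
#'   `mean_enrichment`, `pval` and `qval`, sorted by position.
#' @export
call_broad_domains <- function(enrichment, gap_penalty = 4,
                               n_perm = 1000, fdr = 0.05, seed = 1,
                               merge_gap_bins = 2) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  for (ch in names(enrichment$values))
    if (sum(!is.na(enrichment$values[[ch]])) < 100)
      stop("too few informative bins on ", ch, " (need >= 100)")
  set.seed(seed)
  bs <- enrichment$bin_size
  segs <- list()
  for (ch in names(enrichment$values)) {
    v <- enrichment$values[[ch]]
    med <- stats::median(v, na.rm = TRUE)
    x <- ifelse(!is.na(v) & v > med, 1, -gap_penalty)
    df <- extract_segments(x)
    if (nrow(df) == 0) next
    ## permutation null: pooled positive-segment scores under label
    ## shuffling (per-segment, not family-wise maximum)
    null_pool <- sort(unlist(lapply(seq_len(n_perm), function(i)
      extract_segments(sample(x))$score)))
    n_null <- length(null_pool)
    df$pval <- vapply(df$score, function(s)
      (1 + n_null - findInterval(s - 1e-9, null_pool)) / (n_null + 1), 0)
    df$chrom <- ch
    df$mean_enrichment <- vapply(seq_len(nrow(df)), function(i)
      mean(v[df$start[i]:df$end[i]], na.rm = TRUE), 0)
    segs[[ch]] <- df
  }
  if (!length(segs))
    return(GenomicRanges::GRanges())
  all <- do.call(rbind, segs)
  all$qval <- stats::p.adjust(all$pval, method = "BH")
  all <- all[all$qval <= fdr, , drop = FALSE]
  if (nrow(all) == 0)
    return(GenomicRanges::GRanges())
  ## merge near-adjacent calls per chromosome
  all <- all[order(all$chrom, all$start), ]
  merged <- list()
  for (ch in unique(all$chrom)) {
    sub <- all[all$chrom == ch, ]
    grp <- integer(nrow(sub)); g <- 1; grp[1] <- 1
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      if (sub$start[i] - sub$end[i - 1] - 1 < merge_gap_bins) grp[i] <- g
      else { g <- g + 1; grp[i] <- g }
    }
    v <- enrichment$values[[ch]]
    for (g in unique(grp)) {
      s <- sub[grp == g, ]
      merged[[length(merged) + 1]] <- data.frame(
        chrom = ch, b0 = min(s$start), b1 = max(s$end),
        score = sum(s$score), pval = min(s$pval), qval = min(s$qval),
        mean_enrichment = mean(v[min(s$start):max(s$end)], na.rm = TRUE))
    }
  }
  m <- do.call(rbind, merged)
  m <- m[order(m$chrom, m$b0), ]
  intervals(m$chrom, (m$b0 - 1) * bs, m$b1 * bs,
            score = m$score, mean_enrichment = m$mean_enrichment,
            pval = m$pval, qval = m$qval)
}

#' Base-pair Venn overlap of two interval sets
#'
#' Exact base-pair accounting between two interval sets (each is merged
#' first so internal overlaps do not double count).
#'
#' @param a,b `GRanges`.
#' @return list of class `OverlapSummary`: `unique_a`, `unique_b`,
#'   `shared` (bp) and `jaccard = shared / (unique_a + unique_b + shared)`.
#' @examples
#' a <- intervals("chr1", 0, 100); b <- intervals("chr1", 50, 150)
#' overlap_venn(a, b)  # unique 50/50, shared 50, Jaccard 1/3
#' @export
overlap_venn <- function(a, b) {
  a <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  b <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  shared <- sum(BiocGenerics::width(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  wa <- sum(BiocGenerics::width(a)); wb <- sum(BiocGenerics::width(b))
  structure(list(unique_a = wa - shared, unique_b = wb - shared,
                 shared = shared,
                 jaccard = if (wa + wb - shared > 0)
                   shared / (wa + wb - shared) else NA_real_),
            class = "OverlapSummary")
}

#' Partition RADs by lamin co-occupancy
#'
#' A RAD is LB+ when at least `min_lamin_frac` of its length is covered by
#' LADs, LB- otherwise ("mostly bound by Rif1 alone"). The partition is
#' exhaustive and exclusive.
#'
#' @param rads,lads `GRanges`.
#' @param min_lamin_frac coverage threshold in (0, 1].
#' @return list with `lb_pos` and `lb_neg` (`GRanges`, each with mcol
#'   `lamin_frac`).
#' @export
partition_rads <- function(rads, lads, min_lamin_frac = 0.5) {
  if (min_lamin_frac <= 0 || min_lamin_frac > 1)
    stop("min_lamin_frac must lie in (0, 1]")
  lads <- GenomicRanges::reduce(lads, ignore.strand = TRUE)
  frac <- vapply(seq_along(rads), function(i) {
    hit <- GenomicRanges::intersect(rads[i], lads, ignore.strand = TRUE)
    sum(BiocGenerics::width(hit)) / BiocGenerics::width(rads[i])
  }, 0)
  out_pos <- rads[frac >= min_lamin_frac]
  out_neg <- rads[frac < min_lamin_frac]
  S4Vectors::mcols(out_pos)$lamin_frac <- frac[frac >= min_lamin_frac]
  S4Vectors::mcols(out_neg)$lamin_frac <- frac[frac < min_lamin_frac]
  list(lb_pos = out_pos, lb_neg = out_neg)
}

#' Coverage of the late-replicating genome by RADs/LADs
#'
#' Fractions of late-domain base pairs covered by RADs, by LADs, and by
#' their union.
#'
#' @param late `GRanges` of late-replicating domains (non-empty).
#' @param rads,lads `GRanges`.
#' @return named numeric vector: `by_rads`, `by_lads`, `by_union`.
#' @export
late_genome_coverage <- function(late, rads, lads) {
  if (length(late) == 0) stop("empty late-domain set")
  late <- GenomicRanges::reduce(late, ignore.strand = TRUE)
  total <- sum(BiocGenerics::width(late))
  cov_by <- function(s) sum(BiocGenerics::width(GenomicRanges::intersect(
    late, GenomicRanges::reduce(s, ignore.strand = TRUE),
    ignore.strand = TRUE))) / total
  u <- GenomicRanges::reduce(c(GenomicRanges::granges(rads),
                               GenomicRanges::granges(lads)),
                             ignore.strand = TRUE)
  c(by_rads = cov_by(rads), by_lads = cov_by(lads), by_union = cov_by(u))
}

#' Enrichment distributions by RT-switch class
#'
#' Summarises per-region mean Rif1 and lamin enrichment by switch class
#' (median and quartiles), and emits the per-region scatter table of RT
#' change versus Rif1 enrichment.
#'
#' @param switch_calls `GRanges` from [classify_switches()] (mcols
#'   `switch_class`, `delta_rt`).
#' @param rif1,lamin enrichment `BinnedTrack`s.
#' @return list with `summary` (data.frame: class, factor, n, q25, median,
#'   q75) and `scatter` (data.frame: chrom, start, end, switch_class,
#'   delta_rt, rif1, lamin). Empty classes yield no summary rows.
#' @export
enrichment_by_switch_class <- function(switch_calls, rif1, lamin) {
  mc <- S4Vectors::mcols(switch_calls)
  scatter <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(switch_calls)),
    start = BiocGenerics::start(switch_calls) - 1,
    end = BiocGenerics::end(switch_calls),
    switch_class = as.character(mc$switch_class),
    delta_rt = mc$delta_rt,
    rif1 = domain_track_mean(switch_calls, rif1),
    lamin = domain_track_mean(switch_calls, lamin),
    stringsAsFactors = FALSE)
  rows <- list()
  for (fac in c("rif1", "lamin")) {
    for (cl in unique(scatter$switch_class)) {
      v <- scatter[[fac]][scatter$switch_class == cl]
      v <- v[!is.na(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, factor = fac, n = length(v),
        q25 = q[1], median = q[2], q75 = q[3])
    }
  }
  list(summary = do.call(rbind, rows), scatter = scatter)
}
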