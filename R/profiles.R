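## slot means over [a, b) on a binned vector via interpolated cumulative
## sums; equal-width slots conserve the overall mean exactly for
## bin-aligned intervals.
slot_means <- function(v, bin_size, from_bp, to_bp, n_slots) {
  n <- length(v)
  vv <- v; vv[is.na(vv)] <- 0
  wt <- as.numeric(!is.na(v))
  cs_v <- c(0, cumsum(vv)) * bin_size
  cs_w <- c(0, cumsum(wt)) * bin_size
  interp <- function(cs, x) {
    x <- pmin(pmax(x, 0), n * bin_size)
    i <- floor(x / bin_size)
    frac <- x / bin_size - i
    cs[i + 1] + frac * (cs[pmin(i + 2, n + 1)] - cs[i + 1])
  }
  edges <- seq(from_bp, to_bp, length.out = n_slots + 1)
  num <- diff(interp(cs_v, edges))
  den <- diff(interp(cs_w, edges))
  out <- num / den
  out[den <= 0] <- NA_real_
  ## out-of-chromosome slots are masked, not zero
  out[edges[-1] <= 0 | edges[-(n_slots + 1)] >= n * bin_size] <- NA_real_
  out
}

#' Scaled meta-domain signal matrix
#'
#' One row per domain: the domain body is rescaled to `n_body_bins` columns
#' (length-weighted averages of the source bins overlapping each scaled
#' slot), flanked by `n_flank_bins` fixed-width columns covering
#' `flank_bp` on each side at native orientation. Rows keep the input
#' order. Domains shorter than one source bin give fully masked rows.
#'
#' @param domains `GRanges`.
#' @param track a `BinnedTrack`.
#' @param n_body_bins scaled body columns (default 40).
#' @param flank_bp flank extent on each side in bp (default 2e5).
#' @param n_flank_bins columns per flank (default 20).
#' @return a `MetaMatrix`: list with `matrix` (rows = domains), `col_type`
#'   (`"flank5"`, `"body"`, `"flank3"`) and `col_coord` (bp offset for
#'   flanks, fractional position for body).
#' @export
meta_domain_matrix <- function(domains, track, n_body_bins = 40,
                               flank_bp = 200000, n_flank_bins = 20) {
  bs <- track$bin_size
  chrom <- as.character(GenomicRanges::seqnames(domains))
  s <- BiocGenerics::start(domains) - 1
  e <- BiocGenerics::end(domains)
  n <- length(domains)
  ncol_tot <- n_body_bins + 2 * n_flank_bins
  m <- matrix(NA_real_, n, ncol_tot)
  for (i in seq_len(n)) {
    v <- track$values[[chrom[i]]]
    if (is.null(v) || (e[i] - s[i]) < bs) next
    left <- slot_means(v, bs, s[i] - flank_bp, s[i], n_flank_bins)
    body <- slot_means(v, bs, s[i], e[i], n_body_bins)
    right <- slot_means(v, bs, e[i], e[i] + flank_bp, n_flank_bins)
    m[i, ] <- c(left, body, right)
  }
  structure(list(
    matrix = m,
    col_type = c(rep("flank5", n_flank_bins), rep("body", n_body_bins),
                 rep("flank3", n_flank_bins)),
    col_coord = c(seq(-flank_bp, 0, length.out = n_flank_bins + 1)[-(n_flank_bins + 1)] +
                    flank_bp / n_flank_bins / 2,
                  (seq_len(n_body_bins) - 0.5) / n_body_bins,
                  seq(0, flank_bp, length.out = n_flank_bins + 1)[-(n_flank_bins + 1)] +
                    flank_bp / n_flank_bins / 2)),
    class = "MetaMatrix")
}

#' Point-centred signal matrix
#'
#' One row per locus (interval midpoints), columns at fixed offsets
#' covering `±half_width_bp` around the point at the track's native bin
#' width. Rows keep the input order (so heatmap row order is comparable
#' across tracks); minus-strand loci are flipped so upstream is left.
#' Cells beyond a chromosome edge are masked.
#'
#' @param loci `GRanges` of points (midpoints taken for wider intervals).
#' @param track a `BinnedTrack`.
#' @param half_width_bp half window size (default 5000).
#' @return a `MetaMatrix` with `col_coord` in bp offsets from the point.
#' @export
point_signal_matrix <- function(loci, track, half_width_bp = 5000) {
  bs <- track$bin_size
  k <- max(1L, round(half_width_bp / bs))
  chrom <- as.character(GenomicRanges::seqnames(loci))
  midpt <- floor((BiocGenerics::start(loci) - 1 + BiocGenerics::end(loci)) / 2)
  strand <- as.character(BiocGenerics::strand(loci))
  n <- length(loci)
  m <- matrix(NA_real_, n, 2 * k + 1)
  for (i in seq_len(n)) {
    v <- track$values[[chrom[i]]]
    if (is.null(v)) next
    cbin <- floor(midpt[i] / bs) + 1
    idx <- (cbin - k):(cbin + k)
    ok <- idx >= 1 & idx <= length(v)
    row <- rep(NA_real_, 2 * k + 1)
    row[ok] <- v[idx[ok]]
    if (strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  structure(list(matrix = m,
                 col_type = rep("point", 2 * k + 1),
                 col_coord = (-k:k) * bs),
            class = "MetaMatrix")
}

#' Cluster matrix rows (k-means)
#'
#' Unsupervised k-means clustering of the rows with `nstart` restarts.
#' Masked cells are imputed with their column mean (rows with no
#' informative cell are imputed to 0 and flagged). Cluster labels are
#' relabelled in decreasing order of cluster mean signal, so label 1 is
#' always the strongest cluster and solutions are comparable across runs.
#'
#' @param mm a `MetaMatrix` or plain numeric matrix.
#' @param k number of clusters (default 4).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return a `ClusterSolution`: list with `k`, `assignment` (integer per
#'   row), `centers` (k x ncol matrix of cluster mean profiles), `sizes`,
#'   and `seed`.
#' @export
cluster_rows <- function(mm, k = 4, seed = 1, nstart = 10) {
  m <- if (inherits(mm, "MetaMatrix")) mm$matrix else mm
  if (k < 2) stop("k must be >= 2")
  if (nrow(m) < k) stop("k exceeds the number of rows")
  imp <- m
  cm <- colMeans(m, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(imp))) imp[is.na(imp[, j]), j] <- cm[j]
  set.seed(seed)
  ## degenerate all-identical rows: k-means cannot split them
  if (all(apply(imp, 2, function(col) length(unique(col)) == 1))) {
    assignment <- rep(1L, nrow(m))
    centers <- matrix(rep(imp[1, ], k), k, ncol(m), byrow = TRUE)
    centers[-1, ] <- NA_real_
    return(structure(list(k = k, assignment = assignment, centers = centers,
                          sizes = c(nrow(m), rep(0L, k - 1)), seed = seed,
                          degenerate = TRUE), class = "ClusterSolution"))
  }
  if (k == nrow(imp)) {
    ## one row per cluster: kmeans itself rejects k == n; label 1 is
    ## still the strongest row, matching the usual relabelling
    assignment <- rank(-rowMeans(imp), ties.method = "first")
    return(structure(list(k = k, assignment = as.integer(assignment),
                          centers = imp[order(assignment), , drop = FALSE],
                          sizes = rep(1L, k), seed = seed,
                          degenerate = FALSE), class = "ClusterSolution"))
  }
  km <- stats::kmeans(imp, centers = k, nstart = nstart, iter.max = 100)
  ord <- order(rowMeans(km$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assignment <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  structure(list(k = k, assignment = assignment, centers = centers,
                 sizes = as.integer(table(factor(assignment, 1:k))),
                 seed = seed, degenerate = FALSE),
            class = "ClusterSolution")
}

#' Per-cluster replication-timing summary
#'
#' Summarises RT per cluster for both genotypes, preserving cluster order,
#' for the "replication status per LAD class" style readout.
#'
#' @param solution a `ClusterSolution`.
#' @param rt_wt,rt_ko numeric vectors of per-row (per-domain) RT, aligned
#'   with the clustered rows.
#' @return data.frame: cluster, genotype, n, q25, median, q75, mean.
#' @export
cluster_rt_summary <- function(solution, rt_wt, rt_ko) {
  if (length(rt_wt) != length(solution$assignment) ||
      length(rt_ko) != length(solution$assignment))
    stop("RT vectors must align with the cluster assignment")
  rows <- list()
  for (cl in seq_len(solution$k)) {
    sel <- solution$assignment == cl
    for (g in c("wt", "ko")) {
      v <- if (g == "wt") rt_wt[sel] else rt_ko[sel]
      v <- v[!is.na(v)]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, genotype = g, n = length(v),
        q25 = q[1], median = q[2], q75 = q[3], mean = mean(v))
    }
  }
  do.call(rbind, rows)
}
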