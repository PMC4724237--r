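#' In-silico restriction digestion
#'
#' Cuts every chromosome at each occurrence of the recognition motif. The
#' cut offset is the position of the cut within the motif (1 for HindIII
#' `A^AGCTT`), so a motif starting at 0-based position `p` produces a
#' fragment boundary at `p + cut_offset`. Fragments tile each chromosome
#' without gaps or overlap; a motif-free chromosome yields one fragment.
#'
#' @param sequence named `DNAStringSet` (or named character vector).
#' @param motif recognition sequence, length >= 4 (default `AAGCTT`).
#' @param cut_offset cut position within the motif (default 1).
#' @return a `FragmentMap`: list with `fragments` (data.frame chrom,
#'   start, end in 0-based half-open coordinates, in genomic order),
#'   `motif` and `cut_offset`.
#' @export
digest_sequence <- function(sequence, motif = "AAGCTT", cut_offset = 1) {
  if (nchar(motif) < 4) stop("motif length must be >= 4")
  if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
  rows <- lapply(names(sequence), function(ch) {
    L <- Biostrings::nchar(sequence[[ch]])
    hits <- Biostrings::start(
      Biostrings::matchPattern(motif, sequence[[ch]])) - 1
    cuts <- sort(unique(pmin(pmax(hits + cut_offset, 0), L)))
    bounds <- c(0, cuts[cuts > 0 & cuts < L], L)
    data.frame(chrom = ch, start = bounds[-length(bounds)],
               end = bounds[-1], stringsAsFactors = FALSE)
  })
  structure(list(fragments = do.call(rbind, rows), motif = motif,
                 cut_offset = cut_offset), class = "FragmentMap")
}

#' @rdname digest_sequence
#' @param fragmap a `FragmentMap`.
#' @param viewpoints `GRanges` of viewpoint positions.
#' @return `viewpoint_fragments`: integer row index into
#'   `fragmap$fragments` of the fragment containing each viewpoint; errors
#'   when a viewpoint lies on no fragment.
#' @export
viewpoint_fragments <- function(fragmap, viewpoints) {
  fr <- fragmap$fragments
  chrom <- as.character(GenomicRanges::seqnames(viewpoints))
  pos <- BiocGenerics::start(viewpoints) - 1
  vapply(seq_along(viewpoints), function(i) {
    hit <- which(fr$chrom == chrom[i] & fr$start <= pos[i] &
                   fr$end > pos[i])
    if (!length(hit))
      stop("viewpoint ", i, " (", chrom[i], ":", pos[i],
           ") lies on no fragment")
    hit[1]
  }, 0L)
}

#' Reads-per-million normalisation of a 4C library
#'
#' `RPM = count * 1e6 / total`, with the total taken over fragments
#' outside the viewpoint exclusion zone (the self-ligation/undigested
#' signal around the viewpoint); fragments inside the zone are masked.
#'
#' @param counts data.frame with chrom, start, end, count (one row per
#'   fragment).
#' @param viewpoint_chrom,viewpoint_pos viewpoint location (0-based bp).
#' @param exclude_bp half-width of the exclusion zone (default 1e4).
#' @return the input data.frame with an `rpm` column (`NA` inside the
#'   exclusion zone).
#' @export
rpm_normalize <- function(counts, viewpoint_chrom, viewpoint_pos,
                          exclude_bp = 10000) {
  mid <- (counts$start + counts$end) / 2
  excluded <- counts$chrom == viewpoint_chrom &
    abs(mid - viewpoint_pos) <= exclude_bp
  total <- sum(counts$count[!excluded])
  if (total <= 0) stop("zero library after viewpoint exclusion")
  counts$rpm <- counts$count * 1e6 / total
  counts$rpm[excluded] <- NA_real_
  counts
}

## distance-decay background: power-law fit to the library's own cis
## profile (log-binned distance, mean RPM per bin)
fit_decay_background <- function(dist, rpm, n_bins = 30) {
  ok <- !is.na(rpm) & dist > 0
  if (sum(ok) < 10) return(function(d) rep(0, length(d)))
  ld <- log10(dist[ok])
  br <- seq(min(ld), max(ld) + 1e-9, length.out = n_bins + 1)
  grp <- findInterval(ld, br, rightmost.closed = TRUE)
  mu <- tapply(rpm[ok], grp, mean)
  xc <- tapply(ld, grp, mean)
  pos <- !is.na(mu) & mu > 0
  if (sum(pos) < 3) return(function(d) rep(mean(rpm[ok]), length(d)))
  fit <- stats::lm(log2(mu[pos]) ~ xc[pos])
  a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
  function(d) ifelse(d > 0, 2^(a + b * log10(pmax(d, 1))), Inf)
}

#' Call replicate-consistent 4C contacts
#'
#' Per replicate, a fragment is called when its RPM reaches `min_rpm` and
#' exceeds the distance-decay background expectation at its genomic
#' distance by `call_factor`. The background is a power law fitted to the
#' replicate's own cis profile (log-binned distance vs mean RPM); trans
#' fragments are compared against the mean trans RPM. Consistent contacts
#' are fragments called in both replicates; their reported RPM is the
#' replicate mean.
#'
#' @param rep1,rep2 data.frames from [rpm_normalize()] on one fragment
#'   grid (columns chrom, start, end, rpm).
#' @param viewpoint_chrom,viewpoint_pos viewpoint location (0-based bp).
#' @param min_rpm minimum RPM for a call (default 10).
#' @param call_factor multiple of the background expectation required
#'   (default 3).
#' @return a `ContactSet`: list with `table` (data.frame: chrom, start,
#'   end, mid, distance, rpm1, rpm2, rpm, called1, called2, consistent),
#'   `viewpoint` (list chrom/pos), `min_rpm`, `call_factor`.
#' @export
call_contacts <- function(rep1, rep2, viewpoint_chrom, viewpoint_pos,
                          min_rpm = 10, call_factor = 3) {
  if (nrow(rep1) != nrow(rep2) ||
      any(rep1$start != rep2$start) || any(rep1$chrom != rep2$chrom))
    stop("replicate fragment grids do not match")
  mid <- (rep1$start + rep1$end) / 2
  cis <- rep1$chrom == viewpoint_chrom
  dist <- ifelse(cis, abs(mid - viewpoint_pos), NA_real_)
  call_one <- function(rpm) {
    bg_fun <- fit_decay_background(dist[cis], rpm[cis])
    bg <- rep(NA_real_, length(rpm))
    bg[cis] <- bg_fun(dist[cis])
    if (any(!cis)) bg[!cis] <- mean(rpm[!cis], na.rm = TRUE)
    !is.na(rpm) & rpm >= min_rpm & rpm >= call_factor * bg
  }
  called1 <- call_one(rep1$rpm)
  called2 <- call_one(rep2$rpm)
  tab <- data.frame(chrom = rep1$chrom, start = rep1$start, end = rep1$end,
                    mid = mid, distance = dist,
                    rpm1 = rep1$rpm, rpm2 = rep2$rpm,
                    rpm = (rep1$rpm + rep2$rpm) / 2,
                    called1 = called1, called2 = called2,
                    consistent = called1 & called2,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 viewpoint = list(chrom = viewpoint_chrom,
                                  pos = viewpoint_pos),
                 min_rpm = min_rpm, call_factor = call_factor),
            class = "ContactSet")
}

#' @rdname call_contacts
#' @param contacts a `ContactSet`.
#' @export
consistent_contacts <- function(contacts) {
  tab <- contacts$table
  tab[tab$consistent, , drop = FALSE]
}

#' Compare genotype contact counts by RPM range
#'
#' Counts consistent contacts per viewpoint, genotype and RPM range
#' (default ranges `[10, 200)` and `[200, Inf)`), reports the knockout /
#' wild-type fold increase per range, and tests the per-viewpoint log2
#' fold increases against 0 with a two-sided paired (one-sample) t-test.
#'
#' @param wt_sets,ko_sets named lists of `ContactSet`s, one per viewpoint,
#'   in matching order (>= 2 viewpoints for the test).
#' @param edges RPM range edges (default `c(10, 200, Inf)`).
#' @return an `RPMBinSummary`: list with `counts` (data.frame: viewpoint,
#'   range, wt, ko, fold), `fold` (per-range ratio of summed counts),
#'   `tests` (per-range data.frame: range, n, mean_log2_fold, p, flag).
#'   Folds with a zero wild-type count are `NA` and flagged.
#' @export
rpm_bin_compare <- function(wt_sets, ko_sets, edges = c(10, 200, Inf)) {
  if (length(wt_sets) != length(ko_sets) || length(wt_sets) < 2)
    stop("need matched contact sets for >= 2 viewpoints")
  vp <- names(wt_sets)
  if (is.null(vp)) vp <- paste0("VP", seq_along(wt_sets))
  ranges <- paste0("[", edges[-length(edges)], ",",
                   edges[-1], ")")
  count_in <- function(set, lo, hi) {
    r <- consistent_contacts(set)$rpm
    sum(r >= lo & r < hi)
  }
  rows <- list()
  for (i in seq_along(vp)) for (j in seq_along(ranges)) {
    w <- count_in(wt_sets[[i]], edges[j], edges[j + 1])
    k <- count_in(ko_sets[[i]], edges[j], edges[j + 1])
    rows[[length(rows) + 1]] <- data.frame(
      viewpoint = vp[i], range = ranges[j], wt = w, ko = k,
      fold = if (w > 0) k / w else NA_real_)
  }
  counts <- do.call(rbind, rows)
  fold <- vapply(ranges, function(r) {
    s <- counts[counts$range == r, ]
    if (sum(s$wt) > 0) sum(s$ko) / sum(s$wt) else NA_real_
  }, 0)
  tests <- do.call(rbind, lapply(ranges, function(r) {
    lf <- log2(counts$fold[counts$range == r])
    lf <- lf[is.finite(lf)]
    if (length(lf) < 2 || stats::sd(lf) == 0)
      return(data.frame(range = r, n = length(lf),
                        mean_log2_fold = mean(lf), p = NA_real_,
                        flag = "degenerate"))
    tt <- stats::t.test(lf)
    data.frame(range = r, n = length(lf), mean_log2_fold = mean(lf),
               p = tt$p.value, flag = "ok")
  }))
  structure(list(counts = counts, fold = fold, tests = tests,
                 edges = edges), class = "RPMBinSummary")
}

#' Cis and intra-RT-domain contact counts
#'
#' Counts consistent contacts on the viewpoint chromosome (cis) and within
#' the viewpoint's RT domain; fragments are assigned by midpoint.
#'
#' @param contacts a `ContactSet`.
#' @param vp_domain `GRanges` of length 1, the viewpoint's RT domain
#'   (must contain the viewpoint).
#' @return named vector: `cis`, `intra`, `genome_wide`.
#' @export
classify_scope <- function(contacts, vp_domain) {
  tab <- consistent_contacts(contacts)
  ch <- as.character(GenomicRanges::seqnames(vp_domain))[1]
  s <- BiocGenerics::start(vp_domain)[1] - 1
  e <- BiocGenerics::end(vp_domain)[1]
  vp <- contacts$viewpoint
  if (!(vp$chrom == ch && vp$pos >= s && vp$pos < e))
    stop("viewpoint does not lie inside the supplied RT domain")
  cis <- tab$chrom == ch
  intra <- cis & tab$mid >= s & tab$mid < e
  c(cis = sum(cis), intra = sum(intra), genome_wide = nrow(tab))
}

#' TAD-level RT specificity of gained contacts
#'
#' Groups consistent contacts into TADs (midpoint assignment): TADs hit in
#' both genotypes are shared, TADs hit only in the knockout are gained.
#' Collects the RT value at each knockout contact position within each TAD
#' class and reports the class medians alongside the viewpoint's own RT.
#' Contacts in no TAD go to an inter-TAD bucket excluded from both
#' classes.
#'
#' @param wt,ko `ContactSet`s for the same viewpoint.
#' @param tads non-overlapping `GRanges`.
#' @param rt a `BinnedTrack` of RT values.
#' @return a `TADInteractionSummary`: list with `shared_tads`,
#'   `gained_tads` (`GRanges`), `rt_shared`, `rt_gained` (per-contact RT),
#'   `median_shared`, `median_gained`, `viewpoint_rt`, `n_inter_tad`.
#' @export
tad_rt_specificity <- function(wt, ko, tads, rt) {
  if (sum(BiocGenerics::width(GenomicRanges::reduce(
        tads, ignore.strand = TRUE))) != sum(BiocGenerics::width(tads)))
    stop("TADs must be non-overlapping")
  hit_tads <- function(set) {
    tab <- consistent_contacts(set)
    if (nrow(tab) == 0) return(list(idx = integer(0), tab = tab,
                                    assign = integer(0)))
    pt <- intervals(tab$chrom, floor(tab$mid), floor(tab$mid) + 1)
    ov <- GenomicRanges::findOverlaps(pt, tads, select = "first")
    list(idx = sort(unique(ov[!is.na(ov)])), tab = tab, assign = ov)
  }
  hw <- hit_tads(wt); hk <- hit_tads(ko)
  shared_idx <- intersect(hw$idx, hk$idx)
  gained_idx <- setdiff(hk$idx, hw$idx)
  rt_at <- function(tab, sel) {
    if (!length(sel)) return(numeric(0))
    domain_track_mean(intervals(tab$chrom[sel], floor(tab$mid[sel]),
                                floor(tab$mid[sel]) + 1), rt)
  }
  in_class <- function(h, idx) which(!is.na(h$assign) & h$assign %in% idx)
  rt_shared <- rt_at(hk$tab, in_class(hk, shared_idx))
  rt_gained <- rt_at(hk$tab, in_class(hk, gained_idx))
  vp_rt <- domain_track_mean(
    intervals(ko$viewpoint$chrom, ko$viewpoint$pos,
              ko$viewpoint$pos + 1), rt)
  structure(list(
    shared_tads = tads[shared_idx], gained_tads = tads[gained_idx],
    rt_shared = rt_shared, rt_gained = rt_gained,
    median_shared = stats::median(rt_shared, na.rm = TRUE),
    median_gained = stats::median(rt_gained, na.rm = TRUE),
    viewpoint_rt = vp_rt,
    n_inter_tad = sum(is.na(hk$assign))), class = "TADInteractionSummary")
}
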