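#' GC fraction of a sequence window
#'
#' `(#G + #C) / #unambiguous bases`; `N` bases count in neither numerator
#' nor denominator. All-ambiguous windows return `NA`.
#'
#' @param seq a character string, `DNAString`, or vector of strings.
#' @return numeric vector of GC fractions.
#' @examples
#' gc_content(c("ATGC", "ANGC"))  # 0.5, 2/3
#' @export
gc_content <- function(seq) {
  seq <- as.character(seq)
  if (any(nchar(seq) == 0)) stop("empty window")
  vapply(seq, function(s) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                     c("G", "C", "A", "T"))
    tot <- sum(f)
    if (tot == 0) NA_real_ else (f[["G"]] + f[["C"]]) / tot
  }, 0, USE.NAMES = FALSE)
}

#' CpG observed/expected ratio
#'
#' Observed CpG = overlapping `CG` dinucleotide count divided by `L - 1`;
#' expected = `(GC/2)^2` with GC the base fraction; the ratio is
#' observed/expected. `NA` (undefined) when the window has no G or C.
#'
#' @param seq character string(s) or `DNAString`, length >= 2.
#' @return numeric vector of ratios.
#' @examples
#' cpg_ratio("CGCGCGCG")  # (4/7) / 0.25 = 16/7
#' @export
cpg_ratio <- function(seq) {
  seq <- as.character(seq)
  if (any(nchar(seq) < 2)) stop("window length must be >= 2")
  vapply(seq, function(s) {
    L <- nchar(s)
    obs <- Biostrings::countPattern("CG", Biostrings::DNAString(s)) / (L - 1)
    gc <- gc_content(s)
    if (is.na(gc) || gc == 0) return(NA_real_)
    obs / (gc / 2)^2
  }, 0, USE.NAMES = FALSE)
}

## canonical G4 pattern: four G-tracts (>= 3 G) with 1-7 nt loops
g4_regex <- function(min_tract = 3, loop = c(1, 7), base = "G")
  sprintf("%s{%d,}([ACGTN]{%d,%d}%s{%d,}){3}", base, min_tract,
          loop[1], loop[2], base, min_tract)

#' Scan for G-quadruplex-forming motifs
#'
#' Matches the canonical four-G-tract pattern
#' `G{3,}(N{1,7}G{3,}){3}` on the plus strand and its complementary
#' C-pattern for minus-strand quadruplexes. Matches are leftmost and
#' greedy (leftmost-longest for this pattern), hence deterministic.
#'
#' @param seq character string or `DNAString`.
#' @param min_tract minimum G-run length (default 3).
#' @param loop loop length bounds (default c(1, 7)).
#' @return data.frame: start, end (0-based half-open), strand, width,
#'   motif (`"G4"`).
#' @export
scan_g4 <- function(seq, min_tract = 3, loop = c(1, 7)) {
  seq <- as.character(seq)
  hits <- function(pat, strand) {
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               strand = strand,
               width = attr(m, "match.length"), motif = "G4")
  }
  out <- rbind(hits(g4_regex(min_tract, loop, "G"), "+"),
               hits(g4_regex(min_tract, loop, "C"), "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), width = integer(0),
                      motif = character(0)))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan for G-rich origin elements (OGRE-like)
#'
#' Maximal regions covered by windows of at least `min_len` bp whose G
#' density (C density for the minus strand) reaches `min_g_frac`. All
#' qualifying windows of width `min_len` are merged into maximal
#' intervals (runs separated by less than `min_len` join, since one
#' G-rich region can dip below the cutoff at integer-count phase
#' boundaries); deterministic.
#'
#' @param seq character string or `DNAString`.
#' @param min_g_frac minimum G fraction in a window (default 0.67).
#' @param min_len window length in bp (default 30).
#' @return data.frame: start, end (0-based half-open), strand, width,
#'   motif (`"OGRE"`).
#' @export
scan_ogre <- function(seq, min_g_frac = 0.67, min_len = 30) {
  if (min_g_frac <= 0 || min_g_frac > 1 || min_len < 1)
    stop("invalid OGRE parameters")
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  scan_one <- function(base, strand) {
    isb <- as.integer(s == base)
    n <- length(isb)
    if (n < min_len) return(NULL)
    cs <- c(0, cumsum(isb))
    win <- (cs[(min_len + 1):(n + 1)] - cs[1:(n - min_len + 1)]) / min_len
    ok <- win >= min_g_frac
    if (!any(ok)) return(NULL)
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    a <- starts[keep] - 1L            # 0-based interval start
    b <- ends[keep] + min_len - 1L    # 0-based half-open end
    ## one G-rich region can briefly dip below the density cutoff at
    ## integer-count phase boundaries; joins gaps below min_len
    if (length(a) > 1) {
      grp <- cumsum(c(1, a[-1] - b[-length(b)] >= min_len))
      a <- tapply(a, grp, min); b <- tapply(b, grp, max)
    }
    data.frame(start = as.integer(a), end = as.integer(b),
               strand = strand, width = as.integer(b - a), motif = "OGRE")
  }
  out <- rbind(scan_one("G", "+"), scan_one("C", "-"))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), width = integer(0),
                      motif = character(0)))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Window features around loci
#'
#' GC fraction, CpG ratio and motif hit counts in fixed windows centred on
#' each locus.
#'
#' @param loci `GRanges` of points.
#' @param sequence named `DNAStringSet`.
#' @param half_width_bp half window size (default 500).
#' @return data.frame: chrom, pos, gc, cpg_ratio, n_g4, n_ogre.
#' @export
window_features <- function(loci, sequence, half_width_bp = 500) {
  chrom <- as.character(GenomicRanges::seqnames(loci))
  mid <- floor((BiocGenerics::start(loci) - 1 + BiocGenerics::end(loci)) / 2)
  out <- lapply(seq_along(loci), function(i) {
    L <- Biostrings::nchar(sequence[[chrom[i]]])
    a <- max(1, mid[i] - half_width_bp + 1)
    b <- min(L, mid[i] + half_width_bp)
    w <- as.character(Biostrings::subseq(sequence[[chrom[i]]], a, b))
    data.frame(chrom = chrom[i], pos = mid[i], gc = gc_content(w),
               cpg_ratio = cpg_ratio(w), n_g4 = nrow(scan_g4(w)),
               n_ogre = nrow(scan_ogre(w)))
  })
  do.call(rbind, out)
}

#' Stratify origin loci by RT class and TSS association
#'
#' Each SNS is labelled early (`rt > 0.5`), late (`rt < -0.5`) or
#' intermediate from the RT value of the 200-kb bin containing its centre
#' (the track is rebinned when finer), and by overlap with any TSS within
#' `overlap_bp`. Also reports the fraction of SNSs overlapped by a
#' supplied sharp-peak interval set (the peak-association rate).
#'
#' @param sns,tss `GRanges` of loci.
#' @param rt a `BinnedTrack` of RT values (bin size <= 200 kb dividing it).
#' @param overlap_bp half-window for TSS association (default 500, i.e. a
#'   1-kb window centred on the SNS).
#' @param peaks optional `GRanges` of sharp peaks.
#' @param grid_bp RT classification grid (default 2e5).
#' @param early_thr,late_thr RT class thresholds.
#' @return list with `table` (data.frame: chrom, pos, rt, rt_class,
#'   at_tss, stratum) and `peak_association` (fraction of SNSs overlapping
#'   a peak, `NA` when no peaks given). Strata are
#'   `early_TSS+`, `early_TSS-`, `late_TSS+`, `late_TSS-`, or
#'   `intermediate` (excluded band); loci off the RT grid are `NA`-masked.
#' @export
stratify_loci <- function(sns, tss, rt, overlap_bp = 500, peaks = NULL,
                          grid_bp = 200000, early_thr = 0.5,
                          late_thr = -0.5) {
  if (rt$bin_size != grid_bp) {
    if (grid_bp %% rt$bin_size != 0)
      stop("RT bin size must divide the ", grid_bp, "-bp grid")
    rt <- track_rebin(rt, grid_bp)
  }
  chrom <- as.character(GenomicRanges::seqnames(sns))
  mid <- floor((BiocGenerics::start(sns) - 1 + BiocGenerics::end(sns)) / 2)
  rt_at <- vapply(seq_along(sns), function(i) {
    v <- rt$values[[chrom[i]]]
    b <- floor(mid[i] / grid_bp) + 1
    if (is.null(v) || b > length(v)) NA_real_ else v[b]
  }, 0)
  rt_class <- ifelse(is.na(rt_at), NA_character_,
                ifelse(rt_at > early_thr, "early",
                  ifelse(rt_at < late_thr, "late", "intermediate")))
  win <- intervals(chrom, pmax(0, mid - overlap_bp), mid + overlap_bp)
  at_tss <- GenomicRanges::countOverlaps(win, tss, ignore.strand = TRUE) > 0
  stratum <- ifelse(is.na(rt_class), NA_character_,
               ifelse(rt_class == "intermediate", "intermediate",
                 paste0(rt_class, ifelse(at_tss, "_TSS+", "_TSS-"))))
  peak_assoc <- NA_real_
  if (!is.null(peaks)) {
    pt <- intervals(chrom, mid, mid + 1)
    peak_assoc <- mean(GenomicRanges::countOverlaps(
      pt, peaks, ignore.strand = TRUE) > 0)
  }
  list(table = data.frame(chrom = chrom, pos = mid, rt = rt_at,
                          rt_class = rt_class, at_tss = at_tss,
                          stratum = stratum, stringsAsFactors = FALSE),
       peak_association = peak_assoc)
}
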