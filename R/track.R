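#' Binned genomic track
#'
#' A `BinnedTrack` holds one fixed-width value per genomic bin, for one or
#' more chromosomes. Values are real numbers (counts, RT score, log2
#' enrichment); `NA` marks masked bins (no informative data). Bins are
#' start-aligned: bin `i` of chromosome `c` covers
#' `[(i-1)*bin_size, i*bin_size)` in 0-based half-open coordinates.
#'
#' @param values named list of numeric vectors, one per chromosome, or a
#'   single numeric vector (treated as one chromosome named `"chr1"`).
#' @param bin_size bin width in bp (positive integer).
#' @return an object of class `BinnedTrack`.
#' @examples
#' tr <- binned_track(list(chr1 = c(0, 1, 2, NA)), bin_size = 1000)
#' track_chroms(tr)
#' @export
binned_track <- function(values, bin_size) {
  if (is.numeric(values)) values <- list(chr1 = values)
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    stop("'values' must be a named list of numeric vectors")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("'bin_size' must be a single positive number")
  values <- lapply(values, as.numeric)
  structure(list(values = values, bin_size = as.integer(bin_size)),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: %d chromosome(s), bin size %d bp\n",
              length(x$values), x$bin_size))
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    cat(sprintf("  %s: %d bins, %d masked, mean %.3f\n", ch, length(v),
                sum(is.na(v)), mean(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' @rdname binned_track
#' @param track a `BinnedTrack`.
#' @export
track_chroms <- function(track) names(track$values)

#' @rdname binned_track
#' @export
track_values <- function(track) track$values

#' Check that two tracks share a bin grid
#'
#' Same bin size, same chromosomes, same per-chromosome bin counts.
#' @param a,b `BinnedTrack` objects.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "BinnedTrack"), inherits(b, "BinnedTrack"))
  if (a$bin_size != b$bin_size)
    stop("bin grid mismatch: bin sizes differ (", a$bin_size, " vs ",
         b$bin_size, ")")
  if (!identical(sort(names(a$values)), sort(names(b$values))))
    stop("bin grid mismatch: chromosome sets differ")
  for (ch in names(a$values))
    if (length(a$values[[ch]]) != length(b$values[[ch]]))
      stop("bin grid mismatch: bin counts differ on ", ch)
  invisible(TRUE)
}

#' Apply a function bin-wise to one or two tracks
#'
#' @param f function of one (or two) numeric vectors.
#' @param a,b `BinnedTrack`s on the same grid (`b` optional).
#' @return a `BinnedTrack` on the same grid.
#' @keywords internal
track_map <- function(f, a, b = NULL) {
  if (!is.null(b)) check_same_grid(a, b)
  vals <- lapply(names(a$values), function(ch) {
    if (is.null(b)) f(a$values[[ch]]) else f(a$values[[ch]], b$values[[ch]])
  })
  names(vals) <- names(a$values)
  binned_track(vals, a$bin_size)
}

#' Convert a track to a bedGraph-style data frame
#'
#' Masked bins are dropped, matching bedGraph semantics where absent
#' intervals mean "no data".
#' @param track a `BinnedTrack`.
#' @return data.frame with columns chrom, start, end, value.
#' @export
track_to_bedgraph <- function(track) {
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    keep <- !is.na(v)
    idx <- which(keep)
    data.frame(chrom = rep(ch, length(idx)),
               start = (idx - 1L) * track$bin_size,
               end = idx * track$bin_size,
               value = v[idx], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a track from a bedGraph-style data frame
#'
#' Intervals must be non-overlapping and aligned to a common bin grid;
#' uncovered bins become masked (`NA`).
#' @param df data.frame with chrom, start, end, value.
#' @param bin_size bin width in bp; inferred from the first row when `NULL`.
#' @param chrom_lengths optional named vector fixing per-chromosome bin
#'   counts (else the last covered bin defines the length).
#' @return a `BinnedTrack`.
#' @export
bedgraph_to_track <- function(df, bin_size = NULL, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (is.null(bin_size)) bin_size <- df$end[1] - df$start[1]
  if (any(df$start %% bin_size != 0) || any(df$end - df$start != bin_size))
    stop("bedGraph intervals are not aligned to a ", bin_size, "-bp grid")
  key <- paste(df$chrom, df$start)
  if (anyDuplicated(key)) stop("bedGraph has overlapping intervals")
  chroms <- unique(df$chrom)
  vals <- lapply(chroms, function(ch) {
    sub <- df[df$chrom == ch, ]
    n <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      ceiling(chrom_lengths[[ch]] / bin_size) else max(sub$end) / bin_size
    v <- rep(NA_real_, n)
    v[sub$start / bin_size + 1L] <- sub$value
    v
  })
  names(vals) <- chroms
  binned_track(vals, bin_size)
}

#' Resample a track onto a coarser grid by length-weighted mean
#'
#' @param track a `BinnedTrack`.
#' @param new_bin_size target bin width, a multiple of the source width.
#' @return a `BinnedTrack` at the new resolution; a coarse bin is masked
#'   when all source bins inside it are masked.
#' @export
track_rebin <- function(track, new_bin_size) {
  k <- new_bin_size / track$bin_size
  if (k != round(k) || k < 1) stop("new bin size must be a multiple of ",
                                   track$bin_size)
  k <- as.integer(k)
  vals <- lapply(track$values, function(v) {
    n_out <- ceiling(length(v) / k)
    grp <- rep(seq_len(n_out), each = k)[seq_along(v)]
    out <- tapply(v, grp, function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
    as.numeric(out)
  })
  binned_track(vals, new_bin_size)
}
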