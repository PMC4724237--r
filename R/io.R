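#' Read a BED file into a GRanges
#'
#' Accepts 3- or 6-column BED (chrom, start, end[, name, score, strand]).
#' Coordinates are 0-based half-open on disk and converted to the 1-based
#' closed convention of `GRanges` on read. Malformed lines are rejected with
#' their line number.
#'
#' @param path file path.
#' @return a `GRanges`; name and score columns, when present, become the
#'   metadata columns `name` and `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": requires 0 <= start < end, got [",
         start[bad[1]], ", ", end[bad[1]], ")")
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start + 1, end = end))
  if (all(nf >= 4L)) S4Vectors::mcols(gr)$name <-
      vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) S4Vectors::mcols(gr)$score <-
      suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(nf >= 6L)) {
    st <- vapply(fields, `[[`, "", 6L)
    st[!st %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- st
  }
  gr
}

#' Write a GRanges to a BED file
#'
#' Emits 0-based half-open coordinates. When the GRanges carries `name`,
#' `score` or strand information the 6-column form is written; scores are
#' clamped to the BED integer range 0-1000 after rounding.
#'
#' @param gr a `GRanges`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  mc <- S4Vectors::mcols(gr)
  has_extra <- any(c("name", "score") %in% names(mc)) ||
    any(as.character(BiocGenerics::strand(gr)) != "*")
  if (has_extra && n > 0) {
    name <- if ("name" %in% names(mc)) as.character(mc$name) else
      rep(".", n)
    score <- if ("score" %in% names(mc))
      pmin(pmax(round(as.numeric(mc$score)), 0), 1000) else rep(0, n)
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "."
    df <- data.frame(chrom, start, end, name, score, strand)
  } else {
    df <- data.frame(chrom, start, end)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a BinnedTrack
#'
#' The track must tile a fixed-width bin grid without overlaps.
#' @param path file path.
#' @param bin_size bin width (inferred from the first interval when NULL).
#' @return a `BinnedTrack`.
#' @export
read_bedgraph <- function(path, bin_size = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("malformed bedGraph line ", bad[1], ": fewer than 4 fields")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.numeric(vapply(fields, `[[`, "", 2L)),
    end = as.numeric(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$value)))
    stop("malformed bedGraph: non-numeric fields")
  bedgraph_to_track(df, bin_size)
}

#' Write a BinnedTrack to a bedGraph file
#'
#' @param track a `BinnedTrack`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  df <- track_to_bedgraph(track)
  utils::write.table(format(df, trim = TRUE, scientific = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping one entry point per format.
#' @param path file path.
#' @return `read_fasta`: a named `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs a named `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Build a GRanges from chrom/start/end vectors (0-based half-open input)
#'
#' @param chrom,start,end interval coordinates, 0-based half-open.
#' @param ... further metadata columns.
#' @return a `GRanges`.
#' @export
intervals <- function(chrom, start, end, ...) {
  stopifnot(all(start >= 0), all(start < end))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1, end = end))
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}
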