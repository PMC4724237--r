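# Shared fixtures and independent oracles. Simulations are memoized per
# (seed, sequence) so expensive genomes are built once per test run.

.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(seed = 1, with_sequence = FALSE, spec = NULL) {
  key <- paste0("s", seed, "_", as.integer(with_sequence),
                if (is.null(spec)) "" else "_custom")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  if (is.null(spec)) spec <- synthetic_genome_spec(seed = seed)
  sim <- simulate_genome(spec, with_sequence = with_sequence)
  sim$spec <- spec
  .sim_cache[[key]] <- sim
  sim
}

get_assays <- function(seed = 1) {
  key <- paste0("a", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- get_sim(seed)
  out <- simulate_replication_assays(sim$spec, sim$truth)
  .sim_cache[[key]] <- out
  out
}

# --- oracle: exhaustive greedy maximal-segment extraction, O(n^2) ---------
# Enumerates every segment sum from scratch, takes the best (ties:
# leftmost start, then longest), removes it, recurses on the remainder.
oracle_segments <- function(x, lo = 1L, hi = length(x)) {
  if (hi < lo) return(NULL)
  best <- NULL
  for (i in lo:hi) {
    s <- 0
    for (j in i:hi) {
      s <- s + x[j]
      if (s > 0 && (is.null(best) || s > best$score ||
                    (s == best$score &&
                     (i < best$start ||
                      (i == best$start && j > best$end)))))
        best <- list(start = i, end = j, score = s)
    }
  }
  if (is.null(best)) return(NULL)
  rbind(oracle_segments(x, lo, best$start - 1L),
        data.frame(start = best$start, end = best$end, score = best$score),
        oracle_segments(x, best$end + 1L, hi))
}

# --- oracle: per-base boolean-mask Venn overlap ---------------------------
oracle_venn <- function(a, b, space_bp = 2000) {
  chroms <- union(as.character(GenomicRanges::seqnames(a)),
                  as.character(GenomicRanges::seqnames(b)))
  ua <- 0L; ub <- 0L; sh <- 0L
  for (ch in chroms) {
    ma <- rep(FALSE, space_bp); mb <- rep(FALSE, space_bp)
    sel <- as.character(GenomicRanges::seqnames(a)) == ch
    for (i in which(sel))
      ma[BiocGenerics::start(a)[i]:BiocGenerics::end(a)[i]] <- TRUE
    sel <- as.character(GenomicRanges::seqnames(b)) == ch
    for (i in which(sel))
      mb[BiocGenerics::start(b)[i]:BiocGenerics::end(b)[i]] <- TRUE
    ua <- ua + sum(ma & !mb); ub <- ub + sum(mb & !ma); sh <- sh + sum(ma & mb)
  }
  list(unique_a = ua, unique_b = ub, shared = sh)
}

random_interval_set <- function(n, space_bp = 2000, chroms = c("c1", "c2")) {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(space_bp - 20, n)
  w <- sample.int(100, n)
  GenomicRanges::reduce(intervals(ch, s, pmin(s + w, space_bp)))
}

# --- oracle: leftmost-longest G4 matcher by exhaustive recursion ----------
oracle_g4 <- function(s, base = "G") {
  n <- nchar(s); ch <- strsplit(s, "")[[1]]
  grun <- function(j) { k <- j; while (k <= n && ch[k] == base) k <- k + 1; k - j }
  rec <- function(i, k) {
    g <- grun(i); if (g < 3) return(-1L)
    if (k == 0) return(g)
    best <- -1L
    for (t in 3:g) for (l in 1:7) {
      j <- i + t + l
      if (j > n) next
      r <- rec(j, k - 1)
      if (r > 0) best <- max(best, t + l + r)
    }
    best
  }
  out <- NULL; i <- 1
  while (i <= n - 14) {
    if (ch[i] == base) {
      L <- rec(i, 3)
      if (L > 0) { out <- rbind(out, data.frame(start = i - 1, end = i - 1 + L)); i <- i + L; next }
    }
    i <- i + 1
  }
  out
}

# --- oracle: dinucleotide tally for the CpG ratio -------------------------
oracle_cpg <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  obs <- sum(ch[-L] == "C" & ch[-1] == "G") / (L - 1)
  gc <- mean(ch %in% c("G", "C"))
  if (gc == 0) return(NA_real_)
  obs / (gc / 2)^2
}

random_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}
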