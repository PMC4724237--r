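#' Parameterization of the synthetic genome and assays
#'
#' Describes a toy genome with planted early/late replication-timing (RT)
#' domains, Rif1-associated domains (RADs) and lamina-associated domains
#' (LADs) with configurable co-occupancy, Poisson sequencing coverage,
#' sequence composition with CpG islands and planted G-rich motifs, and
#' two-genotype 4C libraries with distance decay, same-RT compartment
#' preference and planted gained contacts in the knockout. All downstream
#' operations are tested against the truth planted here.
#'
#' Knockout RT layout: late domains that are RADs without lamin
#' co-occupancy (RAD-LB-) flip to early replication; a configurable
#' fraction of early domains flips reciprocally to late. Everything else
#' keeps its wild-type RT.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size RT/enrichment bin width (bp).
#' @param domain_size_range min/max RT-domain size (bp); sizes are drawn
#'   uniformly and rounded to whole bins, classes alternate early/late.
#' @param rt_early,rt_late planted mean RT per class (log2 early/late).
#' @param depth mean reads per bin for Repli-seq and ChIP tracks.
#' @param chip_effect log2 ChIP/input enrichment inside occupied domains.
#' @param p_rad probability that a late domain is a RAD.
#' @param p_lb probability that a RAD is lamin co-occupied (RAD-LB+).
#' @param p_lad_only probability that a non-RAD late domain is a LAD alone.
#' @param p_etol fraction of early domains flipping to late in the knockout.
#' @param gc_background background GC base fraction.
#' @param cpg_depletion fraction of background CpG dinucleotides retained
#'   (vertebrate-like observed/expected ~0.2; planted islands are exempt).
#' @param n_tss,n_sns TSS and SNS (nascent-strand origin) count per
#'   chromosome.
#' @param cpg_island_frac fraction of early TSSs receiving a planted CpG
#'   island (1 kb, elevated CpG dinucleotide rate).
#' @param sns_early_frac fraction of SNSs placed in early domains.
#' @param sns_at_tss_frac fraction of SNSs placed at a TSS.
#' @param n_g4,n_ogre planted G-quadruplex / G-rich (OGRE-like) motif
#'   instances per chromosome.
#' @param fine_bin_size bin width of the fine-scale ChIP track used for
#'   point-centred profiles (bp).
#' @param peak_effect log2 focal Rif1 enrichment planted at CpG-rich TSSs
#'   on the fine track.
#' @param tad_size_range min/max TAD size (bp); TADs tile each chromosome.
#' @param n_viewpoints number of 4C viewpoints (placed inside late RADs).
#' @param restriction_motif primary cutter recognition sequence
#'   (HindIII `AAGCTT` by default).
#' @param decay_exponent power-law exponent of 4C contact distance decay.
#' @param decay_offset distance offset (bp) regularising the decay at 0.
#' @param same_rt_weight extra weight multiplier `(1 + w)` for fragments in
#'   the viewpoint's RT class (compartment preference).
#' @param trans_frac fraction of library weight on other chromosomes.
#' @param reads_per_library expected reads per 4C library.
#' @param n_true_contacts planted replicate-consistent contacts per
#'   viewpoint, shared by both genotypes, in the viewpoint's RT class.
#' @param true_contact_rpm RPM range of planted shared contacts.
#' @param true_contact_local_frac fraction of the shared contacts placed
#'   inside the viewpoint's own RT domain (structured local
#'   interactions), the rest elsewhere in the viewpoint's RT class.
#' @param gained_rate fraction of eligible inter-RT-domain cis fragments
#'   gaining a planted contact in the knockout.
#' @param gained_rpm RPM range (low-to-mid frequency) of gained contacts.
#' @param seed RNG seed; all simulator randomness flows from it.
#' @return a validated object of class `SyntheticGenomeSpec` (a list).
#' @export
synthetic_genome_spec <- function(
    chrom_lengths = c(chr1 = 20e6, chr2 = 20e6),
    bin_size = 50000,
    domain_size_range = c(8e5, 1.2e6),
    rt_early = 2, rt_late = -2,
    depth = 100,
    chip_effect = 1.5,
    p_rad = 0.65, p_lb = 0.6, p_lad_only = 0.25,
    p_etol = 0.15,
    gc_background = 0.42,
    cpg_depletion = 0.2,
    n_tss = 150, n_sns = 300,
    cpg_island_frac = 0.5,
    sns_early_frac = 0.7,
    sns_at_tss_frac = 0.3,
    n_g4 = 100, n_ogre = 50,
    fine_bin_size = 500,
    peak_effect = 3,
    tad_size_range = c(4e5, 1.2e6),
    n_viewpoints = 5,
    restriction_motif = "AAGCTT",
    decay_exponent = 2,
    decay_offset = 2000,
    same_rt_weight = 1,
    trans_frac = 0.05,
    reads_per_library = 5e5,
    n_true_contacts = 30,
    true_contact_rpm = c(20, 500),
    true_contact_local_frac = 0.5,
    gained_rate = 0.01,
    gained_rpm = c(15, 100),
    seed = 1) {
  spec <- as.list(environment())
  class(spec) <- "SyntheticGenomeSpec"
  validate_spec(spec)
  spec
}

#' @rdname synthetic_genome_spec
#' @param spec a `SyntheticGenomeSpec`.
#' @export
validate_spec <- function(spec) {
  chk_pos <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || any(v <= 0))
      stop("invalid spec field '", field, "': must be strictly positive")
  }
  for (f in c("chrom_lengths", "bin_size", "domain_size_range", "depth",
              "fine_bin_size", "tad_size_range", "n_viewpoints",
              "decay_exponent", "decay_offset", "reads_per_library"))
    chk_pos(f)
  for (f in c("p_rad", "p_lb", "p_lad_only", "p_etol", "cpg_island_frac",
              "sns_early_frac", "sns_at_tss_frac", "gc_background",
              "trans_frac", "gained_rate", "cpg_depletion",
              "true_contact_local_frac")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("invalid spec field '", f, "': must lie in [0, 1]")
  }
  if (is.null(names(spec$chrom_lengths)))
    stop("invalid spec field 'chrom_lengths': must be named")
  if (spec$rt_early <= spec$rt_late)
    stop("invalid spec field 'rt_early': must exceed rt_late")
  if (nchar(spec$restriction_motif) < 4)
    stop("invalid spec field 'restriction_motif': length must be >= 4")
  if (max(spec$domain_size_range) >= min(spec$chrom_lengths))
    stop("invalid spec field 'domain_size_range': exceeds chromosome length")
  invisible(TRUE)
}

## per-chromosome alternating early/late layout; sizes rounded to whole bins
plant_rt_domains <- function(spec) {
  out <- list()
  for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]
    sizes <- integer(0)
    total <- 0
    while (total < len) {
      s <- stats::runif(1, spec$domain_size_range[1], spec$domain_size_range[2])
      s <- max(spec$bin_size, round(s / spec$bin_size) * spec$bin_size)
      sizes <- c(sizes, s)
      total <- total + s
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (total - len)
    if (sizes[length(sizes)] < spec$bin_size)
      sizes <- sizes[-length(sizes)]
    end <- cumsum(sizes)
    start <- c(0, end[-length(end)])
    end[length(end)] <- len
    cls <- rep(c("early", "late"), length.out = length(sizes))
    out[[ch]] <- data.frame(chrom = ch, start = start, end = end,
                            class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

plant_tads <- function(spec) {
  out <- list()
  for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]
    sizes <- numeric(0); total <- 0
    while (total < len) {
      s <- round(stats::runif(1, spec$tad_size_range[1],
                              spec$tad_size_range[2]))
      sizes <- c(sizes, s); total <- total + s
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (total - len)
    end <- cumsum(sizes); start <- c(0, end[-length(end)])
    out[[ch]] <- data.frame(chrom = ch, start = start, end = end)
  }
  df <- do.call(rbind, out)
  intervals(df$chrom, df$start, df$end)
}

## random DNA as a raw vector (fast path for multi-Mb chromosomes)
random_dna_raw <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ## inverse-CDF sampling: much faster than sample.int(prob=) at 1e7+ bases
  idx <- findInterval(stats::runif(n), cumsum(p)[-4]) + 1L
  charToRaw("ACGT")[idx]
}

## vertebrate-like background: most CpG dinucleotides mutated to CpT
## (deamination), leaving observed/expected CpG ~ `keep`
deplete_cpg <- function(raw, keep) {
  if (keep >= 1) return(raw)
  n <- length(raw)
  cg <- which(raw[-n] == charToRaw("C") & raw[-1] == charToRaw("G"))
  drop <- cg[stats::runif(length(cg)) >= keep]
  raw[drop + 1L] <- charToRaw("T")
  raw
}

## CpG-island sequence: dinucleotide sampler with boosted CG rate
cpg_island_seq <- function(len, cg_rate = 0.15, gc = 0.6) {
  ndi <- ceiling(len / 2)
  is_cg <- stats::runif(ndi) < cg_rate
  di <- character(ndi)
  di[is_cg] <- "CG"
  n_other <- sum(!is_cg)
  if (n_other > 0) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    b <- c("A", "C", "G", "T")
    di[!is_cg] <- paste0(b[sample.int(4L, n_other, TRUE, prob = p)],
                         b[sample.int(4L, n_other, TRUE, prob = p)])
  }
  substr(paste(di, collapse = ""), 1, len)
}

## place n points on [lo, hi] at least min_gap apart (best effort)
spaced_positions <- function(n, lo, hi, min_gap) {
  cand <- sort(round(stats::runif(n * 4, lo, hi)))
  keep <- c(TRUE, diff(cand) >= min_gap)
  cand <- cand[keep]
  if (length(cand) > n) cand <- sort(sample(cand, n))
  cand
}

#' Simulate the toy genome sequence and planted truth
#'
#' Generates per-chromosome DNA with background GC, plants CpG islands at a
#' subset of early TSSs, G4 motifs (`GGGATGGGATGGGATGGG`) and OGRE-like
#' G-rich elements (`GGAG` repeats, 75% G, no G3 runs) at recorded
#' coordinates, and records the full planted truth: RT domain layout for
#' both genotypes, RAD/LAD intervals with their lamin partition, per-domain
#' switch classes, TADs, TSS/SNS/viewpoint loci.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param with_sequence when `FALSE`, skip DNA generation (the slow step)
#'   and return `sequence = NULL`; the planted truth is byte-identical
#'   either way because sequence bases are drawn after all layout draws.
#' @return list with `sequence` (named `DNAStringSet`) and `truth`
#'   (class `PlantedTruth`; see Details).
#' @details `truth` fields: `domains` (GRanges, mcols `class`,
#'   `switch_class`, `is_rad`, `is_lad`, `rt_wt`, `rt_ko`), `rads`, `lads`,
#'   `rads_lb_pos`, `rads_lb_neg`, `tads` (GRanges), `rt_wt`, `rt_ko`
#'   (`BinnedTrack` of planted per-bin RT), `tss`, `sns`, `viewpoints`
#'   (GRanges), `cpg_rich_tss` (logical per TSS), `g4`, `ogre` (GRanges of
#'   planted motifs), and the generating `spec`.
#' @export
simulate_genome <- function(spec, with_sequence = TRUE) {
  validate_spec(spec)
  set.seed(spec$seed)
  dom <- plant_rt_domains(spec)

  ## occupancy draws, one per domain
  is_late <- dom$class == "late"
  dom$is_rad <- is_late & stats::runif(nrow(dom)) < spec$p_rad
  dom$is_lad <- FALSE
  dom$is_lad[dom$is_rad] <- stats::runif(sum(dom$is_rad)) < spec$p_lb
  lad_only <- is_late & !dom$is_rad & stats::runif(nrow(dom)) < spec$p_lad_only
  dom$is_lad <- dom$is_lad | lad_only

  ## knockout layout: RAD-LB- lates flip to early; p_etol of earlies flip
  dom$rt_wt <- ifelse(is_late, spec$rt_late, spec$rt_early)
  flip_ltoe <- dom$is_rad & !dom$is_lad
  flip_etol <- !is_late & stats::runif(nrow(dom)) < spec$p_etol
  dom$rt_ko <- dom$rt_wt
  dom$rt_ko[flip_ltoe] <- spec$rt_early
  dom$rt_ko[flip_etol] <- spec$rt_late
  dom$switch_class <- ifelse(flip_ltoe, "LtoE",
                        ifelse(flip_etol, "EtoL",
                          ifelse(is_late, "LtoL", "EtoE")))

  ## per-bin planted RT tracks
  rt_vals_wt <- list(); rt_vals_ko <- list()
  for (ch in names(spec$chrom_lengths)) {
    nb <- floor(spec$chrom_lengths[[ch]] / spec$bin_size)
    v_wt <- rep(NA_real_, nb); v_ko <- rep(NA_real_, nb)
    sub <- dom[dom$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      b0 <- sub$start[i] / spec$bin_size + 1
      b1 <- min(nb, ceiling(sub$end[i] / spec$bin_size))
      v_wt[b0:b1] <- sub$rt_wt[i]; v_ko[b0:b1] <- sub$rt_ko[i]
    }
    rt_vals_wt[[ch]] <- v_wt; rt_vals_ko[[ch]] <- v_ko
  }

  tads <- plant_tads(spec)

  ## loci: TSSs (strand-random), SNSs stratified by RT class, viewpoints
  tss_l <- list(); sns_l <- list(); g4_l <- list(); ogre_l <- list()
  g4_seq <- "GGGATGGGATGGGATGGG"
  ogre_seq <- strrep("GGAG", 9)
  for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]
    sub <- dom[dom$chrom == ch, ]
    early_dom <- sub[sub$class == "early", ]
    late_dom <- sub[sub$class == "late", ]
    pick_in <- function(doms, n) {
      i <- sample.int(nrow(doms), n, replace = TRUE)
      round(stats::runif(n, doms$start[i] + 2000, doms$end[i] - 2000))
    }
    n_e <- round(spec$n_tss * 0.7)
    tss_pos <- sort(c(pick_in(early_dom, n_e),
                      pick_in(late_dom, spec$n_tss - n_e)))
    tss_l[[ch]] <- data.frame(chrom = ch, pos = tss_pos,
                              strand = sample(c("+", "-"), length(tss_pos),
                                              TRUE))
    n_se <- round(spec$n_sns * spec$sns_early_frac)
    sns_pos <- c(pick_in(early_dom, n_se),
                 pick_in(late_dom, spec$n_sns - n_se))
    n_at <- round(spec$n_sns * spec$sns_at_tss_frac)
    at_tss <- sample(tss_pos, min(n_at, length(tss_pos)))
    sns_pos[seq_along(at_tss)] <- at_tss + round(stats::runif(length(at_tss),
                                                              -300, 300))
    sns_l[[ch]] <- data.frame(chrom = ch, pos = sort(sns_pos))
    g4_pos <- spaced_positions(spec$n_g4, 5000, len - 5000, 3000)
    g4_l[[ch]] <- data.frame(chrom = rep(ch, length(g4_pos)),
                             start = g4_pos,
                             width = rep(nchar(g4_seq), length(g4_pos)))
    ogre_pos <- spaced_positions(spec$n_ogre, 5000, len - 5000, 3000) + 1200
    ogre_l[[ch]] <- data.frame(chrom = rep(ch, length(ogre_pos)),
                               start = ogre_pos,
                               width = rep(nchar(ogre_seq), length(ogre_pos)))
  }
  tss_df <- do.call(rbind, tss_l)
  sns_df <- do.call(rbind, sns_l)
  g4_df <- do.call(rbind, g4_l)
  ogre_df <- do.call(rbind, ogre_l)

  ## CpG-rich subset: fraction of early TSSs
  tss_gr <- intervals(tss_df$chrom, tss_df$pos, tss_df$pos + 1)
  BiocGenerics::strand(tss_gr) <- tss_df$strand
  tss_rt <- domain_value_at(dom, tss_df$chrom, tss_df$pos, "rt_wt")
  early_tss <- which(tss_rt > 0)
  cpg_rich <- rep(FALSE, nrow(tss_df))
  cpg_rich[sample(early_tss, round(length(early_tss) *
                                     spec$cpg_island_frac))] <- TRUE

  ## sequence assembly with planted features overlaid (after all layout
  ## draws, so skipping it cannot change the truth)
  seqs <- character(length(spec$chrom_lengths))
  names(seqs) <- names(spec$chrom_lengths)
  if (with_sequence) for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]
    raw <- deplete_cpg(random_dna_raw(len, spec$gc_background),
                       spec$cpg_depletion)
    overlay <- function(raw, pos0, txt) {
      ins <- charToRaw(txt)
      raw[(pos0 + 1):(pos0 + length(ins))] <- ins
      raw
    }
    idx <- which(tss_df$chrom == ch & cpg_rich)
    for (i in idx) {
      isl <- cpg_island_seq(1000)
      raw <- overlay(raw, max(0, tss_df$pos[i] - 500), isl)
    }
    sub <- g4_df[g4_df$chrom == ch, ]
    for (i in seq_len(nrow(sub))) raw <- overlay(raw, sub$start[i], g4_seq)
    sub <- ogre_df[ogre_df$chrom == ch, ]
    for (i in seq_len(nrow(sub))) raw <- overlay(raw, sub$start[i], ogre_seq)
    seqs[[ch]] <- rawToChar(raw)
  }
  sequence <- if (with_sequence) Biostrings::DNAStringSet(seqs) else NULL

  ## viewpoints: midpoints of distinct late RADs, spread across chromosomes
  rad_dom <- dom[dom$is_rad, ]
  rad_dom <- rad_dom[order(-(rad_dom$end - rad_dom$start)), ]
  take <- integer(0); used <- table(factor(character(0)))
  for (i in seq_len(nrow(rad_dom))) {
    if (length(take) >= spec$n_viewpoints) break
    take <- c(take, i)
  }
  vp <- rad_dom[take, ]
  vp_pos <- round((vp$start + vp$end) / 2)
  viewpoints <- intervals(vp$chrom, vp_pos, vp_pos + 1,
                          name = paste0("VP", seq_along(vp_pos)))

  dom_gr <- intervals(dom$chrom, dom$start, dom$end, class = dom$class,
                      switch_class = dom$switch_class, is_rad = dom$is_rad,
                      is_lad = dom$is_lad, rt_wt = dom$rt_wt,
                      rt_ko = dom$rt_ko)
  truth <- structure(list(
    spec = spec,
    domains = dom_gr,
    rads = dom_gr[dom$is_rad],
    lads = dom_gr[dom$is_lad],
    rads_lb_pos = dom_gr[dom$is_rad & dom$is_lad],
    rads_lb_neg = dom_gr[dom$is_rad & !dom$is_lad],
    tads = tads,
    rt_wt = binned_track(rt_vals_wt, spec$bin_size),
    rt_ko = binned_track(rt_vals_ko, spec$bin_size),
    tss = tss_gr,
    cpg_rich_tss = cpg_rich,
    sns = intervals(sns_df$chrom, sns_df$pos, sns_df$pos + 1),
    viewpoints = viewpoints,
    g4 = intervals(g4_df$chrom, g4_df$start, g4_df$start + g4_df$width),
    ogre = intervals(ogre_df$chrom, ogre_df$start,
                     ogre_df$start + ogre_df$width)
  ), class = "PlantedTruth")
  list(sequence = sequence, truth = truth)
}

## planted domain-level value at point positions
domain_value_at <- function(dom, chrom, pos, field) {
  out <- rep(NA_real_, length(pos))
  for (i in seq_along(pos)) {
    hit <- which(dom$chrom == chrom[i] & dom$start <= pos[i] &
                   dom$end > pos[i])
    if (length(hit)) out[i] <- dom[[field]][hit[1]]
  }
  out
}

#' Simulate Repli-seq and ChIP coverage tracks
#'
#' Early/late Repli-seq counts are Poisson with means
#' `depth * 2^(rt/2)` and `depth * 2^(-rt/2)`, so the expected log2
#' early/late ratio per bin equals the planted RT. ChIP counts are Poisson
#' with mean `depth * 2^chip_effect` inside occupied domains (RADs for
#' Rif1, LADs for lamin) and `depth` outside; the input track is flat
#' Poisson. A fine-scale Rif1 track plants focal peaks (±1 kb,
#' `peak_effect` log2) at CpG-rich TSSs.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param truth the matching `PlantedTruth`.
#' @param seed optional RNG seed (defaults to `spec$seed + 1` so assay
#'   noise is independent of layout draws).
#' @return list of `BinnedTrack`s: `early_wt`, `late_wt`, `early_ko`,
#'   `late_ko`, `chip_rif1`, `chip_lamin`, `input`, and fine-scale
#'   `chip_rif1_fine`, `input_fine`.
#' @export
simulate_replication_assays <- function(spec, truth, seed = spec$seed + 1) {
  set.seed(seed)
  draw_fraction <- function(rt_track, sign) {
    vals <- lapply(rt_track$values, function(rt) {
      mu <- spec$depth * 2^(sign * rt / 2)
      as.numeric(stats::rpois(length(rt), mu))
    })
    binned_track(vals, spec$bin_size)
  }
  chip_track <- function(occupied) {
    cov <- GenomicRanges::coverage(occupied)
    vals <- lapply(names(spec$chrom_lengths), function(ch) {
      nb <- floor(spec$chrom_lengths[[ch]] / spec$bin_size)
      occ <- rep(FALSE, nb)
      if (ch %in% names(cov)) {
        v <- as.numeric(cov[[ch]])
        length(v) <- nb * spec$bin_size
        v[is.na(v)] <- 0
        occ <- tapply(v, rep(seq_len(nb), each = spec$bin_size),
                      mean) >= 0.5
      }
      mu <- spec$depth * ifelse(occ, 2^spec$chip_effect, 1)
      as.numeric(stats::rpois(nb, mu))
    })
    names(vals) <- names(spec$chrom_lengths)
    binned_track(vals, spec$bin_size)
  }
  flat_track <- function(bin) {
    vals <- lapply(names(spec$chrom_lengths), function(ch) {
      nb <- floor(spec$chrom_lengths[[ch]] / bin)
      as.numeric(stats::rpois(nb, spec$depth * bin / spec$bin_size))
    })
    names(vals) <- names(spec$chrom_lengths)
    binned_track(vals, bin)
  }
  ## fine Rif1 track with focal peaks at CpG-rich TSSs
  fine_depth <- spec$depth * spec$fine_bin_size / spec$bin_size
  fine_vals <- lapply(names(spec$chrom_lengths), function(ch) {
    nb <- floor(spec$chrom_lengths[[ch]] / spec$fine_bin_size)
    mu <- rep(fine_depth, nb)
    sel <- as.character(GenomicRanges::seqnames(truth$tss)) == ch &
      truth$cpg_rich_tss
    pos <- BiocGenerics::start(truth$tss)[sel] - 1
    for (p in pos) {
      b0 <- max(1, floor((p - 1000) / spec$fine_bin_size) + 1)
      b1 <- min(nb, floor((p + 1000) / spec$fine_bin_size) + 1)
      mu[b0:b1] <- fine_depth * 2^spec$peak_effect
    }
    as.numeric(stats::rpois(nb, mu))
  })
  names(fine_vals) <- names(spec$chrom_lengths)

  list(
    early_wt = draw_fraction(truth$rt_wt, +1),
    late_wt = draw_fraction(truth$rt_wt, -1),
    early_ko = draw_fraction(truth$rt_ko, +1),
    late_ko = draw_fraction(truth$rt_ko, -1),
    chip_rif1 = chip_track(truth$rads),
    chip_lamin = chip_track(truth$lads),
    input = flat_track(spec$bin_size),
    chip_rif1_fine = binned_track(fine_vals, spec$fine_bin_size),
    input_fine = flat_track(spec$fine_bin_size)
  )
}

#' Simulate two-genotype 4C-seq libraries
#'
#' The simulated sequence is digested in silico at the primary restriction
#' motif; per-fragment expected reads follow a power-law distance decay
#' from the viewpoint multiplied by a same-RT compartment preference
#' (computed on the wild-type layout for both genotypes, so the planted
#' knockout difference is the gained contacts alone). Planted
#' replicate-consistent contacts (both genotypes, viewpoint's RT class) and
#' knockout-only gained contacts (uniform over inter-RT-domain cis
#' fragments, low-to-mid RPM) are added as extra Poisson mean; replicates
#' share true contact positions but draw independent noise.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param truth the matching `PlantedTruth`.
#' @param sequence the `DNAStringSet` from [simulate_genome()].
#' @param seed optional RNG seed (defaults to `spec$seed + 2`).
#' @return list with `fragments` (the `FragmentMap`), `libraries` (nested
#'   list `[[viewpoint]][[genotype]][[replicate]]` of per-fragment count
#'   data frames with chrom, start, end, count), `gained` (per-viewpoint
#'   GRanges of planted knockout-only contact fragments), and `shared`
#'   (per-viewpoint GRanges of planted contacts present in both genotypes).
#' @export
simulate_4c_libraries <- function(spec, truth, sequence,
                                  seed = spec$seed + 2) {
  set.seed(seed)
  fragmap <- digest_sequence(sequence, spec$restriction_motif)
  frags <- fragmap$fragments  # data.frame chrom,start,end
  mid <- (frags$start + frags$end) / 2

  ## RT class of each fragment midpoint under the wild-type layout
  frag_gr <- intervals(frags$chrom, floor(mid), floor(mid) + 1)
  ov <- GenomicRanges::findOverlaps(frag_gr, truth$domains, select = "first")
  frag_rt_class <- rep(NA_character_, nrow(frags))
  ok <- !is.na(ov)
  frag_rt_class[ok] <-
    S4Vectors::mcols(truth$domains)$class[ov[ok]]

  vp_chrom <- as.character(GenomicRanges::seqnames(truth$viewpoints))
  vp_pos <- BiocGenerics::start(truth$viewpoints) - 1
  libraries <- list(); gained_l <- list(); shared_l <- list()
  for (v in seq_along(vp_pos)) {
    vname <- S4Vectors::mcols(truth$viewpoints)$name[v]
    ch <- vp_chrom[v]; pos <- vp_pos[v]
    vp_dom <- truth$domains[
      GenomicRanges::findOverlaps(truth$viewpoints[v], truth$domains,
                                  select = "first")]
    vp_class <- S4Vectors::mcols(vp_dom)$class

    cis <- frags$chrom == ch
    w <- rep(0, nrow(frags))
    d <- abs(mid - pos)
    w[cis] <- (d[cis] + spec$decay_offset)^(-spec$decay_exponent)
    same <- cis & !is.na(frag_rt_class) & frag_rt_class == vp_class
    w[same] <- w[same] * (1 + spec$same_rt_weight)
    w_cis <- sum(w)
    if (any(!cis)) w[!cis] <- w_cis * spec$trans_frac /
        (1 - spec$trans_frac) / sum(!cis)
    lambda_base <- spec$reads_per_library * w / sum(w)

    ## planted shared contacts: part local (inside the viewpoint's RT
    ## domain, beyond the self-ligation zone), rest distal in the
    ## viewpoint's RT class
    in_vp_dom <- cis & mid >= (BiocGenerics::start(vp_dom) - 1) &
      mid < BiocGenerics::end(vp_dom)
    n_local <- round(spec$n_true_contacts * spec$true_contact_local_frac)
    elig_local <- which(in_vp_dom & d > 20000)
    elig_distal <- which(cis & !in_vp_dom & d > 100000 &
                           !is.na(frag_rt_class) &
                           frag_rt_class == vp_class)
    shared_idx <- c(
      sample(elig_local, min(n_local, length(elig_local))),
      sample(elig_distal, min(spec$n_true_contacts - n_local,
                              length(elig_distal))))
    shared_rpm <- stats::runif(length(shared_idx), spec$true_contact_rpm[1],
                               spec$true_contact_rpm[2])
    ## gained contacts: knockout only, uniform over inter-domain cis frags
    eligible_gain <- which(cis & !in_vp_dom &
                             !seq_len(nrow(frags)) %in% shared_idx)
    n_gain <- stats::rbinom(1, length(eligible_gain), spec$gained_rate)
    gain_idx <- sample(eligible_gain, n_gain)
    gain_rpm <- stats::runif(n_gain, spec$gained_rpm[1], spec$gained_rpm[2])

    rpm2lambda <- spec$reads_per_library / 1e6
    lam_wt <- lambda_base
    lam_wt[shared_idx] <- lam_wt[shared_idx] + shared_rpm * rpm2lambda
    lam_ko <- lam_wt
    lam_ko[gain_idx] <- lam_ko[gain_idx] + gain_rpm * rpm2lambda

    draw <- function(lam) {
      cnt <- stats::rpois(length(lam), lam)
      data.frame(chrom = frags$chrom, start = frags$start,
                 end = frags$end, count = cnt, stringsAsFactors = FALSE)
    }
    libraries[[vname]] <- list(
      wt = list(rep1 = draw(lam_wt), rep2 = draw(lam_wt)),
      ko = list(rep1 = draw(lam_ko), rep2 = draw(lam_ko)))
    gained_l[[vname]] <- intervals(frags$chrom[gain_idx],
                                   frags$start[gain_idx],
                                   frags$end[gain_idx], rpm = gain_rpm)
    shared_l[[vname]] <- intervals(frags$chrom[shared_idx],
                                   frags$start[shared_idx],
                                   frags$end[shared_idx], rpm = shared_rpm)
  }
  list(fragments = fragmap, libraries = libraries,
       gained = gained_l, shared = shared_l)
}
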