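#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one auditable place:
#' RT class thresholds (late below -0.5, early above +0.5), the switch
#' threshold (|mean RT change| > 1), the 200-kb classification grid, the
#' ±0.2-Mb meta-domain flanks, the ±5-kb point windows, the ±250-kb
#' RT-change windows, the RPM range edges 10/200, k = 4 LAD clusters and
#' 60-bp distribution tiles. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed in [default_config()].
#' @return a validated config list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$early_thr > cfg$late_thr, cfg$delta_thr > 0,
            cfg$k_clusters >= 2, cfg$tile_bp > 0,
            all(diff(cfg$rpm_edges) > 0))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipeline_config
#' @export
default_config <- function() {
  list(
    outdir = "rtarch_out",
    seed = 1,
    spec = NULL,             # SyntheticGenomeSpec; built from seed if NULL
    early_thr = 0.5,
    late_thr = -0.5,
    delta_thr = 1,
    min_domain_bp = 200000,
    grid_bp = 200000,
    loess_span_bp = 300000,
    tile_bp = 60,
    gap_penalty = 4,
    n_perm = 300,
    fdr = 0.05,
    min_lamin_frac = 0.5,
    flank_bp = 200000,
    n_body_bins = 40,
    n_flank_bins = 20,
    point_half_width_bp = 5000,
    delta_half_width_bp = 250000,
    k_clusters = 4,
    min_rpm = 10,
    call_factor = 3,
    rpm_edges = c(10, 200, Inf),
    exclude_bp = 10000,
    run_contacts = TRUE,
    run_seqfeatures = TRUE
  )
}

#' Run the full synthetic-genome pipeline
#'
#' Executes simulate -> timing -> domain calling -> meta-profiles ->
#' sequence features -> 4C contacts, writing every result as plain text
#' under `config$outdir` together with a JSON manifest recording the
#' package version, seeds and every threshold used. Reruns with the same
#' config are byte-identical.
#'
#' @param config a `PipelineConfig`.
#' @param quiet suppress progress messages.
#' @return invisibly, a result bundle (list) with the main in-memory
#'   objects: `truth`, `assays`, `rt_wt`, `rt_ko`, `domains`, `switches`,
#'   `rads_called`, `venn`, `partition`, `coverage`, `cluster`,
#'   `strata`, `rpm_summary`, `tad_summaries`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message("[rtarch] ", ...)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  spec <- config$spec
  if (is.null(spec)) spec <- synthetic_genome_spec(seed = config$seed)

  say("simulate: genome + assays (seed ", spec$seed, ")")
  sim <- simulate_genome(spec)
  truth <- sim$truth
  assays <- simulate_replication_assays(spec, truth)
  write_fasta(sim$sequence, out("genome.fa"))
  write_bed(truth$domains, out("truth_rt_domains.bed"))
  write_bed(truth$rads, out("truth_rads.bed"))
  write_bed(truth$lads, out("truth_lads.bed"))
  write_bed(truth$tads, out("truth_tads.bed"))
  write_bed(truth$tss, out("tss.bed"))
  write_bed(truth$sns, out("sns.bed"))
  write_bed(truth$viewpoints, out("viewpoints.bed"))

  say("timing: RT, smoothing, segmentation, switches")
  rt_wt <- compute_rt(assays$early_wt, assays$late_wt, pseudocount = 1)
  rt_ko <- compute_rt(assays$early_ko, assays$late_ko, pseudocount = 1)
  write_bedgraph(rt_wt, out("rt_wt.bedgraph"))
  write_bedgraph(rt_ko, out("rt_ko.bedgraph"))
  rt_sm <- loess_smooth(rt_wt, config$loess_span_bp)
  domains <- segment_rt_domains(rt_sm, config$early_thr, config$late_thr,
                                config$min_domain_bp)
  switches <- classify_switches(rt_wt, rt_ko, domains, config$delta_thr)
  sw_out <- switches
  S4Vectors::mcols(sw_out) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(switches)$switch_class,
    score = pmin(pmax(round(S4Vectors::mcols(switches)$delta_rt * 1000) +
                        500, 0), 1000))
  write_bed(sw_out, out("switch_calls.bed"))
  dist_wt <- rt_distribution(rt_wt, config$tile_bp)
  dist_ko <- rt_distribution(rt_ko, config$tile_bp)

  say("domains: broad caller + interval algebra")
  enr_rif1 <- compute_enrichment(assays$chip_rif1, assays$input, 1)
  enr_lamin <- compute_enrichment(assays$chip_lamin, assays$input, 1)
  rads_called <- call_broad_domains(enr_rif1, config$gap_penalty,
                                    config$n_perm, config$fdr,
                                    seed = config$seed)
  lads_called <- call_broad_domains(enr_lamin, config$gap_penalty,
                                    config$n_perm, config$fdr,
                                    seed = config$seed)
  write_bed(rads_called, out("rads_called.bed"))
  write_bed(lads_called, out("lads_called.bed"))
  venn <- overlap_venn(rads_called, lads_called)
  part <- partition_rads(rads_called, lads_called, config$min_lamin_frac)
  late_set <- domains[S4Vectors::mcols(domains)$class == "late"]
  coverage <- late_genome_coverage(late_set, rads_called, lads_called)
  enr_cls <- enrichment_by_switch_class(switches, enr_rif1, enr_lamin)
  utils::write.table(
    data.frame(set = c("unique_rads", "unique_lads", "shared", "jaccard"),
               value = c(venn$unique_a, venn$unique_b, venn$shared,
                         venn$jaccard)),
    out("rad_lad_venn.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(metric = names(coverage), value = coverage),
                     out("late_coverage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(enr_cls$summary, out("enrichment_by_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr_cls$scatter, out("delta_rt_scatter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("profiles: LAD meta-matrix + clustering")
  lads_for_meta <- truth$lads
  meta <- meta_domain_matrix(lads_for_meta, enr_rif1, config$n_body_bins,
                             config$flank_bp, config$n_flank_bins)
  if (length(lads_for_meta) >= 2) {
    sol <- cluster_rows(meta, k = min(config$k_clusters,
                                      length(lads_for_meta)),
                        seed = config$seed)
  } else {
    ## too few domains to cluster: everything in one class
    sol <- structure(list(k = 1L, assignment = rep(1L,
                                                   length(lads_for_meta)),
                          centers = NULL, sizes = length(lads_for_meta),
                          seed = config$seed, degenerate = TRUE),
                     class = "ClusterSolution")
  }
  rtsum <- cluster_rt_summary(sol, domain_track_mean(lads_for_meta, rt_wt),
                              domain_track_mean(lads_for_meta, rt_ko))
  utils::write.table(
    cbind(data.frame(cluster = sol$assignment), as.data.frame(meta$matrix)),
    out("lad_meta_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rtsum, out("lad_cluster_rt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  strata <- NULL
  if (config$run_seqfeatures) {
    say("seqfeatures: stratification + motif scans")
    strata <- stratify_loci(truth$sns, truth$tss, rt_wt,
                            grid_bp = config$grid_bp,
                            early_thr = config$early_thr,
                            late_thr = config$late_thr)
    utils::write.table(strata$table, out("sns_strata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    feats <- window_features(truth$tss, sim$sequence, 500)
    utils::write.table(feats, out("tss_features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  rpm_summary <- NULL; tad_summaries <- NULL
  if (config$run_contacts) {
    say("contacts: 4C simulation + genotype comparison")
    fourc <- simulate_4c_libraries(spec, truth, sim$sequence)
    vp <- truth$viewpoints
    vp_chrom <- as.character(GenomicRanges::seqnames(vp))
    vp_pos <- BiocGenerics::start(vp) - 1
    wt_sets <- list(); ko_sets <- list()
    for (v in seq_along(vp)) {
      nm <- S4Vectors::mcols(vp)$name[v]
      lib <- fourc$libraries[[nm]]
      norm <- function(cnt) rpm_normalize(cnt, vp_chrom[v], vp_pos[v],
                                          config$exclude_bp)
      wt_sets[[nm]] <- call_contacts(norm(lib$wt$rep1), norm(lib$wt$rep2),
                                     vp_chrom[v], vp_pos[v],
                                     config$min_rpm, config$call_factor)
      ko_sets[[nm]] <- call_contacts(norm(lib$ko$rep1), norm(lib$ko$rep2),
                                     vp_chrom[v], vp_pos[v],
                                     config$min_rpm, config$call_factor)
    }
    rpm_summary <- rpm_bin_compare(wt_sets, ko_sets, config$rpm_edges)
    utils::write.table(rpm_summary$counts, out("rpm_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rpm_summary$tests, out("rpm_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tad_summaries <- lapply(seq_along(vp), function(v) {
      nm <- S4Vectors::mcols(vp)$name[v]
      tad_rt_specificity(wt_sets[[nm]], ko_sets[[nm]], truth$tads, rt_wt)
    })
    names(tad_summaries) <- S4Vectors::mcols(vp)$name
    tads_df <- data.frame(
      viewpoint = names(tad_summaries),
      n_shared = vapply(tad_summaries, function(x)
        length(x$shared_tads), 0L),
      n_gained = vapply(tad_summaries, function(x)
        length(x$gained_tads), 0L),
      median_rt_shared = vapply(tad_summaries, `[[`, 0, "median_shared"),
      median_rt_gained = vapply(tad_summaries, `[[`, 0, "median_gained"))
    utils::write.table(tads_df, out("tad_rt_specificity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "rtarch",
    version = as.character(utils::packageVersion("rtarch")),
    seed = config$seed,
    spec = spec[setdiff(names(spec), character(0))],
    thresholds = config[c("early_thr", "late_thr", "delta_thr",
                          "min_domain_bp", "grid_bp", "loess_span_bp",
                          "tile_bp", "gap_penalty", "n_perm", "fdr",
                          "min_lamin_frac", "flank_bp", "min_rpm",
                          "call_factor", "exclude_bp", "k_clusters",
                          "tile_bp")],
    bimodality = list(wt = dist_wt$bimodality, ko = dist_ko$bimodality),
    stages = list(contacts = config$run_contacts,
                  seqfeatures = config$run_seqfeatures))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: outputs in ", config$outdir)
  invisible(list(truth = truth, assays = assays, rt_wt = rt_wt,
                 rt_ko = rt_ko, domains = domains, switches = switches,
                 rads_called = rads_called, lads_called = lads_called,
                 venn = venn, partition = part, coverage = coverage,
                 cluster = sol, cluster_rt = rtsum, strata = strata,
                 distribution = list(wt = dist_wt, ko = dist_ko),
                 rpm_summary = rpm_summary, tad_summaries = tad_summaries,
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Dispatches `rtarch <subcommand>`; see `rtarch help`. Intended to be
#' called from the thin launcher installed at `inst/cli/rtarch.R`:
#' `Rscript -e 'rtarch::rtarch_main()' --args ...` or
#' `Rscript $(Rscript -e 'cat(system.file("cli/rtarch.R", package="rtarch"))') run --outdir out --seed 1`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   [base::commandArgs()]).
#' @return exit status, invisibly.
#' @export
rtarch_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rtarch <command> [options]",
    "commands:",
    "  run       --outdir <dir> --seed <int>   full synthetic pipeline",
    "  simulate  --outdir <dir> --seed <int>   genome + assays only",
    "  digest    --fasta <f> --motif <m> --out <bed>",
    "  timing    --early <bg> --late <bg> --out <bg>  RT from counts",
    "  overlap   --a <bed> --b <bed>           base-pair Venn",
    sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  status <- 0L
  if (cmd == "run" || cmd == "simulate") {
    cfg <- pipeline_config(outdir = opt("outdir", "rtarch_out"),
                           seed = as.integer(opt("seed", "1")),
                           run_contacts = cmd == "run",
                           run_seqfeatures = cmd == "run")
    run_pipeline(cfg)
  } else if (cmd == "digest") {
    fm <- digest_sequence(read_fasta(opt("fasta")),
                          opt("motif", "AAGCTT"))
    write_bed(intervals(fm$fragments$chrom, fm$fragments$start,
                        fm$fragments$end), opt("out", "fragments.bed"))
  } else if (cmd == "timing") {
    early <- read_bedgraph(opt("early")); late <- read_bedgraph(opt("late"))
    write_bedgraph(compute_rt(early, late, pseudocount = 1),
                   opt("out", "rt.bedgraph"))
  } else if (cmd == "overlap") {
    v <- overlap_venn(read_bed(opt("a")), read_bed(opt("b")))
    cat(sprintf("unique_a\t%d\nunique_b\t%d\nshared\t%d\njaccard\t%.6f\n",
                v$unique_a, v$unique_b, v$shared, v$jaccard))
  } else if (cmd == "help") {
    cat(usage, "\n")
  } else {
    cat("unknown command: ", cmd, "\n", usage, "\n"); status <- 1L
  }
  invisible(status)
}
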