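#' Read and write simulation configs as YAML
#'
#' The file mirrors the nested groups of [sim_config()]; unknown groups or
#' fields are rejected on read.
#'
#' @param path YAML path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("config file lacks a seed")
  do.call(sim_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_sim_config
#' @param cfg A `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Type- and range-checks every field of a config (given as a YAML path, a
#' plain list, or a `sim_config`) and reports ALL violations rather than
#' failing on the first. Unknown groups or fields are violations.
#'
#' @param config Path to a YAML config, or a list.
#' @return A tibble with one row per problem (column `problem`); zero rows
#'   means the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  cfg <- tryCatch({
    if (is.character(config)) read_sim_config(config)
    else if (inherits(config, "sim_config")) config
    else do.call(sim_config, c(list(seed = config$seed %||% NA),
                               config[setdiff(names(config), "seed")]))
  }, error = function(e) {
    lines <- strsplit(conditionMessage(e), "\n", fixed = TRUE)[[1]]
    lines <- setdiff(lines, "invalid config:")
    problems <<- sub("^- ", "", lines)
    NULL
  })
  if (!is.null(cfg)) problems <- validate_sim_config(cfg)
  tibble(problem = problems)
}

stage_message <- function(stage) inform(paste0("[epipersist] stage: ", stage))

#' Run the full synthetic pipeline end to end
#'
#' Executes the stages in dependency order — simulate, ChIP signal and
#' changed-tile calling, differential methylation, persistence, feature
#' association, motif enrichment — writing every intermediate and final
#' table under `out_dir` and returning the in-memory results plus a run
#' manifest (JSON) with the config snapshot, seed, package version, file
#' digests and methodological notes. All randomness derives from the config
#' seed, so a rerun with the same config is byte-identical on every TSV and
#' BED output.
#'
#' @param config A [sim_config()] or a YAML config path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_sim_config(config) else config
  if (!inherits(cfg, "sim_config")) abort("config must be a sim_config or a YAML path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  notes <- c("q-values are Benjamini-Hochberg (not SLIM)",
             "coverage rule: every sample >= min coverage per tile",
             "thinning: every cluster of >= 2 significant tiles keeps one random member")

  # --- stage: simulate ------------------------------------------------
  stage_message("simulate")
  write_sim_config(cfg, path("config.yaml"))
  layout <- sim_layout(cfg)
  write_genome_layout(layout, path("layout.tsv"))
  chip <- simulate_chip(cfg)
  for (nm in names(chip$tracks))
    write_tile_track(chip$tracks[[nm]], path(paste0(nm, ".bedGraph")))
  write_tile_tsv(chip$truth, path("truth_chip.tsv"))
  rrbs <- simulate_rrbs(cfg, chip = chip)
  for (s in rrbs$samples$sample) {
    rec <- dplyr::filter(rrbs$records, .data$sample == s)
    write_bismark_cov(rec, path(paste0("meth_", s, ".cov")))
  }
  write_tile_tsv(rrbs$truth, path("truth_dmr.tsv"))
  feats <- simulate_features(cfg, rrbs)
  for (nm in names(feats$features))
    write_bed(feats$features[[nm]], path(paste0("features_", nm, ".bed")))

  # --- stage: chip ----------------------------------------------------
  stage_message("chip")
  tiling2k <- make_tiling(layout, cfg$chip$width)
  rd <- function(nm) read_tile_track(path(paste0(nm, ".bedGraph")), tiling2k)
  sig <- list()
  for (cond in c("control", "cko"))
    for (r in seq_len(cfg$chip$n_replicates))
      sig[[paste0(cond, "_", r)]] <-
        tile_signal(rd(paste0("chip_", cond, "_", r)),
                    rd(paste0("input_", cond, "_", r)))
  cmp <- purrr::map(seq_len(cfg$chip$n_replicates), function(r)
    tile_log2fc(sig[[paste0("cko_", r)]], sig[[paste0("control_", r)]]))
  ctrl_ctrl <- tile_log2fc(sig[["control_2"]], sig[["control_1"]])
  cko_cko <- tile_log2fc(sig[["cko_2"]], sig[["cko_1"]])
  calls <- call_changed_tiles(cmp[[1]], cmp[[2]], ctrl_ctrl, cko_cko)
  mean_control <- sig[["control_1"]]
  mean_control$signal <- rowMeans(
    vapply(seq_len(cfg$chip$n_replicates),
           function(r) sig[[paste0("control_", r)]]$signal,
           numeric(nrow(tiling2k))))
  mean_cmp <- cmp[[1]]
  mean_cmp$log2fc <- rowMeans(
    vapply(cmp, function(x) x$log2fc, numeric(nrow(tiling2k))))
  metagene <- top_tile_metagene(mean_control, mean_cmp,
                                top_fraction = 0.05, flank = 5)
  shift <- genomewide_shift(sig, rep(c("control", "cko"),
                                     each = cfg$chip$n_replicates))
  for (r in seq_len(cfg$chip$n_replicates))
    write_tile_tsv(cmp[[r]], path(paste0("chip_comparison_rep", r, ".tsv")))
  write_calls_bed(calls, path("chip_changed_tiles.bed"))
  write_tile_tsv(calls, path("chip_changed_tiles.tsv"))
  write_tile_tsv(metagene, path("chip_metagene.tsv"))
  write_tile_tsv(tidy(shift), path("chip_shift_summary.tsv"))

  # --- stage: dmr -----------------------------------------------------
  stage_message("dmr")
  tiling100 <- make_tiling(layout, cfg$rrbs$width)
  read_tissue <- function(tissue) {
    ss <- dplyr::filter(rrbs$samples, .data$tissue == !!tissue)
    dplyr::bind_rows(purrr::map(ss$sample, function(s)
      read_bismark_cov(path(paste0("meth_", s, ".cov")), s)))
  }
  variants <- read_bed(path("features_variant.bed"), layout)
  tissue_dmrs <- list(); universes <- list(); full_dm <- list()
  for (tissue in c("sperm", "soma")) {
    tab <- aggregate_cpgs(read_tissue(tissue), tiling100, min_coverage = 10)
    universes[[tissue]] <- unique(tab$tile_id)
    grp <- function(g) paste(tissue, g, seq_len(cfg$rrbs$n_per_group), sep = "_")
    dm <- diff_methylation(tab, case = grp("cko"), control = grp("control"))
    full_dm[[tissue]] <- dm
    # variant masking applies to every downstream use; thinning exists to
    # avoid over-weighting a region in FEATURE characterisation, so it is
    # applied to the persistent set later, not before the intersection
    sig_dm <- dplyr::filter(dm, .data$q_value < 0.05)
    sig_dm <- mask_variant_tiles(sig_dm, variants)
    tissue_dmrs[[tissue]] <- sig_dm
    write_tile_tsv(dm, path(paste0("dmr_all_", tissue, ".tsv")))
    write_tile_tsv(sig_dm, path(paste0("dmr_significant_", tissue, ".tsv")))
    write_bed(dplyr::mutate(
      dplyr::select(sig_dm, dplyr::all_of(c("chrom", "start", "end"))),
      name = sig_dm$direction), path(paste0("dmr_", tissue, ".bed")))
  }
  universe <- intersect(universes$sperm, universes$soma)
  sperm_u <- dplyr::filter(tissue_dmrs$sperm, .data$tile_id %in% universe)
  soma_u <- dplyr::filter(tissue_dmrs$soma, .data$tile_id %in% universe)

  # --- stage: persist -------------------------------------------------
  stage_message("persist")
  persist <- persistence_report(sperm_u, soma_u, universe_n = length(universe))
  shared <- intersect_dmrs(sperm_u, soma_u)
  write_tile_tsv(shared, path("shared_dmrs.tsv"))
  write_tile_tsv(glance(persist), path("persistence_report.tsv"))
  write_tile_tsv(tidy(persist), path("persistence_classes.tsv"))
  if (nrow(persist$persistent))
    write_bed(dplyr::select(persist$persistent,
                            dplyr::all_of(c("chrom", "start", "end"))),
              path("persistent_dmrs.bed"))

  # --- stage: features ------------------------------------------------
  stage_message("features")
  background <- tiling100[tiling100$tile_id %in% universe, ]
  # thin clustered persistent DMRs so one region is not weighted repeatedly
  # in the feature and motif characterisation
  query <- thin_clustered(persist$persistent, max_gap = 1000,
                          seed = cfg$seed + 5L)
  write_tile_tsv(query, path("persistent_dmrs_thinned.tsv"))
  feat_rows <- list()
  if (nrow(query) >= 3) {
    top_changed <- top_changed_regions(mean_cmp, fraction = 0.25)
    dists <- list(
      enhancer = read_bed(path("features_enhancer.bed"), layout),
      cpg_island = read_bed(path("features_cpg_island.bed"), layout),
      tss = read_bed(path("features_tss.bed"), layout),
      top_changed_h3k27me3 = top_changed)
    for (nm in names(dists))
      feat_rows[[nm]] <- tidy(distance_comparison(query, background,
                                                  dists[[nm]], label = nm))
    write_tile_tsv(dplyr::bind_rows(feat_rows), path("feature_distances.tsv"))
    reps <- read_bed(path("features_repeat_element.bed"), layout)
    genes <- read_bed(path("features_gene_body.bed"), layout)
    enr <- dplyr::bind_rows(
      overlap_fraction_test(query, background, reps, label = "repeat_element"),
      proximity_enrichment(query, background, genes, window = 1000,
                           label = "gene_body"))
    write_tile_tsv(enr, path("feature_enrichment.tsv"))
  } else {
    enr <- tibble()
    inform("too few persistent DMRs for feature association; stage skipped")
  }

  # --- stage: motifs --------------------------------------------------
  stage_message("motifs")
  seqs <- simulate_sequences(
    cfg,
    query_tiles = sort(rrbs$truth$tile_id[rrbs$truth$persists &
                                            rrbs$truth$direction == "hyper"]),
    control_tiles = sort(sample_universe(universe, cfg, rrbs)))
  write_meme(seqs$pwms, path("motifs.meme"))
  write_tile_fasta(seqs$query, path("sequences_query.fasta"))
  write_tile_fasta(seqs$control, path("sequences_control.fasta"))
  q_ids <- intersect(names(seqs$query), as.character(query$tile_id))
  qseq <- if (length(q_ids) >= 10) seqs$query[q_ids] else seqs$query
  motif <- motif_enrichment(qseq, seqs$control, seqs$pwms,
                            score_fraction = cfg$motifs$score_fraction)
  write_tile_tsv(motif, path("motif_enrichment.tsv"))

  # --- manifest -------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    tool = "epipersist",
    version = as.character(utils::packageVersion("epipersist")),
    seed = cfg$seed,
    config = unclass(cfg),
    notes = notes,
    timestamp = format(Sys.time(), tz = "UTC"),
    digests = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(
    config = cfg, chip = chip, rrbs = rrbs, features = feats,
    signal = sig, comparisons = cmp, calls = calls, metagene = metagene,
    shift = shift, dmrs = tissue_dmrs, full_dm = full_dm,
    universe = universe, persistence = persist, feature_distances = feat_rows,
    feature_enrichment = enr, motif = motif, sequences = seqs,
    manifest = manifest))
}

# deterministic control-tile sample for sequence generation (kept separate
# from the generator seeds so pipeline and standalone use agree)
sample_universe <- function(universe, cfg, rrbs) {
  n <- min(cfg$motifs$n_control_seqs, length(universe))
  with_local_seed(cfg$seed + 6L, sample(universe, n))
}
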