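#' Build a simulation configuration
#'
#' Parameters of the synthetic-data generator, grouped by stage. The
#' defaults define the package's standard desk-scale study: a 2 x 2 Mb
#' genome (2,000 ChIP tiles of 2 kb; 40,000 methylation tiles of 100 bp), a
#' flattened histone-mark landscape (isolated high-signal tiles depleted to
#' d = 0.6 of their intensity, a 30%-of-median background gain everywhere
#' else), 300 planted DMR tiles shifted by 30 percentage points with a 14:1
#' hyper:hypo imbalance, 80% sperm-to-soma concordance, negative-binomial
#' CpG coverage with mean 30, and mild beta-binomial overdispersion (0.02).
#' Every field can be overridden through `...` using nested lists, e.g.
#' `sim_config(1, rrbs = list(delta = 0))`.
#'
#' @param seed Integer seed; mandatory, drives every draw.
#' @param ... Named overrides for the groups `layout`, `chip`, `rrbs`,
#'   `features`, `motifs`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    abort("a single integer seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    layout = list(n_chrom = 2, chrom_length = 2e6),
    chip = list(
      width = 2000, meanlog = 3, sdlog = 0.7,
      high_fraction = 0.05, high_multiplier = 8, high_min_gap = 6,
      depletion = 0.6, background_gain = 0.3,
      n_replicates = 2, depth = 1e6, input_level = 0.3),
    rrbs = list(
      width = 100, cpg_density = 0.03,
      coverage_mean = 30, coverage_size = 10,
      beta_a = 6.5, beta_b = 3.5,
      n_dmr = 300, delta = 30, hyper_fraction = 14 / 15,
      concordance = 0.8, n_per_group = 3, overdispersion = 0.02,
      dmr_in_changed_fraction = 0.5, flank_tiles = 3),
    features = list(
      n_tss = 400, n_cpg_island = 300, n_enhancer = 200, n_repeat = 500,
      n_gene_body = 300,
      tss_width = 1, cpg_island_width = 500, enhancer_width = 1000,
      repeat_width = 300, gene_body_width = 10000,
      enhancer_adjacent_fraction = 0.8, enhancer_adjacent_dist = 500,
      n_variant = 200, variant_in_dmr_fraction = 0.05),
    motifs = list(
      planted_query_fraction = 0.4, planted_control_fraction = 0.02,
      mutation_rate = 0.05, gc = 0.5, n_control_seqs = 1000,
      score_fraction = 0.8))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown config group(s): ", paste(bad, collapse = ", ")))
  for (grp in names(dots)) {
    unknown <- setdiff(names(dots[[grp]]), names(cfg[[grp]]))
    if (length(unknown))
      abort(paste0("unknown config field(s) in ", grp, ": ",
                   paste(unknown, collapse = ", ")))
    cfg[[grp]][names(dots[[grp]])] <- dots[[grp]]
  }
  problems <- validate_sim_config(cfg)
  if (length(problems))
    abort(paste0("invalid config:\n", paste("-", problems, collapse = "\n")))
  structure(cfg, class = "sim_config")
}

#' Validate a simulation configuration
#'
#' Checks every field's type and range and returns ALL violations (not just
#' the first) as a character vector; an empty vector means valid.
#'
#' @param cfg A config list (need not have been built by [sim_config()]).
#' @return Character vector of problems, empty when valid.
#' @export
validate_sim_config <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$seed), "seed: must be a single integer")
  chk(num1(cfg$layout$n_chrom) && cfg$layout$n_chrom >= 1,
      "layout$n_chrom: must be >= 1")
  chk(num1(cfg$layout$chrom_length) && cfg$layout$chrom_length >= 1e4,
      "layout$chrom_length: must be >= 1e4")
  ch <- cfg$chip
  chk(num1(ch$width) && ch$width >= 1, "chip$width: must be >= 1")
  chk(num1(ch$high_fraction) && ch$high_fraction > 0 && ch$high_fraction < 1,
      "chip$high_fraction: must lie in (0, 1)")
  chk(num1(ch$high_multiplier) && ch$high_multiplier >= 1,
      "chip$high_multiplier: must be >= 1")
  chk(num1(ch$depletion) && ch$depletion > 0 && ch$depletion <= 1,
      "chip$depletion: must lie in (0, 1]")
  chk(num1(ch$background_gain) && ch$background_gain >= 0,
      "chip$background_gain: must be >= 0")
  chk(num1(ch$n_replicates) && ch$n_replicates >= 1,
      "chip$n_replicates: must be >= 1")
  chk(num1(ch$depth) && ch$depth >= 1000, "chip$depth: must be >= 1000")
  rr <- cfg$rrbs
  chk(num1(rr$width) && rr$width >= 1, "rrbs$width: must be >= 1")
  chk(num1(rr$cpg_density) && rr$cpg_density > 0 && rr$cpg_density < 1,
      "rrbs$cpg_density: must lie in (0, 1)")
  chk(num1(rr$coverage_mean) && rr$coverage_mean > 0,
      "rrbs$coverage_mean: must be > 0")
  chk(num1(rr$delta) && abs(rr$delta) <= 100,
      "rrbs$delta: percentage points, |delta| <= 100")
  chk(num1(rr$hyper_fraction) && rr$hyper_fraction >= 0 && rr$hyper_fraction <= 1,
      "rrbs$hyper_fraction: must lie in [0, 1]")
  chk(num1(rr$concordance) && rr$concordance >= 0 && rr$concordance <= 1,
      "rrbs$concordance: must lie in [0, 1]")
  chk(num1(rr$n_per_group) && rr$n_per_group >= 1,
      "rrbs$n_per_group: must be >= 1")
  chk(num1(rr$overdispersion) && rr$overdispersion >= 0 && rr$overdispersion < 1,
      "rrbs$overdispersion: must lie in [0, 1)")
  chk(num1(rr$n_dmr) && rr$n_dmr >= 0, "rrbs$n_dmr: must be >= 0")
  fe <- cfg$features
  chk(num1(fe$enhancer_adjacent_fraction) &&
        fe$enhancer_adjacent_fraction >= 0 && fe$enhancer_adjacent_fraction <= 1,
      "features$enhancer_adjacent_fraction: must lie in [0, 1]")
  chk(num1(fe$variant_in_dmr_fraction) &&
        fe$variant_in_dmr_fraction >= 0 && fe$variant_in_dmr_fraction <= 1,
      "features$variant_in_dmr_fraction: must lie in [0, 1]")
  mo <- cfg$motifs
  for (f in c("planted_query_fraction", "planted_control_fraction",
              "mutation_rate", "gc"))
    chk(num1(mo[[f]]) && mo[[f]] >= 0 && mo[[f]] <= 1,
        paste0("motifs$", f, ": must lie in [0, 1]"))
  p
}

sim_layout <- function(cfg) {
  genome_layout(paste0("chr", seq_len(cfg$layout$n_chrom)),
                rep(cfg$layout$chrom_length, cfg$layout$n_chrom))
}

# pick n tile ids, all >= min_gap ids apart and away from chromosome edges
place_spaced <- function(tiling, n, min_gap) {
  chosen <- integer()
  for (ch in unique(tiling$chrom)) {
    ids <- tiling$tile_id[tiling$chrom == ch]
    quota <- round(n * length(ids) / nrow(tiling))
    pool <- ids[(min_gap + 1):(length(ids) - min_gap)]
    pool <- sample(pool)
    acc <- integer()
    for (cand in pool) {
      if (length(acc) >= quota) break
      if (!length(acc) || min(abs(acc - cand)) >= min_gap) acc <- c(acc, cand)
    }
    chosen <- c(chosen, acc)
  }
  sort(chosen)
}

#' Simulate replicate ChIP and input tile-count tracks
#'
#' Control intensities per 2-kb tile are log-normal with a planted set of
#' isolated high-signal tiles (intensity multiplied, spaced at least
#' `high_min_gap` tiles apart so their flanks are ordinary background).
#' Mutant intensities model the flattening: high tiles are depleted to
#' `depletion` of their control intensity while every other tile gains
#' `background_gain` times the median intensity. Counts are Poisson draws
#' scaled to the library depth, independently per replicate; input
#' libraries have flat intensity. Truth records the depleted anchors, their
#' flanking tiles, and the background-gain set.
#'
#' @param config A [sim_config()].
#' @return A list: `tiling`, `tracks` (named list of tile count tracks,
#'   `chip_<condition>_<rep>` and `input_<condition>_<rep>`), `truth`
#'   (tibble `tile_id`, `class` in depleted/flank/background).
#' @export
simulate_chip <- function(config) {
  cfg <- config; ch <- cfg$chip
  layout <- sim_layout(cfg)
  tiling <- make_tiling(layout, ch$width)
  with_local_seed(cfg$seed + 1L, {
    T_ <- nrow(tiling)
    anchors <- place_spaced(tiling, round(ch$high_fraction * T_), ch$high_min_gap)
    lam <- rlnorm(T_, ch$meanlog, ch$sdlog)
    lam[tiling$tile_id %in% anchors] <-
      lam[tiling$tile_id %in% anchors] * ch$high_multiplier
    gain <- ch$background_gain * median(lam)
    lam_mut <- ifelse(tiling$tile_id %in% anchors, lam * ch$depletion, lam + gain)
    draw <- function(intensity, label) {
      counts <- rpois(T_, intensity / sum(intensity) * ch$depth)
      tile_track(tiling, counts, lib_size = ch$depth, label = label)
    }
    # input libraries are flat; only input_level of their reads fall in
    # retained tiles (the rest are filtered upstream), so their in-tile
    # depth is below the nominal library size
    draw_input <- function(label) {
      counts <- rpois(T_, ch$input_level * ch$depth / T_)
      tile_track(tiling, counts, lib_size = ch$depth, label = label)
    }
    tracks <- list()
    for (cond in c("control", "cko")) {
      li <- if (cond == "control") lam else lam_mut
      for (r in seq_len(ch$n_replicates)) {
        tracks[[paste0("chip_", cond, "_", r)]] <- draw(li, paste0("chip_", cond, "_", r))
        tracks[[paste0("input_", cond, "_", r)]] <-
          draw_input(paste0("input_", cond, "_", r))
      }
    }
    flanks <- setdiff(unique(as.vector(outer(anchors, -cfg$rrbs$flank_tiles:cfg$rrbs$flank_tiles, "+"))),
                      anchors)
    flanks <- flanks[flanks >= 0 & flanks < T_]
    truth <- tibble(tile_id = tiling$tile_id,
                    class = dplyr::case_when(
                      tiling$tile_id %in% anchors ~ "depleted",
                      tiling$tile_id %in% flanks ~ "flank",
                      .default = "background"))
    list(tiling = tiling, tracks = tracks, truth = truth)
  })
}

# rrbs tile ids covered by a set of chip tiles (the two grids share a layout)
fine_tiles_within <- function(fine_tiling, coarse_tiling, coarse_ids) {
  sel <- coarse_tiling[coarse_tiling$tile_id %in% coarse_ids, ]
  hit <- overlaps_any(fine_tiling, sel)
  fine_tiling$tile_id[hit]
}

#' Simulate per-CpG methylation tables for two tissues
#'
#' Plants CpG sites at the configured density, draws a baseline methylation
#' level per 100-bp tile from Beta(a, b), and shifts `n_dmr` planted tiles
#' by `delta` percentage points (hyper or hypo at the configured 14:1
#' imbalance) in the mutant ("cko") samples of the germline tissue
#' ("sperm"). A Bernoulli(`concordance`) subset of planted tiles carries
#' the same shift in the mutant somatic samples ("soma"), modelling
#' persistence. When a ChIP simulation is supplied, a configurable fraction
#' of planted tiles is placed inside its changed (depleted + flank) tiles.
#' Per-CpG totals are negative binomial; methylated counts are
#' beta-binomial around the tile level.
#'
#' @param config A [sim_config()].
#' @param chip Optional result of [simulate_chip()] guiding DMR placement.
#' @return A list: `tiling` (fine grid), `records` (per-CpG tibble across
#'   all samples: chrom, pos, meth, total, sample), `samples` (tibble
#'   sample/tissue/group), `truth` (tibble tile_id, direction, persists).
#' @export
simulate_rrbs <- function(config, chip = NULL) {
  cfg <- config; rr <- cfg$rrbs
  layout <- sim_layout(cfg)
  tiling <- make_tiling(layout, rr$width)
  with_local_seed(cfg$seed + 2L, {
    cpgs <- dplyr::bind_rows(purrr::map2(layout$chrom, layout$length, function(ch, len) {
      n <- rbinom(1, len, rr$cpg_density)
      tibble(chrom = ch, pos = sort(sample.int(len, n)) - 1)
    }))
    base <- dplyr::summarise(dplyr::group_by(tiling, .data$chrom),
                             base_id = min(.data$tile_id), .groups = "drop")
    cpgs$tile_id <- base$base_id[match(cpgs$chrom, base$chrom)] +
      floor(cpgs$pos / rr$width)
    pi_tile <- rbeta(nrow(tiling), rr$beta_a, rr$beta_b)

    covered <- unique(cpgs$tile_id)
    pref_pool <- if (!is.null(chip)) {
      changed <- chip$truth$tile_id[chip$truth$class %in% c("depleted", "flank")]
      intersect(fine_tiles_within(tiling, chip$tiling, changed), covered)
    } else integer()
    n_pref <- min(length(pref_pool), round(rr$dmr_in_changed_fraction * rr$n_dmr))
    dmr_tiles <- c(
      if (n_pref > 0) sample(pref_pool, n_pref),
      sample(setdiff(covered, pref_pool), rr$n_dmr - n_pref))
    n_hyper <- round(rr$n_dmr * rr$hyper_fraction)
    direction <- sample(c(rep("hyper", n_hyper), rep("hypo", rr$n_dmr - n_hyper)))
    persists <- runif(rr$n_dmr) < rr$concordance
    truth <- tibble(tile_id = dmr_tiles, direction = direction, persists = persists)

    shift <- rr$delta / 100
    pi_shift <- pi_tile
    hy <- truth$tile_id[truth$direction == "hyper"]
    ho <- truth$tile_id[truth$direction == "hypo"]
    pi_shift[hy + 1] <- pmin(pi_tile[hy + 1] + shift, 0.99)
    pi_shift[ho + 1] <- pmax(pi_tile[ho + 1] - shift, 0.01)
    pi_soma <- pi_tile
    keep <- truth$tile_id[truth$persists]
    pi_soma[keep + 1] <- pi_shift[keep + 1]

    phi <- rr$overdispersion
    draw_sample <- function(pi_vec, name) {
      p_site <- pi_vec[cpgs$tile_id + 1]
      total <- rnbinom(nrow(cpgs), mu = rr$coverage_mean, size = rr$coverage_size)
      p_obs <- if (phi > 0) {
        a <- p_site * (1 - phi) / phi
        b <- (1 - p_site) * (1 - phi) / phi
        rbeta(nrow(cpgs), a, b)
      } else p_site
      tibble(chrom = cpgs$chrom, pos = cpgs$pos,
             meth = rbinom(nrow(cpgs), total, p_obs), total = total,
             sample = name)
    }
    samples <- tidyr::expand_grid(tissue = c("sperm", "soma"),
                                  group = c("control", "cko"),
                                  idx = seq_len(rr$n_per_group))
    samples$sample <- paste(samples$tissue, samples$group, samples$idx, sep = "_")
    records <- dplyr::bind_rows(purrr::pmap(samples, function(tissue, group, idx, sample) {
      pv <- if (group == "control") pi_tile
      else if (tissue == "sperm") pi_shift else pi_soma
      draw_sample(pv, sample)
    }))
    list(tiling = tiling, records = records,
         samples = dplyr::select(samples, -"idx"), truth = truth)
  })
}

random_features <- function(layout, n, width) {
  ch <- sample(layout$chrom, n, replace = TRUE,
               prob = layout$length / sum(layout$length))
  len <- setNames(layout$length, layout$chrom)
  start <- floor(runif(n) * (len[ch] - width))
  sort_intervals(tibble(chrom = unname(ch), start = unname(start),
                        end = unname(start) + width))
}

#' Simulate genomic feature sets and strain variants
#'
#' Places TSS, CpG islands, enhancers, repeats and gene bodies uniformly on
#' the genome, except that a configured fraction of enhancers is planted
#' within `enhancer_adjacent_dist` bp of persistent-truth methylation
#' tiles. Strain variants are 1-bp positions placed uniformly, plus one
#' variant inside a configured fraction of planted DMR tiles (to exercise
#' variant masking). Truth records which tiles received an adjacent
#' enhancer or a variant.
#'
#' @param config A [sim_config()].
#' @param rrbs Result of [simulate_rrbs()] (supplies the fine tiling and
#'   planted truth).
#' @return A list: `features` (named list of interval tibbles: tss,
#'   cpg_island, enhancer, repeat_element, gene_body, variant) and `truth`
#'   (list with `enhancer_adjacent_tiles`, `variant_tiles`).
#' @export
simulate_features <- function(config, rrbs) {
  cfg <- config; fe <- cfg$features
  layout <- sim_layout(cfg)
  tiling <- rrbs$tiling
  with_local_seed(cfg$seed + 3L, {
    feats <- list(
      tss = random_features(layout, fe$n_tss, fe$tss_width),
      cpg_island = random_features(layout, fe$n_cpg_island, fe$cpg_island_width),
      repeat_element = random_features(layout, fe$n_repeat, fe$repeat_width),
      gene_body = random_features(layout, fe$n_gene_body, fe$gene_body_width))
    persistent <- rrbs$truth$tile_id[rrbs$truth$persists &
                                       rrbs$truth$direction == "hyper"]
    n_adj <- min(length(persistent),
                 round(fe$enhancer_adjacent_fraction * fe$n_enhancer))
    adj_tiles <- if (n_adj > 0) sample(persistent, n_adj) else integer()
    adj <- if (n_adj > 0) {
      anchor <- tiling[match(adj_tiles, tiling$tile_id), ]
      offset <- floor(runif(n_adj, -fe$enhancer_adjacent_dist,
                            fe$enhancer_adjacent_dist))
      len <- setNames(layout$length, layout$chrom)
      start <- pmax(0, pmin(anchor$start + offset,
                            len[anchor$chrom] - fe$enhancer_width))
      tibble(chrom = anchor$chrom, start = unname(start),
             end = unname(start) + fe$enhancer_width)
    } else tibble(chrom = character(), start = numeric(), end = numeric())
    feats$enhancer <- sort_intervals(dplyr::bind_rows(
      adj, random_features(layout, fe$n_enhancer - n_adj, fe$enhancer_width)))
    uv <- random_features(layout, fe$n_variant, 1)
    n_var <- round(fe$variant_in_dmr_fraction * nrow(rrbs$truth))
    var_tiles <- if (n_var > 0) sample(rrbs$truth$tile_id, n_var) else integer()
    inside <- if (n_var > 0) {
      t0 <- tiling[match(var_tiles, tiling$tile_id), ]
      pos <- t0$start + floor(runif(n_var) * (t0$end - t0$start))
      tibble(chrom = t0$chrom, start = pos, end = pos + 1)
    } else NULL
    feats$variant <- sort_intervals(dplyr::bind_rows(uv, inside))
    list(features = feats,
         truth = list(enhancer_adjacent_tiles = sort(adj_tiles),
                      variant_tiles = sort(var_tiles)))
  })
}

#' Built-in synthetic PWM set
#'
#' One "planted" motif that the sequence generator embeds, plus three decoy
#' motifs that are never embedded; all are sharply-peaked 8-mers
#' (probability 0.97 on the consensus base).
#'
#' @return Named list of 4-row probability matrices.
#' @export
default_pwm_set <- function() {
  from_consensus <- function(s, p = 0.97) {
    bases <- strsplit(s, "")[[1]]
    m <- matrix((1 - p) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(BASE_CODE[bases], seq_along(bases))] <- p
    m
  }
  list(planted = from_consensus("TGACGTCA"),
       decoy_a = from_consensus("GGATTACC"),
       decoy_b = from_consensus("CACGTGAC"),
       decoy_c = from_consensus("ATTCGAAT"))
}

embed_motif <- function(seq, consensus, mutation_rate) {
  bases <- strsplit(consensus, "")[[1]]
  mut <- runif(length(bases)) < mutation_rate
  bases[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
  at <- sample.int(nchar(seq) - length(bases) + 1, 1)
  paste0(substr(seq, 1, at - 1), paste(bases, collapse = ""),
         substr(seq, at + length(bases), nchar(seq)))
}

#' Simulate tile sequences with a planted motif
#'
#' Generates i.i.d. background sequence at the configured GC content for
#' the query (persistent-truth) tiles and for a control sample of covered
#' tiles, then embeds the planted PWM's consensus (with per-base mutation
#' rate `mutation_rate`) at a random offset in the configured fraction of
#' each set. Decoy PWMs are never embedded.
#'
#' @param config A [sim_config()].
#' @param query_tiles,control_tiles Integer tile ids; sequences are named
#'   by them.
#' @param tile_width Sequence length in bp; default the fine tile width.
#' @return A list: `query`, `control` (named character vectors), `pwms`
#'   (from [default_pwm_set()]), `truth` (list of planted tile ids per set).
#' @export
simulate_sequences <- function(config, query_tiles, control_tiles,
                               tile_width = config$rrbs$width) {
  cfg <- config; mo <- cfg$motifs
  pwms <- default_pwm_set()
  consensus <- "TGACGTCA"
  with_local_seed(cfg$seed + 4L, {
    gen <- function(n) {
      pr <- c(A = (1 - mo$gc) / 2, C = mo$gc / 2, G = mo$gc / 2, T = (1 - mo$gc) / 2)
      vapply(seq_len(n), function(i)
        paste(sample(names(pr), tile_width, replace = TRUE, prob = pr),
              collapse = ""), character(1))
    }
    make_set <- function(ids, fraction) {
      seqs <- setNames(gen(length(ids)), as.character(ids))
      n_plant <- round(fraction * length(ids))
      planted <- if (n_plant > 0) sample(seq_along(ids), n_plant) else integer()
      for (i in planted)
        seqs[i] <- embed_motif(seqs[i], consensus, mo$mutation_rate)
      list(seqs = seqs, planted = sort(ids[planted]))
    }
    q <- make_set(query_tiles, mo$planted_query_fraction)
    ctl <- make_set(control_tiles, mo$planted_control_fraction)
    list(query = q$seqs, control = ctl$seqs, pwms = pwms,
         truth = list(query_planted = q$planted, control_planted = ctl$planted))
  })
}
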