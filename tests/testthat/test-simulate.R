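test_that("config validation reports every violation and rejects unknown keys", {
  expect_s3_class(sim_config(1), "sim_config")
  expect_error(sim_config(1, rrbs = list(concordance = 1.5)),
               "rrbs\\$concordance")
  err <- tryCatch(sim_config(1, rrbs = list(concordance = 1.5,
                                            overdispersion = -1)),
                  error = conditionMessage)
  expect_match(err, "concordance")
  expect_match(err, "overdispersion")
  expect_error(sim_config(1, rrbs = list(nonsense = 3)), "unknown config field")
  expect_error(sim_config(1, bogus = list(a = 1)), "unknown config group")
  expect_error(sim_config(), "seed")
})

test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(11, layout = list(n_chrom = 1, chrom_length = 1e5),
                    rrbs = list(n_dmr = 20))
  a <- simulate_chip(cfg); b <- simulate_chip(cfg)
  expect_identical(purrr::map(a$tracks, "count"), purrr::map(b$tracks, "count"))
  expect_identical(a$truth, b$truth)
  ra <- simulate_rrbs(cfg); rb <- simulate_rrbs(cfg)
  expect_identical(ra$records, rb$records)
  expect_identical(ra$truth, rb$truth)
  sa <- simulate_sequences(cfg, 1:20, 21:60)
  sb <- simulate_sequences(cfg, 1:20, 21:60)
  expect_identical(sa$query, sb$query)
  expect_identical(sa$control, sb$control)
  # generators leave the caller's RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_chip(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated truth is consistent with the generated data", {
  cfg <- sim_config(13, layout = list(n_chrom = 1, chrom_length = 2e5),
                    rrbs = list(n_dmr = 50))
  chip <- simulate_chip(cfg)
  expect_equal(sort(unique(chip$truth$class)),
               c("background", "depleted", "flank"))
  expect_equal(nrow(chip$truth), nrow(chip$tiling))
  # depleted anchors are spaced and carry the top control intensities
  anchors <- chip$truth$tile_id[chip$truth$class == "depleted"]
  expect_true(all(diff(sort(anchors)) >= cfg$chip$high_min_gap))

  rrbs <- simulate_rrbs(cfg, chip = chip)
  expect_equal(nrow(rrbs$truth), 50)
  expect_true(all(rrbs$truth$tile_id %in% rrbs$tiling$tile_id))
  expect_equal(nrow(rrbs$samples), 12)

  # a null effect leaves the planted set effectless
  cfg0 <- sim_config(13, layout = list(n_chrom = 1, chrom_length = 2e5),
                     rrbs = list(n_dmr = 50, delta = 0))
  r0 <- simulate_rrbs(cfg0)
  tab <- aggregate_cpgs(
    dplyr::filter(r0$records, startsWith(sample, "sperm")), r0$tiling, 10)
  dm <- diff_methylation(tab, paste0("sperm_cko_", 1:3),
                         paste0("sperm_control_", 1:3))
  expect_lte(mean(dm$q_value < 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / nrow(dm)))
})

test_that("feature simulation plants enhancer adjacency and variants", {
  cfg <- sim_config(17, layout = list(n_chrom = 1, chrom_length = 2e5),
                    rrbs = list(n_dmr = 30),
                    features = list(n_variant = 0,
                                    variant_in_dmr_fraction = 1 / 3))
  rrbs <- simulate_rrbs(cfg)
  fs <- simulate_features(cfg, rrbs)
  expect_setequal(names(fs$features),
                  c("tss", "cpg_island", "repeat_element", "gene_body",
                    "enhancer", "variant"))
  # with no uniform variants, masking removes exactly the planted tiles
  expect_equal(length(fs$truth$variant_tiles), 10)
  dmr_tiles <- rrbs$tiling[match(rrbs$truth$tile_id, rrbs$tiling$tile_id), ]
  kept <- suppressMessages(mask_variant_tiles(dmr_tiles, fs$features$variant))
  expect_setequal(setdiff(rrbs$truth$tile_id, kept$tile_id),
                  fs$truth$variant_tiles)
  # planted-adjacent tiles really are within the configured distance
  adj <- rrbs$tiling[match(fs$truth$enhancer_adjacent_tiles,
                           rrbs$tiling$tile_id), ]
  d <- nearest_feature_distance(adj, fs$features$enhancer)
  expect_true(all(d <= cfg$features$enhancer_adjacent_dist + 100))
})

test_that("sequence simulation embeds the planted motif only", {
  cfg <- sim_config(19)
  seqs <- simulate_sequences(cfg, 1:50, 101:300)
  expect_equal(length(seqs$query), 50)
  expect_equal(length(seqs$control), 200)
  expect_equal(length(seqs$truth$query_planted),
               round(0.4 * 50))
  # planted sequences carry the motif far more often than unplanted ones
  pw <- seqs$pwms$planted
  planted_hit <- scan_pwm(seqs$query[as.character(seqs$truth$query_planted)], pw)
  expect_gt(mean(planted_hit), 0.5)
  decoy_hits <- scan_pwm(seqs$control, seqs$pwms$decoy_a)
  expect_lt(mean(decoy_hits), 0.05)
})
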