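meth_tiling <- function(len = 1000) make_tiling(genome_layout("chr1", len), 100)

test_that("aggregate_cpgs sums member CpGs and applies the coverage rule", {
  rec <- tibble::tibble(
    chrom = "chr1",
    pos = c(105, 178, 305, 105, 178, 305),
    meth = c(5, 15, 3, 4, 10, 2),
    total = c(10, 20, 9, 10, 15, 8),
    sample = rep(c("s1", "s2"), each = 3))
  tab <- aggregate_cpgs(rec, meth_tiling(), min_coverage = 10)
  t1 <- dplyr::filter(tab, start == 100)
  expect_equal(t1$meth[t1$sample == "s1"], 20)
  expect_equal(t1$total[t1$sample == "s1"], 30)
  expect_equal(100 * 20 / 30, 66.7, tolerance = 1e-2)
  # tile [300,400): s2 has 8 < 10 reads -> dropped for all samples
  expect_false(any(tab$start == 300))
  expect_equal(attr(tab, "universe_size"), 1L)
  # conservation over retained tiles
  kept <- dplyr::filter(rec, pos < 200)
  expect_equal(sum(tab$meth), sum(kept$meth))
  expect_equal(sum(tab$total), sum(kept$total))

  bad <- dplyr::mutate(rec, pos = pos + 1e6)
  expect_error(aggregate_cpgs(bad, meth_tiling()), "outside the layout")
})

test_that("global_methylation pools counts", {
  rec <- tibble::tibble(chrom = "chr1", pos = c(10, 110), meth = c(10, 20),
                        total = c(10, 20), sample = "s1")
  tab <- aggregate_cpgs(rec, meth_tiling(), min_coverage = 10)
  expect_equal(global_methylation(tab), 100)
  rec$meth <- c(5, 10)
  tab <- aggregate_cpgs(rec, meth_tiling(), min_coverage = 10)
  expect_equal(global_methylation(tab), 50)
})

test_that("baseline methylation of the generator sits near 65%", {
  cfg <- sim_config(101, layout = list(n_chrom = 1, chrom_length = 4e5),
                    rrbs = list(n_dmr = 0))
  sim <- simulate_rrbs(cfg)
  ctl <- paste0("sperm_control_", 1:3)
  tab <- aggregate_cpgs(dplyr::filter(sim$records, sample %in% ctl),
                        sim$tiling, min_coverage = 10)
  pct <- global_methylation(tab)
  expect_gt(pct, 63)
  expect_lt(pct, 67)
})

test_that("diff_methylation matches the G-test worked example and glm oracle", {
  mk <- function(ma, ta, mb, tb) tibble::tibble(
    chrom = "chr1", pos = c(10, 10), meth = c(ma, mb), total = c(ta, tb),
    sample = c("a1", "b1"))
  tab <- aggregate_cpgs(mk(30, 100, 60, 100), meth_tiling(), 10)
  res <- diff_methylation(tab, case = "a1", control = "b1")
  expect_equal(res$statistic, 18.48, tolerance = 1e-3)
  expect_equal(res$p_value, 1.7e-5, tolerance = 0.02)
  expect_equal(res$delta, -30)
  expect_equal(res$direction, "hypo")

  same <- aggregate_cpgs(mk(40, 90, 40, 90), meth_tiling(), 10)
  res2 <- diff_methylation(same, case = "a1", control = "b1")
  expect_equal(res2$delta, 0)
  expect_equal(res2$p_value, 1)

  # independent oracle: binomial glm LRT per tile, 3 vs 3 samples
  set.seed(47)
  rec <- tibble::tibble(
    chrom = "chr1",
    pos = rep(c(10, 110, 210), each = 6),
    total = rpois(18, 40) + 10,
    sample = rep(paste0(rep(c("c", "k"), each = 3), 1:3), 3))
  rec$meth <- rbinom(18, rec$total, rep(c(0.5, 0.7, 0.3), each = 6))
  tab <- aggregate_cpgs(rec, meth_tiling(), 10)
  res3 <- diff_methylation(tab, case = paste0("k", 1:3),
                           control = paste0("c", 1:3))
  for (i in seq_len(nrow(res3))) {
    d <- dplyr::filter(tab, tile_id == res3$tile_id[i])
    d$grp <- d$sample %in% paste0("k", 1:3)
    full <- glm(cbind(meth, total - meth) ~ grp, binomial, data = d)
    null <- glm(cbind(meth, total - meth) ~ 1, binomial, data = d)
    expect_equal(res3$statistic[i], null$deviance - full$deviance,
                 tolerance = 1e-8)
    expect_equal(res3$p_value[i],
                 pchisq(null$deviance - full$deviance, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }

  # swapping the group labels negates delta and keeps p
  swapped <- diff_methylation(tab, case = paste0("c", 1:3),
                              control = paste0("k", 1:3))
  expect_equal(swapped$delta, -res3$delta)
  expect_equal(swapped$p_value, res3$p_value)
})

test_that("planted DMRs at the default effect size are recovered", {
  cfg <- sim_config(103, layout = list(n_chrom = 1, chrom_length = 2e5),
                    rrbs = list(n_dmr = 100))
  sim <- simulate_rrbs(cfg)
  sperm <- paste0("sperm_", rep(c("control", "cko"), each = 3), "_", 1:3)
  tab <- aggregate_cpgs(dplyr::filter(sim$records, sample %in% sperm),
                        sim$tiling, min_coverage = 10)
  dm <- diff_methylation(tab, case = paste0("sperm_cko_", 1:3),
                         control = paste0("sperm_control_", 1:3))
  hit <- sim$truth$tile_id %in% dm$tile_id[dm$q_value < 0.05]
  expect_gte(mean(hit), 0.8)
  # recovered directions agree with the planted ones
  found <- dplyr::inner_join(sim$truth,
                             dplyr::filter(dm, q_value < 0.05),
                             by = "tile_id")
  expect_gt(mean(found$direction.x == found$direction.y), 0.95)
})

test_that("null methylation comparisons stay at the nominal FDR", {
  cfg <- sim_config(105, layout = list(n_chrom = 1, chrom_length = 2e5),
                    rrbs = list(n_dmr = 0))
  sim <- simulate_rrbs(cfg)
  sperm_samples <- paste0("sperm_", rep(c("control", "cko"), each = 3), "_", 1:3)
  tab <- aggregate_cpgs(dplyr::filter(sim$records, sample %in% sperm_samples),
                        sim$tiling, min_coverage = 10)
  dm <- diff_methylation(tab, case = paste0("sperm_cko_", 1:3),
                         control = paste0("sperm_control_", 1:3))
  frac <- mean(dm$q_value < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(dm)))
})

test_that("variant masking removes exactly the overlapping tiles", {
  dmrs <- tibble::tibble(chrom = "chr1", start = c(100, 300), end = c(200, 400))
  v1 <- tibble::tibble(chrom = "chr1", start = 150, end = 151)
  expect_equal(suppressMessages(mask_variant_tiles(dmrs, v1))$start, 300)
  # half-open: a variant at the tile end does not overlap
  v2 <- tibble::tibble(chrom = "chr1", start = 200, end = 201)
  expect_equal(nrow(suppressMessages(mask_variant_tiles(dmrs, v2))), 2)

  set.seed(53)
  s <- sample.int(9900, 100) - 1
  tiles <- tibble::tibble(chrom = "chr1", start = s, end = s + 100)
  vp <- sample.int(10000, 20) - 1
  vars <- tibble::tibble(chrom = "chr1", start = vp, end = vp + 1)
  kept <- suppressMessages(mask_variant_tiles(tiles, vars))
  expect_equal(kept, tiles[!brute_overlap(tiles, vars), ])
})

test_that("clustered significant tiles are randomly thinned to one per region", {
  d3 <- tibble::tibble(chrom = "chr1", start = c(0, 200, 400),
                       end = c(100, 300, 500))
  expect_equal(nrow(thin_clustered(d3, max_gap = 1000, seed = 1)), 1)
  far <- tibble::tibble(chrom = "chr1", start = c(0, 5000), end = c(100, 5100))
  expect_equal(nrow(thin_clustered(far, max_gap = 1000, seed = 1)), 2)
  # determinism under a fixed seed
  set.seed(59)
  s <- sort(sample.int(50000, 200))
  big <- tibble::tibble(chrom = "chr1", start = s, end = s + 100)
  expect_identical(thin_clustered(big, seed = 7), thin_clustered(big, seed = 7))
  # at most one retained tile per original single-linkage cluster
  thin <- thin_clustered(big, max_gap = 1000, seed = 7)
  cl <- cumsum(c(TRUE, diff(big$start) >= 1000))
  expect_false(any(duplicated(cl[match(thin$start, big$start)])))
  # pairs are exempt when min_cluster_size = 3
  pair <- tibble::tibble(chrom = "chr1", start = c(0, 200), end = c(100, 300))
  expect_equal(nrow(thin_clustered(pair, min_cluster_size = 3, seed = 1)), 2)
})

test_that("methylation change by histone category separates planted shifts", {
  calls <- tibble::tibble(
    tile_id = 0:2, chrom = "chr1", start = c(0, 2000, 4000),
    end = c(2000, 4000, 6000),
    category = factor(c("gain", "loss", "unchanged"),
                      levels = c("gain", "loss", "unchanged", "excluded")))
  set.seed(61)
  deltas <- tibble::tibble(
    chrom = "chr1", start = seq(0, 5900, by = 100))
  deltas$end <- deltas$start + 100
  deltas$delta <- ifelse(deltas$start < 2000, rnorm(60, 10, 2),
                         ifelse(deltas$start < 4000, rnorm(60, 10, 2),
                                rnorm(60, 0, 2)))
  res <- methylation_by_category(deltas, calls)
  s <- res$summary
  expect_gt(s$median[s$category == "gain"],
            s$median[s$category == "unchanged"])
  expect_lt(res$tests$p_value[res$tests$comparison == "gain vs unchanged"],
            0.001)
  expect_equal(s$n[s$category == "excluded"], 0)

  flat <- dplyr::mutate(deltas, delta = 0)
  res0 <- methylation_by_category(flat, calls)
  expect_true(all(res0$summary$median[res0$summary$n > 0] == 0))
  expect_true(all(res0$tests$p_value > 0.9))
})
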