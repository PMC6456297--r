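one_chrom_tiling <- function(n_tiles, width = 2000) {
  make_tiling(genome_layout("chr1", n_tiles * width), width)
}

test_that("tile_signal implements RPM subtraction with inverse rescale", {
  tl <- one_chrom_tiling(3)
  chip <- tile_track(tl, c(200, 10, 0), lib_size = 1e7)
  input <- tile_track(tl, c(50, 50, 0), lib_size = 5e6)
  s <- tile_signal(chip, input)
  # tile 1: RPM 20 - 10 = 10, rescaled by 1e7/1e6 -> 100
  expect_equal(s$signal[1], 100)
  # tile 2: input RPM exceeds chip RPM -> clamped to 0
  expect_equal(s$signal[2], 0)
  expect_equal(s$signal[3], 0)
  expect_equal(attr(s, "provenance")$lib_chip, 1e7)

  # all-zero input: scaling and inverse rescale cancel, signal = raw counts
  zero <- tile_track(tl, c(0, 0, 0), lib_size = 1e6)
  expect_equal(tile_signal(chip, zero)$signal, chip$count)

  # scale consistency: doubling chip counts and L_chip doubles the signal
  chip2 <- tile_track(tl, 2 * chip$count, lib_size = 2e7)
  expect_equal(tile_signal(chip2, input)$signal, 2 * s$signal)

  other <- tile_track(one_chrom_tiling(4), rep(1, 4), 1e6)
  expect_error(tile_signal(chip, other), "mismatched tilings")
})

test_that("tile_log2fc computes the ratio with pseudocount and BH q-values", {
  tl <- one_chrom_tiling(4)
  mk <- function(sig, lib = 1e6) {
    tr <- tile_signal(tile_track(tl, sig, lib), tile_track(tl, rep(0, 4), lib))
    tr
  }
  case <- mk(c(8, 8, 5, 2)); ctrl <- mk(c(2, 8, 5, 2))
  cmp0 <- tile_log2fc(case, ctrl, pseudocount = 0)
  expect_equal(cmp0$log2fc[1], 2)
  cmp1 <- tile_log2fc(case, ctrl, pseudocount = 1)
  expect_equal(cmp1$log2fc[1], log2(9 / 3))
  expect_equal(cmp1$log2fc[2:4], rep(0, 3))
  expect_true(all(cmp1$p_value[2:4] == 1))
  expect_equal(cmp1$mean_signal[1], 5)

  zc <- mk(c(8, 0, 5, 2))
  expect_error(tile_log2fc(zc, ctrl, pseudocount = 0), "pseudocount")
})

test_that("changed-tile calling follows the two-replicate consistency rule", {
  within_null <- mini_comparison(rep(0, 1), rep(1, 1))
  r1 <- mini_comparison(0.8, 0.05)
  r2 <- mini_comparison(0.6, 0.08)
  expect_equal(as.character(
    call_changed_tiles(r1, r2, within_null, within_null)$category), "gain")

  r2b <- mini_comparison(0.3, 0.05)  # fails the fc cut in one replicate
  expect_equal(as.character(
    call_changed_tiles(r1, r2b, within_null, within_null)$category), "unchanged")

  r2c <- mini_comparison(0.7, 0.05)
  ctrl <- mini_comparison(0.9, 0.01)  # control-vs-control also calls it
  expect_equal(as.character(
    call_changed_tiles(r1, r2c, ctrl, within_null)$category), "excluded")

  loss1 <- mini_comparison(-0.8, 0.01); loss2 <- mini_comparison(-0.6, 0.02)
  expect_equal(as.character(
    call_changed_tiles(loss1, loss2, within_null, within_null)$category), "loss")

  # discordant signs never produce a call
  expect_equal(as.character(
    call_changed_tiles(r1, loss1, within_null, within_null)$category), "unchanged")

  # categories partition a random table
  set.seed(41)
  n <- 200
  mk <- function() mini_comparison(rnorm(n), runif(n))
  calls <- call_changed_tiles(mk(), mk(), mk(), mk())
  expect_equal(sum(table(calls$category)), n)
})

test_that("metagene anchors are the top tiles and offsets respect boundaries", {
  tl <- one_chrom_tiling(100)
  sig <- tile_signal(tile_track(tl, 1:100, 1e6),
                     tile_track(tl, rep(0, 100), 1e6))
  cmp <- mini_comparison(rep(0, 100), rep(1, 100))
  prof <- top_tile_metagene(sig, cmp, top_fraction = 0.05, flank = 3)
  expect_equal(sort(attr(prof, "anchors")), 95:99)
  expect_equal(prof$mean_log2fc, rep(0, 7))
  # the last anchor (tile 99) has no +1..+3 neighbours
  expect_equal(prof$n[prof$offset == 0], 5)
  expect_lt(prof$n[prof$offset == 3], 5)
})

test_that("genomewide_shift summarises per-track medians and pools conditions", {
  tl <- one_chrom_tiling(50)
  base <- tile_signal(tile_track(tl, rpois(50, 100), 1e6),
                      tile_track(tl, rep(0, 50), 1e6))
  up <- base; up$signal <- base$signal + 1
  same <- genomewide_shift(list(base, base), c("control", "cko"))
  expect_equal(same$summary$median[1], same$summary$median[2])
  expect_gt(same$test$p_value, 0.9)

  shift <- genomewide_shift(list(base, up), c("control", "cko"))
  expect_equal(shift$summary$median[2] - shift$summary$median[1], 1)
  g <- glance(shift)
  expect_equal(g$median_cko - g$median_control, 1)
})
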