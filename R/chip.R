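#' Attach counts to a tiling as a tile count track
#'
#' A tile count track is the tiling tibble plus a `count` column, carrying
#' the library size and a sample label as attributes. Library size is the
#' total mapped reads of the library; it may exceed the in-tile sum (reads
#' can fall outside retained tiles) and must be at least 1.
#'
#' @param tiling A tiling from [make_tiling()].
#' @param count Non-negative integer counts, one per tile.
#' @param lib_size Total mapped reads of the library.
#' @param label Sample label (condition, replicate, ChIP/input).
#' @return A tile count track tibble.
#' @export
tile_track <- function(tiling, count, lib_size, label = NA_character_) {
  if (length(count) != nrow(tiling)) abort("need one count per tile")
  if (any(count < 0)) abort("counts must be non-negative")
  if (!is.numeric(lib_size) || lib_size < 1) abort("library size must be >= 1")
  out <- dplyr::mutate(tiling, count = as.numeric(count))
  attr(out, "tile_width") <- tiling_width(tiling)
  attr(out, "lib_size") <- as.numeric(lib_size)
  attr(out, "label") <- label
  out
}

track_lib_size <- function(track, override = NULL) {
  ls <- override %||% attr(track, "lib_size")
  if (is.null(ls)) abort("track has no lib_size attribute; pass one explicitly")
  ls
}

#' Input-subtracted ChIP tile signal
#'
#' Scales ChIP and input counts to reads per million, subtracts input from
#' ChIP per tile, clamps negatives to zero, then re-scales by the inverse of
#' the ChIP reads-per-million factor so the signal returns to the ChIP count
#' scale (re-scaling avoids damping the between-region variation). With
#' library sizes `Lc` (ChIP) and `Li` (input):
#' `s_t = max(0, chip_t 1e6/Lc - input_t 1e6/Li) * Lc/1e6`.
#'
#' @param chip,input Tile count tracks on the same tiling.
#' @param lib_chip,lib_input Optional library-size overrides.
#' @return A tile signal track: the tiling with a `signal` column; the
#'   `provenance` attribute records both library sizes and labels.
#' @export
tile_signal <- function(chip, input, lib_chip = NULL, lib_input = NULL) {
  assert_same_tiling(chip, input)
  lc <- track_lib_size(chip, lib_chip)
  li <- track_lib_size(input, lib_input)
  # algebraically (chip RPM - input RPM) * Lc/1e6; this form keeps the
  # zero-input identity (signal == raw chip counts) exact in floating point
  s <- pmax(0, chip$count - input$count * (lc / li))
  out <- dplyr::mutate(dplyr::select(chip, -"count"), signal = s)
  attr(out, "tile_width") <- tiling_width(chip)
  attr(out, "provenance") <- list(
    lib_chip = lc, lib_input = li,
    chip_label = attr(chip, "label"), input_label = attr(input, "label"))
  out
}

#' Per-tile log2 fold change between two signal tracks
#'
#' `log2fc_t = log2((case_t + c) / (control_t + c))` with pseudocount `c`
#' keeping the ratio finite at zero-signal tiles. Per-tile significance is
#' the exact two-library count-ratio test ([count_ratio_test()]) on the
#' rounded signals, with the size factor taken from the two ChIP library
#' sizes; q-values are Benjamini-Hochberg over all tiles.
#'
#' @param case,control Tile signal tracks on the same tiling (case = mutant).
#' @param pseudocount Non-negative pseudocount on the rescaled count scale;
#'   default 1.
#' @return A tile comparison tibble: tiling columns plus `log2fc`,
#'   `mean_signal`, `p_value`, `q_value`.
#' @export
tile_log2fc <- function(case, control, pseudocount = 1) {
  assert_same_tiling(case, control, "signal tracks")
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  if (pseudocount == 0 && any(case$signal == 0 | control$signal == 0))
    abort("zero signal with pseudocount 0 gives undefined log2fc; use a positive pseudocount")
  pc <- attr(case, "provenance"); pt <- attr(control, "provenance")
  sf <- if (!is.null(pc) && !is.null(pt)) pc$lib_chip / pt$lib_chip else 1
  p <- count_ratio_test(round(case$signal), round(control$signal), sf)
  out <- dplyr::mutate(
    dplyr::select(case, -"signal"),
    log2fc = log2((case$signal + pseudocount) / (control$signal + pseudocount)),
    mean_signal = (case$signal + control$signal) / 2,
    p_value = p,
    q_value = benjamini_hochberg(p))
  attr(out, "tile_width") <- tiling_width(case)
  class(out) <- c("tile_comparison", class(out))
  out
}

#' Call replicate-consistent changed tiles
#'
#' A tile is a `gain` when log2FC > `fc_cut` with q < `q_cut` in BOTH
#' replicate comparisons, `loss` symmetrically below `-fc_cut`; a tile
#' called by either within-genotype comparison (control vs control or
#' mutant vs mutant, same rule) is `excluded`; everything else is
#' `unchanged`. The categories partition the tiles.
#'
#' @param rep1,rep2 Tile comparisons (mutant vs control), one per replicate.
#' @param ctrl_vs_ctrl,cko_vs_cko Optional within-genotype comparisons used
#'   for exclusion.
#' @param fc_cut Absolute log2FC threshold; default 0.5.
#' @param q_cut FDR threshold; default 0.1.
#' @return The tiling with a `category` factor column
#'   (gain/loss/unchanged/excluded) and both replicates' log2FC.
#' @export
call_changed_tiles <- function(rep1, rep2, ctrl_vs_ctrl = NULL,
                               cko_vs_cko = NULL, fc_cut = 0.5, q_cut = 0.1) {
  assert_same_tiling(rep1, rep2, "comparisons")
  called <- function(cmp, sign) {
    if (is.null(cmp)) return(rep(FALSE, nrow(rep1)))
    assert_same_tiling(rep1, cmp, "comparisons")
    ok <- cmp$q_value < q_cut
    switch(sign,
           up = ok & cmp$log2fc > fc_cut,
           down = ok & cmp$log2fc < -fc_cut,
           any = ok & abs(cmp$log2fc) > fc_cut)
  }
  gain <- called(rep1, "up") & called(rep2, "up")
  loss <- called(rep1, "down") & called(rep2, "down")
  excl <- called(ctrl_vs_ctrl, "any") | called(cko_vs_cko, "any")
  category <- dplyr::case_when(
    excl ~ "excluded",
    gain ~ "gain",
    loss ~ "loss",
    .default = "unchanged")
  out <- dplyr::mutate(
    dplyr::select(rep1, dplyr::all_of(c("tile_id", "chrom", "start", "end"))),
    log2fc_rep1 = rep1$log2fc, log2fc_rep2 = rep2$log2fc,
    category = factor(category, levels = c("gain", "loss", "unchanged", "excluded")))
  attr(out, "tile_width") <- tiling_width(rep1)
  out
}

#' Metagene profile around the highest-signal tiles
#'
#' Anchors are the top `ceiling(top_fraction * T)` tiles ranked by the
#' control signal track (ties broken by tile id). For each offset in
#' `-flank..flank` tiles the profile reports the mean and standard error of
#' log2FC and the median signal over anchors; an anchor contributes nothing
#' at offsets that cross a chromosome boundary (no wrap-around).
#'
#' @param signal The control tile signal track used for ranking and for the
#'   median-signal trace.
#' @param comparison A tile comparison supplying per-tile log2FC.
#' @param top_fraction Fraction of tiles used as anchors; default 0.05.
#' @param flank Number of flanking tiles on each side; default 5.
#' @return A tibble: `offset`, `n`, `mean_log2fc`, `se_log2fc`,
#'   `median_signal`. Class `metagene_profile` (has an autoplot method).
#' @export
top_tile_metagene <- function(signal, comparison, top_fraction = 0.05, flank = 5) {
  assert_same_tiling(signal, comparison, "tracks")
  if (top_fraction <= 0 || top_fraction >= 1) abort("top_fraction must be in (0, 1)")
  if (flank < 1) abort("flank must be >= 1")
  n_anchor <- ceiling(top_fraction * nrow(signal))
  ord <- order(-signal$signal, signal$tile_id)
  anchors <- signal$tile_id[ord[seq_len(n_anchor)]]
  chrom_of <- signal$chrom
  lfc <- comparison$log2fc
  sig <- signal$signal
  offs <- -flank:flank
  rows <- purrr::map(offs, function(o) {
    idx <- match(anchors, signal$tile_id) + o
    ok <- idx >= 1 & idx <= nrow(signal)
    ok[ok] <- chrom_of[idx[ok]] == chrom_of[match(anchors, signal$tile_id)][ok]
    idx <- idx[ok]
    tibble(offset = o, n = length(idx),
           mean_log2fc = mean(lfc[idx]),
           se_log2fc = sd(lfc[idx]) / sqrt(length(idx)),
           median_signal = median(sig[idx]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "anchors") <- anchors
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Genome-wide signal-shift summary
#'
#' Per-track median and interquartile range of tile signal, plus a
#' Mann-Whitney U comparison of pooled mutant vs pooled control tile
#' signals.
#'
#' @param tracks A list of tile signal tracks.
#' @param condition Character vector of condition labels ("control" or
#'   "cko"), one per track.
#' @return An object of class `genomewide_shift` with `summary` (per-track
#'   tibble) and `test` (one-row MWU tibble); has tidy/glance methods.
#' @export
genomewide_shift <- function(tracks, condition) {
  if (!length(tracks) || length(tracks) != length(condition))
    abort("need one condition label per track")
  if (any(vapply(tracks, nrow, 0L) == 0)) abort("empty track")
  summ <- purrr::map2(tracks, condition, function(tr, cond) {
    q <- quantile(tr$signal, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(label = attr(tr, "label") %||% NA_character_, condition = cond,
           n_tiles = nrow(tr), q25 = q[1], median = q[2], q75 = q[3])
  }) |> dplyr::bind_rows()
  pool <- function(cond)
    unlist(purrr::map(tracks[condition == cond], "signal"), use.names = FALSE)
  test <- mann_whitney_u(pool("cko"), pool("control"))
  structure(list(summary = summ, test = test), class = "genomewide_shift")
}

#' @method tidy genomewide_shift
#' @export
tidy.genomewide_shift <- function(x, ...) x$summary

#' @method glance genomewide_shift
#' @export
glance.genomewide_shift <- function(x, ...) {
  dplyr::bind_cols(
    tidyr::pivot_wider(dplyr::summarise(dplyr::group_by(x$summary, .data$condition),
                                        median = median(.data$median), .groups = "drop"),
                       names_from = "condition", values_from = "median",
                       names_prefix = "median_"),
    dplyr::select(x$test, mwu_p_value = "p_value"))
}

#' @method print genomewide_shift
#' @export
print.genomewide_shift <- function(x, ...) {
  cat("Genome-wide tile-signal shift\n")
  print(x$summary)
  cat(sprintf("Pooled cKO vs control Mann-Whitney p = %.3g\n", x$test$p_value))
  invisible(x)
}
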