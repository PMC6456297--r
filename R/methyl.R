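#' Read a Bismark-style per-CpG coverage table
#'
#' Expects the 6-column coverage format: chromosome, start (1-based), end,
#' percent methylation, methylated count, unmethylated count. Positions are
#' converted to 0-based internally. When a 7th strand column is present,
#' records on the minus strand are merged into their plus-strand partner one
#' bp upstream (counts summed), so each CpG site yields one record.
#'
#' @param path File path (plain TSV; `#` comment lines are skipped).
#' @param sample Sample identifier attached to every record.
#' @return A tibble: `chrom`, `pos` (0-based), `meth`, `total`, `sample`.
#' @export
read_bismark_cov <- function(path, sample) {
  x <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                       col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE)
  if (ncol(x) < 6) abort("coverage file needs at least 6 columns")
  out <- tibble(chrom = as.character(x[[1]]), pos = as.numeric(x[[2]]) - 1,
                meth = as.numeric(x[[5]]), total = as.numeric(x[[5]]) + as.numeric(x[[6]]))
  if (ncol(x) >= 7 && all(x[[7]] %in% c("+", "-"))) {
    out$pos <- ifelse(x[[7]] == "-", out$pos - 1, out$pos)
    out <- dplyr::summarise(dplyr::group_by(out, .data$chrom, .data$pos),
                            meth = sum(.data$meth), total = sum(.data$total),
                            .groups = "drop")
  }
  if (any(out$meth > out$total)) abort("methylated count exceeds total")
  dplyr::mutate(dplyr::arrange(out, .data$chrom, .data$pos), sample = sample)
}

#' Write per-CpG records in Bismark coverage format
#'
#' @param records A per-CpG tibble (`chrom`, `pos` 0-based, `meth`, `total`).
#' @param path Output path.
#' @export
write_bismark_cov <- function(records, path) {
  pct <- ifelse(records$total > 0, 100 * records$meth / records$total, 0)
  out <- tibble(c1 = records$chrom, c2 = format_bp(records$pos + 1),
                c3 = format_bp(records$pos + 1), c4 = round(pct, 4),
                c5 = records$meth, c6 = records$total - records$meth)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Aggregate per-CpG counts into coverage-filtered tiles
#'
#' Sums methylated and total counts of all member CpGs per tile per sample.
#' A tile is retained only when EVERY sample has at least `min_coverage`
#' reads in it (the per-sample reading of the "covered by at least 10 reads"
#' rule, matching the convention of tile-based RRBS tools); the retained set
#' is the covered-tile universe used as background by every downstream
#' enrichment. Counts are conserved: retained tiles' sums equal the sums of
#' their member CpGs.
#'
#' @param records Per-CpG records (`chrom`, `pos`, `meth`, `total`,
#'   `sample`), all samples stacked.
#' @param tiling A tiling from [make_tiling()] (100 bp for the standard
#'   analysis).
#' @param min_coverage Per-sample minimum reads per tile; default 10.
#' @return A tibble `tile_id`, `chrom`, `start`, `end`, `sample`, `meth`,
#'   `total`, retained tiles only; attribute `universe_size` holds the
#'   retained-tile count.
#' @export
aggregate_cpgs <- function(records, tiling, min_coverage = 10) {
  width <- tiling_width(tiling)
  base <- dplyr::summarise(dplyr::group_by(tiling, .data$chrom),
                           base_id = min(.data$tile_id),
                           chrom_len = max(.data$end), .groups = "drop")
  idx <- match(records$chrom, base$chrom)
  if (anyNA(idx))
    abort(paste0("CpG record on unknown chromosome ",
                 records$chrom[which(is.na(idx))[1]]))
  over <- which(records$pos >= base$chrom_len[idx] | records$pos < 0)
  if (length(over))
    abort(paste0("CpG record outside the layout: ", records$chrom[over[1]],
                 ":", format_bp(records$pos[over[1]])))
  rec <- dplyr::mutate(records,
                       tile_id = base$base_id[idx] + floor(.data$pos / width))
  per <- dplyr::summarise(dplyr::group_by(rec, .data$tile_id, .data$sample),
                          meth = sum(.data$meth), total = sum(.data$total),
                          .groups = "drop")
  n_samples <- dplyr::n_distinct(records$sample)
  keep <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(per, .data$tile_id),
                     ok = dplyr::n() == n_samples & min(.data$total) >= min_coverage,
                     .groups = "drop"),
    .data$ok)
  out <- dplyr::inner_join(per, keep["tile_id"], by = "tile_id")
  out <- dplyr::inner_join(
    dplyr::select(tiling, dplyr::all_of(c("tile_id", "chrom", "start", "end"))),
    out, by = "tile_id")
  out <- dplyr::arrange(out, .data$tile_id, .data$sample)
  attr(out, "tile_width") <- width
  attr(out, "universe_size") <- nrow(keep)
  out
}

#' Pooled percent methylation of a sample group
#'
#' @param table A methylation tile table from [aggregate_cpgs()].
#' @param samples Sample identifiers to pool; default all.
#' @return Pooled percent methylation (0-100).
#' @export
global_methylation <- function(table, samples = NULL) {
  x <- if (is.null(samples)) table else
    dplyr::filter(table, .data$sample %in% samples)
  if (!nrow(x) || sum(x$total) == 0) abort("no reads to pool")
  100 * sum(x$meth) / sum(x$total)
}

#' Tile-wise differential methylation (binomial-GLM likelihood-ratio test)
#'
#' Per tile, compares a binomial logistic regression of methylated/total on
#' the group indicator against the intercept-only model using per-sample
#' observations. With a single binary covariate the MLE fitted proportions
#' are the group-pooled proportions, so the likelihood-ratio statistic has
#' the closed form of a G-statistic on the pooled counts; p-values come from
#' chi-square with 1 df and q-values from Benjamini-Hochberg over all tested
#' tiles. `delta` is the pooled percent difference (case - control) in
#' percentage points; `direction` is its sign. Tiles where either group has
#' zero total are skipped with a warning. An optional scale-factor
#' overdispersion correction divides the statistic by the per-tile Pearson
#' dispersion estimate when that exceeds 1.
#'
#' @param table A methylation tile table from [aggregate_cpgs()].
#' @param case,control Sample identifiers of the two groups.
#' @param overdispersion `"none"` (default) or `"scale"`.
#' @return A tibble of class `dmr_table`: tile coordinates, `delta`,
#'   `p_value`, `q_value`, `direction`.
#' @export
diff_methylation <- function(table, case, control,
                             overdispersion = c("none", "scale")) {
  overdispersion <- match.arg(overdispersion)
  if (!length(case) || !length(control)) abort("need >= 1 sample per group")
  x <- dplyr::filter(table, .data$sample %in% c(case, control))
  x <- dplyr::mutate(x, grp = ifelse(.data$sample %in% case, "A", "B"))
  xlogx <- function(m, t) ifelse(m > 0, m * log(m / t), 0)
  per <- dplyr::summarise(
    dplyr::group_by(x, .data$tile_id),
    ma = sum(.data$meth[.data$grp == "A"]), ta = sum(.data$total[.data$grp == "A"]),
    mb = sum(.data$meth[.data$grp == "B"]), tb = sum(.data$total[.data$grp == "B"]),
    x2 = {
      p0 <- ifelse(.data$grp == "A",
                   sum(.data$meth[.data$grp == "A"]) / sum(.data$total[.data$grp == "A"]),
                   sum(.data$meth[.data$grp == "B"]) / sum(.data$total[.data$grp == "B"]))
      v <- .data$total * p0 * (1 - p0)
      sum(ifelse(v > 0, (.data$meth - .data$total * p0)^2 / v, 0))
    },
    n_obs = dplyr::n(),
    .groups = "drop")
  skip <- per$ta == 0 | per$tb == 0
  if (any(skip))
    warn(paste0(sum(skip), " tile(s) skipped: a group has zero total reads"))
  per <- per[!skip, ]
  ll <- function(m, t) xlogx(m, t) + xlogx(t - m, t)
  g <- 2 * (ll(per$ma, per$ta) + ll(per$mb, per$tb) -
              ll(per$ma + per$mb, per$ta + per$tb))
  g <- pmax(g, 0)
  if (overdispersion == "scale") {
    phi <- per$x2 / pmax(per$n_obs - 2, 1)
    g <- g / pmax(phi, 1)
  }
  p <- pchisq(g, df = 1, lower.tail = FALSE)
  out <- dplyr::inner_join(
    dplyr::distinct(dplyr::select(
      table, dplyr::all_of(c("tile_id", "chrom", "start", "end")))),
    tibble(tile_id = per$tile_id,
           delta = 100 * (per$ma / per$ta - per$mb / per$tb),
           statistic = g, p_value = p),
    by = "tile_id")
  out <- dplyr::mutate(out,
                       q_value = benjamini_hochberg(.data$p_value),
                       direction = ifelse(.data$delta >= 0, "hyper", "hypo"))
  attr(out, "tile_width") <- attr(table, "tile_width") %||% NULL
  attr(out, "universe_size") <- attr(table, "universe_size") %||% NULL
  attr(out, "fdr_method") <- "Benjamini-Hochberg (not the SLIM q-values of tile-based RRBS tools)"
  class(out) <- c("dmr_table", class(out))
  out
}

#' Remove DMR tiles containing strain variants
#'
#' Drops every DMR tile overlapping at least one variant position (variants
#' given as 1-bp intervals, e.g. known C>T / G>A differences between mouse
#' strains, which confound bisulfite conversion). Boundary semantics are
#' half-open: a variant at position `end` of a tile does not overlap it.
#'
#' @param dmrs A DMR tibble (chrom, start, end, ...).
#' @param variants Variant positions as an interval tibble.
#' @return The DMR tibble with overlapping tiles removed; the number removed
#'   is reported via a message.
#' @export
mask_variant_tiles <- function(dmrs, variants) {
  if (!nrow(dmrs) || !nrow(variants)) return(dmrs)
  hit <- overlaps_any(dmrs, variants)
  inform(paste0(sum(hit), " tile(s) removed for overlapping variants"))
  dmrs[!hit, , drop = FALSE]
}

# run code under a temporary seed, restoring the RNG state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Randomly thin clustered significant tiles
#'
#' Chains significant tiles into clusters by single linkage: consecutive
#' tiles on the same chromosome whose starts are less than `max_gap` apart
#' belong to one cluster. From every cluster of at least `min_cluster_size`
#' members exactly one tile is retained, chosen uniformly at random, so a
#' single genomic region is not weighted repeatedly in feature
#' characterisation; singletons are always retained.
#'
#' @param dmrs A sorted DMR tibble.
#' @param max_gap Start-to-start linkage distance in bp; default 1000.
#' @param min_cluster_size Smallest cluster subject to thinning; default 2
#'   (every multi-tile cluster is thinned).
#' @param seed Optional integer making the random choice reproducible.
#' @return The thinned DMR tibble.
#' @export
thin_clustered <- function(dmrs, max_gap = 1000, min_cluster_size = 2, seed = NULL) {
  if (nrow(dmrs) < 2) return(dmrs)
  x <- sort_intervals(dmrs)
  new_cluster <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                     diff(x$start) >= max_gap)
  cl <- cumsum(new_cluster)
  keep <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(x)), cl), function(ix) {
      if (length(ix) < min_cluster_size) ix else ix[sample.int(length(ix), 1)]
    }), use.names = FALSE)
  })
  x[sort(keep), , drop = FALSE]
}

#' Methylation change by histone-mark category
#'
#' Maps fine methylation tiles into the coarse ChIP tiles that contain them
#' (the fine width divides the coarse width, so containment is exact) and
#' summarises the methylation delta per changed-tile category, with
#' Mann-Whitney comparisons of gain-vs-unchanged and loss-vs-unchanged.
#'
#' @param deltas A tibble of fine tiles with a `delta` column (percentage
#'   points), e.g. a full [diff_methylation()] result.
#' @param calls A changed-tile call table from [call_changed_tiles()].
#' @return An object of class `category_assoc`: `summary` (category, n,
#'   median, q25, q75) and `tests` (comparison, p_value); has tidy/glance
#'   methods.
#' @export
methylation_by_category <- function(deltas, calls) {
  width <- tiling_width(calls)
  if (any(tiling_width(deltas) %% 1 != 0) ||
      width %% tiling_width(deltas) != 0)
    abort("fine tile width must divide the coarse tile width")
  chip_key <- function(chrom, start) paste0(chrom, ":", floor(start / width))
  m <- dplyr::mutate(deltas, key = chip_key(.data$chrom, .data$start))
  c2 <- dplyr::mutate(calls, key = chip_key(.data$chrom, .data$start))
  joined <- dplyr::inner_join(
    dplyr::select(m, dplyr::all_of(c("key", "delta"))),
    dplyr::select(c2, dplyr::all_of(c("key", "category"))), by = "key")
  summ <- dplyr::summarise(
    dplyr::group_by(joined, .data$category, .drop = FALSE),
    n = dplyr::n(),
    median = if (dplyr::n() > 0) median(.data$delta) else NA_real_,
    q25 = if (dplyr::n() > 0) quantile(.data$delta, 0.25, names = FALSE) else NA_real_,
    q75 = if (dplyr::n() > 0) quantile(.data$delta, 0.75, names = FALSE) else NA_real_,
    .groups = "drop")
  grab <- function(cat) joined$delta[joined$category == cat]
  tests <- purrr::map(c("gain", "loss"), function(cat) {
    if (!length(grab(cat)) || !length(grab("unchanged"))) return(NULL)
    dplyr::mutate(mann_whitney_u(grab(cat), grab("unchanged")),
                  comparison = paste0(cat, " vs unchanged"), .before = 1)
  }) |> dplyr::bind_rows()
  structure(list(summary = summ, tests = tests), class = "category_assoc")
}

#' @method tidy category_assoc
#' @export
tidy.category_assoc <- function(x, ...) x$summary

#' @method glance category_assoc
#' @export
glance.category_assoc <- function(x, ...) {
  if (!nrow(x$tests)) return(tibble())
  tidyr::pivot_wider(dplyr::select(x$tests, dplyr::all_of(c("comparison", "p_value"))),
                     names_from = "comparison", values_from = "p_value")
}

#' @method print category_assoc
#' @export
print.category_assoc <- function(x, ...) {
  cat("Methylation delta by H3K27me3 category\n")
  print(x$summary)
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}
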