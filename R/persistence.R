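#' Intersect sperm and soma DMR sets
#'
#' Shared DMRs are the tiles present in BOTH input sets (each already
#' significance-filtered, variant-masked and thinned as desired), matched by
#' exact tile identity on the common 100-bp grid. Each shared record carries
#' both methylation deltas and its concordance class: `concordant-hyper`
#' when both deltas are positive, `concordant-hypo` when both are negative,
#' `discordant` otherwise.
#'
#' @param sperm,soma DMR tibbles (tile_id, chrom, start, end, delta, ...)
#'   on the same tiling.
#' @return A shared-DMR tibble with `delta_sperm`, `delta_soma`,
#'   `concordance`.
#' @export
intersect_dmrs <- function(sperm, soma) {
  if (nrow(sperm) && nrow(soma) &&
      tiling_width(sperm) != tiling_width(soma))
    abort("mismatched tiling widths between the two DMR sets")
  shared <- dplyr::inner_join(
    dplyr::select(sperm, dplyr::all_of(c("tile_id", "chrom", "start", "end")),
                  delta_sperm = "delta"),
    dplyr::select(soma, tile_id = "tile_id", delta_soma = "delta"),
    by = "tile_id")
  dplyr::mutate(shared, concordance = dplyr::case_when(
    .data$delta_sperm > 0 & .data$delta_soma > 0 ~ "concordant-hyper",
    .data$delta_sperm < 0 & .data$delta_soma < 0 ~ "concordant-hypo",
    .default = "discordant"))
}

#' Hypergeometric enrichment of a DMR-set overlap
#'
#' Thin wrapper over [hypergeom_overlap()] asking whether `k` shared tiles
#' between sets of sizes `K` and `n` drawn from a universe of `N` covered
#' tiles exceed the chance expectation `K*n/N`.
#'
#' @param k Observed shared-tile count.
#' @param K,n The two DMR-set sizes.
#' @param N Covered-tile universe size.
#' @return A one-row tibble with the margins, `expected` and `p_value`.
#' @export
overlap_enrichment <- function(k, K, n, N) hypergeom_overlap(N, K, n, k)

#' Classify persistence of shared DMRs
#'
#' Counts and fractions per concordance class; Pearson correlation of the
#' two deltas over ALL shared DMRs; the persistent set is the
#' concordant-hyper subset (tiles hypermethylated in both germ line and
#' offspring soma — the candidates for direct inheritance of methylation
#' state). When universe and set-size margins are supplied the
#' hypergeometric overlap enrichment is included.
#'
#' @param shared A shared-DMR tibble from [intersect_dmrs()].
#' @param universe_n Optional covered-tile universe size.
#' @param n_sperm,n_soma Optional input DMR-set sizes.
#' @return An object of class `persistence_report`: `classes` tibble
#'   (class, n, fraction), `correlation` tibble, `persistent` tibble, and
#'   optionally `enrichment`; has tidy/glance/print methods.
#' @export
classify_persistence <- function(shared, universe_n = NULL, n_sperm = NULL,
                                 n_soma = NULL) {
  lv <- c("concordant-hyper", "concordant-hypo", "discordant")
  k <- nrow(shared)
  classes <- dplyr::count(
    dplyr::mutate(shared, concordance = factor(.data$concordance, levels = lv)),
    .data$concordance, .drop = FALSE, name = "n")
  classes$fraction <- if (k > 0) classes$n / k else 0
  correlation <- if (k >= 3 && sd(shared$delta_sperm) > 0 && sd(shared$delta_soma) > 0)
    pearson_r(shared$delta_sperm, shared$delta_soma)
  else tibble(r = NA_real_, n = k, statistic = NA_real_, p_value = NA_real_)
  enrichment <- if (!is.null(universe_n) && !is.null(n_sperm) && !is.null(n_soma))
    overlap_enrichment(k, n_sperm, n_soma, universe_n)
  structure(list(
    n_shared = k,
    classes = classes,
    correlation = correlation,
    persistent = dplyr::filter(shared, .data$concordance == "concordant-hyper"),
    enrichment = enrichment), class = "persistence_report")
}

#' Full sperm-to-soma persistence report
#'
#' Convenience wrapper: intersects two DMR sets, tests the overlap against
#' the hypergeometric expectation over the covered-tile universe, and
#' classifies concordance.
#'
#' @inheritParams intersect_dmrs
#' @param universe_n Covered-tile universe size.
#' @return A `persistence_report` (see [classify_persistence()]).
#' @export
persistence_report <- function(sperm, soma, universe_n) {
  shared <- intersect_dmrs(sperm, soma)
  classify_persistence(shared, universe_n = universe_n,
                       n_sperm = nrow(sperm), n_soma = nrow(soma))
}

#' @method tidy persistence_report
#' @export
tidy.persistence_report <- function(x, ...) x$classes

#' @method glance persistence_report
#' @export
glance.persistence_report <- function(x, ...) {
  out <- tibble(n_shared = x$n_shared,
                n_persistent = nrow(x$persistent),
                pearson_r = x$correlation$r,
                pearson_p = x$correlation$p_value)
  if (!is.null(x$enrichment))
    out <- dplyr::mutate(out, expected_shared = x$enrichment$expected,
                         hypergeom_p = x$enrichment$p_value)
  out
}

#' @method print persistence_report
#' @export
print.persistence_report <- function(x, ...) {
  cat("Sperm-to-soma DMR persistence\n")
  cat(sprintf("  shared DMRs: %d\n", x$n_shared))
  if (!is.null(x$enrichment))
    cat(sprintf("  expected by chance: %.1f (hypergeometric p = %.3g)\n",
                x$enrichment$expected, x$enrichment$p_value))
  for (i in seq_len(nrow(x$classes)))
    cat(sprintf("  %s: %d (%.0f%%)\n", x$classes$concordance[i],
                x$classes$n[i], 100 * x$classes$fraction[i]))
  cat(sprintf("  delta correlation: R = %.3g (p = %.3g)\n",
              x$correlation$r, x$correlation$p_value))
  cat(sprintf("  persistent (concordant-hyper) DMRs: %d\n", nrow(x$persistent)))
  invisible(x)
}

#' Cross-tissue overlap of the persistent DMR set
#'
#' Asks how many persistent DMRs recur in another tissue's DMR set. The 2x2
#' table is built over the covered-tile universe — (tile in persistent set)
#' x (tile in tissue set) — giving a sample odds ratio and two-sided Fisher
#' p; the overlap fraction is overlap / persistent-set size; the deltas are
#' Pearson-correlated on the overlapping tiles (soma delta of the
#' persistent record vs the tissue delta).
#'
#' @param persistent Persistent-DMR tibble (from a `persistence_report`).
#' @param tissue_dmrs DMR tibble for the other tissue, same tiling.
#' @param universe_n Covered-tile universe size.
#' @param tissue Label for the tissue.
#' @return A one-row tibble: tissue, set sizes, overlap count and fraction,
#'   `odds_ratio`, `p_value`, `pearson_r`.
#' @export
cross_tissue <- function(persistent, tissue_dmrs, universe_n, tissue = "tissue") {
  if (!nrow(persistent)) abort("empty persistent set")
  ov <- dplyr::inner_join(
    dplyr::select(persistent, dplyr::all_of(c("tile_id", "delta_soma"))),
    dplyr::select(tissue_dmrs, dplyr::all_of(c("tile_id")), delta_tissue = "delta"),
    by = "tile_id")
  a <- nrow(ov)
  b <- nrow(persistent) - a
  cc <- nrow(tissue_dmrs) - a
  d <- universe_n - a - b - cc
  if (d < 0) abort("universe_n smaller than the union of the two sets")
  ft <- fisher_exact(c(a, b, cc, d))
  r <- if (a >= 3 && sd(ov$delta_soma) > 0 && sd(ov$delta_tissue) > 0)
    pearson_r(ov$delta_soma, ov$delta_tissue)$r else NA_real_
  tibble(tissue = tissue, n_persistent = nrow(persistent),
         n_tissue = nrow(tissue_dmrs), overlap = a,
         fraction = a / nrow(persistent), odds_ratio = ft$odds_ratio,
         p_value = ft$p_value, pearson_r = r)
}
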