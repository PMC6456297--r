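#' Compare distance-to-feature distributions of two tile sets
#'
#' Computes the midpoint-to-nearest-edge distance (see
#' [nearest_feature_distance()]) of every query and background tile to a
#' feature set and compares the two distributions by a two-sided
#' Mann-Whitney U test. Tiles without a same-chromosome feature (the
#' "no neighbor" sentinel) are excluded from the test, with the excluded
#' counts reported. The background conventionally defaults to the complete
#' covered-tile universe.
#'
#' @param query,background Interval tibbles of tiles.
#' @param features Feature tibble (chrom, start, end).
#' @param label Feature label for the output row.
#' @return An object of class `distance_comparison`: `summary` one-row
#'   tibble (label, set sizes, excluded counts, medians, p_value) and
#'   `distances` (set, distance) for plotting; has tidy/autoplot methods.
#' @export
distance_comparison <- function(query, background, features, label = "feature") {
  if (!nrow(features)) abort("empty feature set")
  dq <- nearest_feature_distance(query, features)
  db <- nearest_feature_distance(background, features)
  test <- mann_whitney_u(dq[!is.na(dq)], db[!is.na(db)])
  summary <- tibble(
    label = label, n_query = nrow(query), n_background = nrow(background),
    excluded_query = sum(is.na(dq)), excluded_background = sum(is.na(db)),
    median_query = median(dq, na.rm = TRUE),
    median_background = median(db, na.rm = TRUE),
    p_value = test$p_value)
  distances <- dplyr::bind_rows(
    tibble(set = "query", distance = dq[!is.na(dq)]),
    tibble(set = "background", distance = db[!is.na(db)]))
  structure(list(summary = summary, distances = distances),
            class = "distance_comparison")
}

#' @method tidy distance_comparison
#' @export
tidy.distance_comparison <- function(x, ...) x$summary

#' @method print distance_comparison
#' @export
print.distance_comparison <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Compare feature-overlap fractions of two tile sets
#'
#' Fraction of each set overlapping at least one feature, with a two-sided
#' Fisher test on the 2x2 of set membership by overlap status.
#'
#' @inheritParams distance_comparison
#' @return A one-row tibble: label, window (0), counts, fractions,
#'   `odds_ratio`, `p_value`.
#' @export
overlap_fraction_test <- function(query, background, features, label = "feature") {
  proximity_enrichment(query, background, features, window = 0, label = label)
}

#' Windowed proximity enrichment of a tile set near features
#'
#' A tile is "near" a feature set when its nearest-feature distance is at
#' most `window` bp (so `window = 0` reduces exactly to the overlap
#' fraction test, since distance 0 means overlap). Enrichment of the query
#' set over the background is a two-sided Fisher test on (set) x (near).
#'
#' @inheritParams distance_comparison
#' @param window Distance threshold in bp; default 1000 (the "within 1 kb"
#'   convention for gene proximity).
#' @return A one-row tibble: label, window, near counts, set sizes,
#'   fractions, `odds_ratio`, `p_value`.
#' @export
proximity_enrichment <- function(query, background, features, window = 1000,
                                 label = "feature") {
  if (window < 0) abort("window must be non-negative")
  near <- function(x) {
    if (!nrow(features)) return(rep(FALSE, nrow(x)))
    d <- nearest_feature_distance(x, features)
    !is.na(d) & d <= window
  }
  nq <- near(query); nb <- near(background)
  ft <- fisher_exact(c(sum(nq), sum(!nq), sum(nb), sum(!nb)))
  tibble(label = label, window = window,
         near_query = sum(nq), n_query = nrow(query),
         near_background = sum(nb), n_background = nrow(background),
         fraction_query = mean(nq), fraction_background = mean(nb),
         odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}

#' Tiles with the greatest histone-mark change
#'
#' Ranks tiles by absolute log2 fold change and returns the top
#' `ceiling(fraction * T)` as a feature set for distance analyses (ties
#' broken by tile id, deterministically).
#'
#' @param comparison A tile comparison from [tile_log2fc()].
#' @param fraction Fraction of tiles to keep; default 0.25.
#' @return A sorted interval tibble (chrom, start, end, name = tile id).
#' @export
top_changed_regions <- function(comparison, fraction = 0.25) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  n <- ceiling(fraction * nrow(comparison))
  ord <- order(-abs(comparison$log2fc), comparison$tile_id)
  out <- comparison[ord[seq_len(n)], c("chrom", "start", "end", "tile_id")]
  out <- dplyr::mutate(out, name = as.character(.data$tile_id))
  sort_intervals(dplyr::select(out, -"tile_id"))
}
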