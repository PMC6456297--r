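#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that
#' anchors every tiling, track and feature set in the pipeline. Coordinates
#' are 0-based half-open throughout the package (BED convention).
#'
#' @param chrom Character vector of unique chromosome names, in the order the
#'   pipeline should use everywhere.
#' @param length Positive integer vector of chromosome lengths in base pairs.
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 2e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (length(chrom) != length(length)) abort("chrom and length differ in length")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length < 1) || any(length != floor(length)))
    abort("every chromosome length must be a positive integer")
  tibble(chrom = chrom, length = length)
}

assert_layout <- function(layout) {
  if (!is.data.frame(layout) || !all(c("chrom", "length") %in% names(layout)))
    abort("expected a genome layout with columns chrom and length")
  invisible(layout)
}

#' Read or write a genome layout as two-column TSV
#'
#' The file holds one row per chromosome: name and length, tab-separated.
#' `write_genome_layout()` prepends a tool-version comment line which
#' `read_genome_layout()` skips.
#'
#' @param path File path.
#' @return `read_genome_layout()` returns a layout tibble.
#' @export
read_genome_layout <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  genome_layout(x$chrom, x$length)
}

#' @rdname read_genome_layout
#' @param layout A genome layout tibble.
#' @export
write_genome_layout <- function(layout, path) {
  assert_layout(layout)
  writeLines(epi_version_header(), path)
  readr::write_tsv(layout, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Tile a genome into fixed-width windows
#'
#' Produces ordered, non-overlapping tiles that partition every chromosome.
#' The final tile of a chromosome is shorter when the length is not an exact
#' multiple of `width`; short terminal tiles are kept (downstream coverage
#' filters remove unreliable tiles anyway). Tile ids are dense integers
#' `0..T-1` in layout order, so a tile id is a stable coordinate for joins
#' across tracks and sample tables.
#'
#' @param layout A genome layout tibble (see [genome_layout()]).
#' @param width Tile width in bp; the analysis grids are 2000 bp for ChIP
#'   signal and 100 bp for methylation.
#' @return A tibble with columns `tile_id`, `chrom`, `start`, `end`.
#' @examples
#' make_tiling(genome_layout("chr1", 250), width = 100)
#' @export
make_tiling <- function(layout, width) {
  assert_layout(layout)
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width < 1)
    abort("width must be a positive number of base pairs")
  width <- as.integer(width)
  per_chrom <- purrr::map2(layout$chrom, layout$length, function(ch, len) {
    starts <- seq(0, len - 1, by = width)
    tibble(chrom = ch, start = starts, end = pmin(starts + width, len))
  })
  out <- dplyr::bind_rows(per_chrom)
  out <- tibble(tile_id = seq_len(nrow(out)) - 1L, out)
  attr(out, "tile_width") <- width
  out
}

tiling_width <- function(tiling) {
  w <- attr(tiling, "tile_width")
  if (!is.null(w)) return(as.integer(w))
  as.integer(max(tiling$end - tiling$start))
}

assert_same_tiling <- function(a, b, what = "tracks") {
  if (nrow(a) != nrow(b) || !identical(a$tile_id, b$tile_id))
    abort(paste0("mismatched tilings: the two ", what,
                 " are not on the same tile grid"))
  invisible(TRUE)
}

validate_intervals <- function(x, layout = NULL, context = "interval set") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    abort(paste0(context, " must have columns chrom, start, end"))
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    abort(paste0(context, ": invalid interval at row ", bad[1],
                 " (need 0 <= start < end)"))
  if (!is.null(layout)) {
    assert_layout(layout)
    unknown <- setdiff(unique(x$chrom), layout$chrom)
    if (length(unknown))
      abort(paste0(context, ": unknown chromosome ", unknown[1]))
    len <- setNames(layout$length, layout$chrom)
    over <- which(x$end > len[x$chrom])
    if (length(over))
      abort(paste0(context, ": interval at row ", over[1],
                   " extends past the chromosome end"))
  }
  invisible(x)
}

sort_intervals <- function(x) dplyr::arrange(x, .data$chrom, .data$start, .data$end)

#' Read a BED file of genomic features
#'
#' Accepts BED3/BED4 (tab-separated, 0-based half-open). Lines beginning with
#' `#`, `track` or `browser` are skipped. Records need not be sorted in the
#' file; the returned tibble is sorted by (chrom, start, end). Malformed
#' records (start >= end, negative coordinates, or a chromosome missing from
#' `layout` when one is supplied) raise an error naming the offending line.
#'
#' @param path BED file path.
#' @param layout Optional genome layout used to validate chromosome names and
#'   bounds.
#' @param label Optional label stored as the `label` attribute of the result
#'   (e.g. "TSS", "enhancer"); defaults to the file name.
#' @return A tibble with columns `chrom`, `start`, `end`, `name` (NA when the
#'   file is BED3), sorted.
#' @export
read_bed <- function(path, layout = NULL, label = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(fields)
    if (any(nfield < 3))
      abort(paste0("BED parse error at line ", lineno[which(nfield < 3)[1]],
                   ": fewer than 3 columns"))
    chrom <- vapply(fields, `[[`, "", 1)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
    name <- ifelse(nfield >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                   NA_character_)
    bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
    if (length(bad))
      abort(paste0("BED parse error at line ", lineno[bad[1]],
                   ": need 0 <= start < end"))
    out <- tibble(chrom = chrom, start = start, end = end, name = name)
    if (!is.null(layout)) {
      unknown <- which(!out$chrom %in% layout$chrom)
      if (length(unknown))
        abort(paste0("BED parse error at line ", lineno[unknown[1]],
                     ": unknown chromosome ", out$chrom[unknown[1]]))
    }
  }
  out <- sort_intervals(out)
  attr(out, "label") <- label %||% basename(path)
  out
}

#' Write features as BED
#'
#' Writes BED4 when a `name` column with any non-missing value is present,
#' BED3 otherwise, sorted, with a tool-version header comment.
#'
#' @param features Interval tibble with columns chrom, start, end and
#'   optionally name.
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  validate_intervals(features, context = "BED output")
  x <- sort_intervals(features)
  has_name <- "name" %in% names(x) && any(!is.na(x$name))
  cols <- if (has_name) {
    tibble(x$chrom, format_bp(x$start), format_bp(x$end),
           ifelse(is.na(x$name), ".", as.character(x$name)))
  } else {
    tibble(x$chrom, format_bp(x$start), format_bp(x$end))
  }
  writeLines(epi_version_header(), path)
  readr::write_tsv(cols, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

# integer-style formatting for coordinates stored as doubles
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

# IRanges handles per-chromosome overlap queries; split/apply by chromosome
overlap_hits_by_chrom <- function(query, features, maxgap = -1L) {
  hit <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    fr <- IRanges::IRanges(start = features$start[fi] + 1, end = features$end[fi])
    hit[qi] <- IRanges::overlapsAny(qr, fr, maxgap = maxgap)
  }
  hit
}

#' Test whether intervals overlap any feature
#'
#' Half-open semantics: `[0,100)` and `[100,200)` do not overlap; an overlap
#' requires at least 1 shared bp. Features on other chromosomes never count.
#'
#' @param query Interval tibble (chrom, start, end), one row per query.
#' @param features Feature tibble (chrom, start, end).
#' @return Logical vector, one element per query row.
#' @export
overlaps_any <- function(query, features) {
  validate_intervals(query, context = "query")
  validate_intervals(features, context = "features")
  overlap_hits_by_chrom(query, features)
}

#' Distance from interval midpoints to the nearest feature edge
#'
#' The distance is 0 when the query overlaps any feature; otherwise it is the
#' gap in bp from the query midpoint (`floor((start+end)/2)`) to the nearest
#' feature edge (start or end coordinate) on the same chromosome. Queries on
#' chromosomes carrying no feature get `NA` (the "no neighbor" sentinel) —
#' never a silent 0.
#'
#' @inheritParams overlaps_any
#' @return Numeric vector of distances in bp, `NA` where no same-chromosome
#'   feature exists.
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' f <- tibble::tibble(chrom = "chr1", start = 650, end = 700)
#' nearest_feature_distance(q, f)  # 500
#' @export
nearest_feature_distance <- function(query, features) {
  validate_intervals(query, context = "query")
  validate_intervals(features, context = "features")
  out <- rep(NA_real_, nrow(query))
  mid <- floor((query$start + query$end) / 2)
  ov <- overlap_hits_by_chrom(query, features)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    edges <- sort(unique(c(features$start[fi], features$end[fi])))
    pos <- findInterval(mid[qi], edges)
    lo <- ifelse(pos >= 1, edges[pmax(pos, 1)], Inf)
    hi <- ifelse(pos < length(edges), edges[pmin(pos + 1, length(edges))], Inf)
    d <- pmin(abs(mid[qi] - lo), abs(hi - mid[qi]))
    out[qi] <- ifelse(ov[qi], 0, d)
  }
  out
}
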