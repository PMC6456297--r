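# Track, comparison and DMR table readers/writers. All writers emit a
# tool-version comment header; readers skip comment lines.

#' Write and read tile count tracks as bedGraph plus a library-size sidecar
#'
#' The bedGraph holds chrom/start/end/count per tile; the sidecar TSV (same
#' path with `.libsize.tsv` appended) records the library size and label.
#'
#' @param track A tile count track from [tile_track()].
#' @param path bedGraph path.
#' @return `read_tile_track()` returns a tile count track.
#' @export
write_tile_track <- function(track, path) {
  writeLines(epi_version_header(), path)
  readr::write_tsv(tibble(track$chrom, format_bp(track$start),
                          format_bp(track$end), track$count),
                   path, col_names = FALSE, append = TRUE)
  side <- tibble(lib_size = attr(track, "lib_size"),
                 label = attr(track, "label") %||% NA_character_)
  readr::write_tsv(side, paste0(path, ".libsize.tsv"))
  invisible(path)
}

#' @rdname write_tile_track
#' @param tiling The tiling the counts live on.
#' @export
read_tile_track <- function(path, tiling) {
  x <- readr::read_tsv(path, comment = "#",
                       col_names = c("chrom", "start", "end", "count"),
                       col_types = "cddd", progress = FALSE)
  key <- paste0(x$chrom, ":", x$start)
  idx <- match(paste0(tiling$chrom, ":", tiling$start), key)
  if (anyNA(idx)) abort("bedGraph does not cover the tiling")
  side <- readr::read_tsv(paste0(path, ".libsize.tsv"), col_types = "dc",
                          progress = FALSE)
  tile_track(tiling, x$count[idx], side$lib_size[1], side$label[1])
}

#' Write a per-tile table as TSV with a version header
#'
#' Generic writer for signal tracks, comparisons and DMR tables; numeric
#' columns are written in full precision.
#'
#' @param x A tibble.
#' @param path Output path.
#' @export
write_tile_tsv <- function(x, path) {
  writeLines(epi_version_header(), path)
  suppressWarnings(readr::write_tsv(as_tibble(x), path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname write_tile_tsv
#' @export
read_tile_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                  progress = FALSE)
}

#' Write changed-tile calls as BED4
#'
#' The category occupies the BED name field.
#'
#' @param calls A changed-tile call table.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  write_bed(dplyr::mutate(
    dplyr::select(calls, dplyr::all_of(c("chrom", "start", "end"))),
    name = as.character(calls$category)), path)
}
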