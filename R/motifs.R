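#' Read position weight matrices in MEME minimal format
#'
#' Parses the minimal motif format: a `MOTIF <name>` line followed by a
#' `letter-probability matrix` header and one row of four probabilities
#' (A C G T) per motif position. Columns must each sum to 1 within 1e-6 and
#' motifs must have at least 4 positions.
#'
#' @param path MEME file path.
#' @return A named list of 4-row probability matrices (rows A, C, G, T).
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) abort("no MOTIF records found")
  pwms <- list()
  for (i in seq_along(starts)) {
    name <- strsplit(lines[starts[i]], "\\s+")[[1]][2]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:to]
    rows <- grep("^[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}$", block, value = TRUE)
    if (!length(rows)) abort(paste0("motif ", name, ": no probability rows"))
    m <- t(vapply(strsplit(rows, "\\s+"),
                  function(r) as.numeric(r[1:4]), numeric(4)))
    pwm <- t(m)  # 4 x L, rows A C G T
    rownames(pwm) <- c("A", "C", "G", "T")
    validate_pwm(pwm, name)
    pwms[[name]] <- pwm
  }
  pwms
}

validate_pwm <- function(pwm, name = "pwm") {
  if (!is.matrix(pwm) || nrow(pwm) != 4)
    abort(paste0(name, ": a PWM must be a 4-row (A,C,G,T) matrix"))
  if (ncol(pwm) < 4) abort(paste0(name, ": motif length must be >= 4"))
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    abort(paste0(name, ": PWM columns must each sum to 1"))
  invisible(pwm)
}

#' Write position weight matrices in MEME minimal format
#'
#' @param pwms Named list of 4-row probability matrices.
#' @param path Output path.
#' @export
write_meme <- function(pwms, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (name in names(pwms)) {
    pwm <- validate_pwm(pwms[[name]], name)
    lines <- c(lines, paste("MOTIF", name),
               sprintf("letter-probability matrix: alength= 4 w= %d", ncol(pwm)),
               apply(pwm, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write tile sequences as FASTA
#'
#' Thin wrappers over Biostrings; sequences are handled in the package as a
#' named character vector (names = tile ids).
#'
#' @param path FASTA path.
#' @return `read_tile_fasta()` returns a named character vector.
#' @export
read_tile_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_tile_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_tile_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, names(seqs) %||% seq_along(seqs))),
    path)
  invisible(path)
}

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# max log2-odds over all windows of one sequence (one strand); -Inf windows
# (containing N) never win
best_window_score <- function(codes, lods) {
  m <- ncol(lods)
  nw <- length(codes) - m + 1
  if (nw < 1) return(-Inf)
  best <- -Inf
  for (w in seq_len(nw)) {
    idx <- codes[w:(w + m - 1)]
    if (anyNA(idx)) next
    s <- sum(lods[cbind(idx, seq_len(m))])
    if (s > best) best <- s
  }
  best
}

#' Scan sequences for a PWM hit
#'
#' Scores every window of each sequence, on both strands, as the sum of
#' per-position log2 odds `log2(p_pos(base) / background)` with a uniform
#' 0.25 background (configurable to the pooled 0-order composition of the
#' sequences). A sequence is a hit when its best window score reaches
#' `score_fraction` of the maximum achievable score of the PWM. Windows
#' containing `N` score `-Inf`; sequences shorter than the motif are
#' no-hits.
#'
#' @param seqs Character vector of DNA sequences over `A,C,G,T,N`.
#' @param pwm A 4-row probability matrix (rows A, C, G, T).
#' @param score_fraction Fraction of the maximum score required; default 0.8.
#' @param background Either `"uniform"` or a length-4 base-frequency vector.
#' @return Logical vector, one flag per sequence.
#' @export
scan_pwm <- function(seqs, pwm, score_fraction = 0.8, background = "uniform") {
  validate_pwm(pwm)
  bg <- if (identical(background, "uniform")) rep(0.25, 4) else {
    if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
      abort("background must be 'uniform' or 4 frequencies summing to 1")
    as.numeric(background)
  }
  eps <- 1e-9
  lods <- log2(pmax(pwm, eps) / bg)
  thresh <- score_fraction * sum(apply(lods, 2, max))
  fwd <- lapply(strsplit(toupper(seqs), ""), function(ch) unname(BASE_CODE[ch]))
  rev_lods <- lods[4:1, ncol(lods):1, drop = FALSE]  # scan reverse strand
  vapply(fwd, function(codes) {
    max(best_window_score(codes, lods), best_window_score(codes, rev_lods)) >= thresh
  }, logical(1))
}

#' Motif enrichment of a query tile set against a control set
#'
#' Classifies every query and control sequence as hit/no-hit per PWM
#' ([scan_pwm()]), then tests each motif's hit counts with a two-sided
#' Fisher exact test; adjusted p-values are Bonferroni over the number of
#' motifs tested. Rows are sorted by adjusted p (ties by raw p, then name).
#'
#' @param query_seqs,control_seqs Character vectors of DNA sequences; the
#'   control set is conventionally the full covered-tile universe.
#' @param pwms Named list of PWMs.
#' @param score_fraction Hit threshold passed to [scan_pwm()].
#' @return A tibble: `motif`, hit counts and set sizes, `pct_query`,
#'   `pct_control`, `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
motif_enrichment <- function(query_seqs, control_seqs, pwms, score_fraction = 0.8) {
  if (!length(pwms)) abort("empty PWM set")
  if (!length(query_seqs) || !length(control_seqs))
    abort("both sequence sets must be non-empty")
  rows <- purrr::imap(pwms, function(pwm, name) {
    hq <- sum(scan_pwm(query_seqs, pwm, score_fraction))
    hc <- sum(scan_pwm(control_seqs, pwm, score_fraction))
    ft <- fisher_exact(c(hq, length(query_seqs) - hq,
                         hc, length(control_seqs) - hc))
    tibble(motif = name,
           hits_query = hq, n_query = length(query_seqs),
           hits_control = hc, n_control = length(control_seqs),
           pct_query = 100 * hq / length(query_seqs),
           pct_control = 100 * hc / length(control_seqs),
           odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, p_adjusted = pmin(1, .data$p_value * length(pwms)))
  dplyr::arrange(out, .data$p_adjusted, .data$p_value, .data$motif)
}
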