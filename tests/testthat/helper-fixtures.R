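# Shared fixtures and independent oracles used across test files.

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(10000, 8000))

# brute-force midpoint-to-edge distance oracle (O(n*m))
brute_nearest <- function(query, features) {
  vapply(seq_len(nrow(query)), function(i) {
    mid <- floor((query$start[i] + query$end[i]) / 2)
    same <- features$chrom == query$chrom[i]
    if (!any(same)) return(NA_real_)
    ov <- any(features$start[same] < query$end[i] &
                features$end[same] > query$start[i])
    if (ov) return(0)
    edges <- c(features$start[same], features$end[same])
    min(abs(mid - edges))
  }, numeric(1))
}

# brute-force pairwise overlap oracle
brute_overlap <- function(query, features) {
  vapply(seq_len(nrow(query)), function(i) {
    any(features$chrom == query$chrom[i] &
          features$start < query$end[i] &
          features$end > query$start[i])
  }, logical(1))
}

# two-sided Fisher oracle: direct point-probability enumeration with dhyper
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  sum(probs[probs <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

# upper-tail hypergeometric oracle by summing point probabilities
hyper_tail_oracle <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# exact two-sided Mann-Whitney oracle: enumerate every way the pooled ranks
# could be split between the samples under the null
mwu_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# a tiny comparison table for changed-tile calling tests
mini_comparison <- function(log2fc, q) {
  n <- length(log2fc)
  tibble::tibble(tile_id = seq_len(n) - 1L, chrom = "chr1",
                 start = (seq_len(n) - 1) * 2000, end = seq_len(n) * 2000,
                 log2fc = log2fc, q_value = q)
}
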