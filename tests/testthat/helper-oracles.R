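# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's interval/statistics code paths: coverage
# questions are answered with per-base boolean arrays, rank tests with
# bitmask permutation enumeration, correlations with cor.test loops.

# per-base occupancy vector of an interval set on one chromosome
occupancy <- function(intervals, chrom_len) {
  occ <- logical(chrom_len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals[i, 1]; e <- intervals[i, 2]
    occ[(s + 1):e] <- TRUE
  }
  occ
}

oracle_union_length <- function(intervals, chrom_len = 1e5) {
  sum(occupancy(intervals, chrom_len))
}

oracle_covered <- function(a, b, chrom_len = 1e5) {
  occ_b <- occupancy(b, chrom_len)
  vapply(seq_len(nrow(a)), function(i)
    sum(occ_b[(a[i, 1] + 1):a[i, 2]]), numeric(1))
}

oracle_tf_diversity <- function(region, track, min_bp = 1) {
  hits <- character(0)
  for (i in seq_len(nrow(track))) {
    ov <- min(track$end[i], region[2]) - max(track$start[i], region[1])
    if (ov >= min_bp) hits <- c(hits, track$subtype[i])
  }
  length(unique(hits))
}

oracle_nearest <- function(pos, sites) {
  best <- Inf
  for (i in seq_len(nrow(sites))) {
    if (pos >= sites$start[i] && pos < sites$end[i]) return(0)
    best <- min(best, abs(pos - sites$start[i]),
                abs(pos - (sites$end[i] - 1)))
  }
  best
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# values to group 1 (bitmask over subsets of the right size)
oracle_ranksum_p <- function(x, y) {
  n <- length(x) + length(y)
  rk <- rank(c(x, y))
  mu <- length(x) * (n + 1) / 2
  obs <- abs(sum(rk[seq_along(x)]) - mu)
  hits <- 0; total <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(bitwShiftL(1, 0:(n - 1)), mask) != 0)
    if (length(sel) != length(x)) next
    total <- total + 1
    if (abs(sum(rk[sel]) - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / total
}

# small fixture: layout + a handful of genes on one 100 kb chromosome
toy_layout <- function() genome_layout(c("chr1", "chrX", "chrY"),
                                       c(1e5, 8e4, 5e4))

toy_gene <- function(id = "g1", biotype = "processed_pseudogene",
                     chrom = "chr1", strand = "+",
                     exons = cbind(c(1000, 3000), c(2000, 4000)),
                     parent = NA) {
  gene_record(id, biotype, chrom, strand, exons, parent)
}

random_intervals <- function(n, chrom_len = 1e5, max_len = 500) {
  s <- sample.int(chrom_len - max_len, n)
  cbind(s, s + sample.int(max_len, n, replace = TRUE))
}

# small expression fixture: 2 tissues x 3 stages x 2 reps
toy_meta <- function(tissues = c("brain", "liver"),
                     times = c(10, 40, 160), reps = 2) {
  meta <- expand.grid(replicate = seq_len(reps), time_days = times,
                      tissue = tissues, stringsAsFactors = FALSE)
  meta$stage <- paste0("s", match(meta$time_days, times))
  meta$sample_id <- sprintf("%s_%d_r%d", meta$tissue, meta$time_days,
                            meta$replicate)
  meta
}
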