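# Overlap-based regulatory metrics: TF diversity at promoters, chromHMM
# state counts, SNP densities, nearest-m6A distances, and rank-based
# comparisons between region classes (coding genes, dynamic pseudogenes,
# non-dynamic pseudogenes, shuffled intergenic controls).

#' Distinct transcription factors overlapping each region
#'
#' TF diversity of a region is the number of distinct TF names (the track's
#' subtype labels) with at least `min_overlap_bp` overlap.
#'
#' @param regions region frame.
#' @param tf_track TF [feature_track()] with subtype labels.
#' @param min_overlap_bp minimum overlap per site (default 1).
#' @return integer vector, one count per region.
#' @export
tf_diversity <- function(regions, tf_track, min_overlap_bp = 1) {
  .check_regions(regions)
  vapply(seq_len(nrow(regions)), function(i) {
    tr <- tf_track[tf_track$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(tr) == 0) return(0L)
    ov <- pmin(tr$end, regions$end[i]) - pmax(tr$start, regions$start[i])
    length(unique(tr$subtype[ov >= min_overlap_bp]))
  }, integer(1))
}

#' Distinct chromHMM states annotating each region
#'
#' A region counts as annotated by a state when it overlaps that state's
#' intervals by more than 1 bp, i.e. `min_overlap_bp = 2` by default (the
#' strict reading of the more-than-1-bp rule).
#'
#' @param regions region frame (typically promoters).
#' @param state_track chromHMM [feature_track()] with state names as
#'   subtypes.
#' @param min_overlap_bp minimum overlap (default 2).
#' @return integer vector of distinct qualifying states per region.
#' @export
chromhmm_state_count <- function(regions, state_track, min_overlap_bp = 2) {
  tf_diversity(regions, state_track, min_overlap_bp)
}

#' SNP count and per-kb density over a region set
#'
#' @param regions region frame; overlapping regions are merged before
#'   counting so no SNP or base is counted twice.
#' @param snps SNP [feature_track()] of single-base features.
#' @return list: `count`, `total_kb` (merged length / 1000), `per_kb`.
#' @export
snp_density <- function(regions, snps) {
  .check_regions(regions)
  if (nrow(snps) > 0 && any(snps$end - snps$start != 1))
    stop("SNP track must contain single-base features")
  total <- 0; count <- 0
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    merged <- .iv_merge(cbind(r$start, r$end))
    total <- total + sum(merged[, 2] - merged[, 1])
    s <- snps[snps$chrom == ch, , drop = FALSE]
    if (nrow(s) > 0)
      count <- count + sum(.iv_covered(cbind(s$start, s$end), merged))
  }
  if (total == 0) stop("zero total region length")
  list(count = count, total_kb = total / 1000, per_kb = count / (total / 1000))
}

#' Distance from anchor positions to the nearest feature site
#'
#' Minimum absolute bp distance from each anchor (e.g. a TSS) to any site
#' interval on the same chromosome; 0 when the anchor lies inside a site.
#' Anchors on chromosomes with no sites get `NA`.
#'
#' @param anchors data.frame with `chrom` and `pos`.
#' @param sites [feature_track()] of intervals.
#' @return numeric vector of distances (>= 0), one per anchor.
#' @export
nearest_site_distance <- function(anchors, sites) {
  if (nrow(sites) == 0) stop("empty site track")
  vapply(seq_len(nrow(anchors)), function(i) {
    s <- sites[sites$chrom == anchors$chrom[i], , drop = FALSE]
    if (nrow(s) == 0) return(NA_real_)
    p <- anchors$pos[i]
    inside <- p >= s$start & p < s$end
    if (any(inside)) return(0)
    min(pmin(abs(p - s$start), abs(p - (s$end - 1))))
  }, numeric(1))
}

# rank-sum statistic of group x against pooled ranks
.ranksum_stat <- function(x, y) sum(rank(c(x, y))[seq_along(x)])

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration of all group assignments (tie-safe) for total
#' n <= `exact_max`, tie-corrected normal approximation above. The
#' two-sided exact p is the fraction of assignments whose rank sum deviates
#' from its null mean at least as much as observed. An all-tied metric
#' returns p = 1 with a warning.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max largest total n for exact enumeration (default 20).
#' @return list: `p_value`, `statistic` (rank sum of `x`), `method`.
#' @export
ranksum_test <- function(x, y, exact_max = 20) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  stopifnot(nx >= 1, ny >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("all values tied; p = 1")
    return(list(p_value = 1, statistic = .ranksum_stat(x, y), method = "degenerate"))
  }
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, nx)
    Wall <- colSums(matrix(rk[combs], nrow = nx))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- 2 * stats::pnorm(-abs(W - mu) / sqrt(sigma2))
    method <- "normal approximation, tie-corrected"
  }
  list(p_value = min(1, p), statistic = W, method = method)
}

#' Regulatory profile of a region set
#'
#' For each region, computes TF diversity, chromHMM state count, SNP count
#' and per-kb density, RBP site count, and (when anchors are supplied)
#' distance to the nearest m6A site.
#'
#' @param regions region frame with `region_id` and `class` columns
#'   (`coding` / `DDP` / `non_dynamic` / `shuffled`).
#' @param tracks named list of [feature_track()]s; recognised names:
#'   `tf`, `chromhmm`, `snp`, `rbp`, `m6a`.
#' @param anchors optional data.frame (`region_id`, `chrom`, `pos`) of
#'   anchor points (TSSs) for m6A distances; defaults to region starts.
#' @param min_overlap_bp overlap rule for TF/RBP calls (default 1; chromHMM
#'   always uses its own >= 2 bp rule via `chromhmm_min_overlap`).
#' @param chromhmm_min_overlap overlap rule for chromHMM annotation
#'   (default 2).
#' @return data.frame of class `regulatory_profile`, one row per region.
#' @export
regulatory_profile <- function(regions, tracks, anchors = NULL,
                               min_overlap_bp = 1, chromhmm_min_overlap = 2) {
  .check_regions(regions)
  if (is.null(regions$region_id))
    regions$region_id <- paste0("region", seq_len(nrow(regions)))
  if (is.null(regions$class)) regions$class <- "region"
  out <- data.frame(region_id = regions$region_id, class = regions$class,
                    chrom = regions$chrom, start = regions$start,
                    end = regions$end, row.names = NULL)
  len_kb <- (regions$end - regions$start) / 1000
  if (!is.null(tracks$tf))
    out$tf_diversity <- tf_diversity(regions, tracks$tf, min_overlap_bp)
  if (!is.null(tracks$chromhmm))
    out$chromhmm_states <- chromhmm_state_count(regions, tracks$chromhmm,
                                                chromhmm_min_overlap)
  if (!is.null(tracks$snp)) {
    cnt <- overlap_fraction(regions, tracks$snp)$covered_bp
    out$snp_count <- cnt
    out$snp_per_kb <- cnt / len_kb
  }
  if (!is.null(tracks$rbp)) {
    rb <- tracks$rbp
    out$rbp_count <- vapply(seq_len(nrow(regions)), function(i) {
      tr <- rb[rb$chrom == regions$chrom[i], , drop = FALSE]
      if (nrow(tr) == 0) return(0L)
      ov <- pmin(tr$end, regions$end[i]) - pmax(tr$start, regions$start[i])
      sum(ov >= min_overlap_bp)
    }, integer(1))
  }
  if (!is.null(tracks$m6a)) {
    if (is.null(anchors))
      anchors <- data.frame(region_id = regions$region_id,
                            chrom = regions$chrom, pos = regions$start)
    anchors <- anchors[match(regions$region_id, anchors$region_id), ]
    out$m6a_distance <- nearest_site_distance(anchors, tracks$m6a)
  }
  structure(out, class = c("regulatory_profile", "data.frame"))
}

#' Compare regulatory metrics between region classes
#'
#' Per-metric medians for each class plus two-sided Wilcoxon rank-sum
#' p-values for each requested class pair (by default DDP vs non-dynamic
#' and DDP vs shuffled controls).
#'
#' @param profile a [regulatory_profile()] (or any data.frame with a
#'   `class` column and numeric metric columns).
#' @param metrics metric column names; default all numeric columns except
#'   coordinates.
#' @param pairs list of length-2 character vectors of class labels.
#' @return list: `medians` (class x metric), `tests` (data.frame metric,
#'   pair, p_value, method).
#' @export
class_comparison <- function(profile,
                             metrics = NULL,
                             pairs = list(c("DDP", "non_dynamic"),
                                          c("DDP", "shuffled"))) {
  if (is.null(metrics)) {
    num <- vapply(profile, is.numeric, logical(1))
    metrics <- setdiff(names(profile)[num], c("start", "end"))
  }
  classes <- unique(profile$class)
  if (length(classes) < 2) stop("need >= 2 region classes")
  med <- sapply(metrics, function(m)
    tapply(profile[[m]], profile$class, stats::median, na.rm = TRUE))
  tests <- list()
  for (pr in pairs) {
    if (!all(pr %in% classes)) next
    for (m in metrics) {
      x <- stats::na.omit(profile[[m]][profile$class == pr[1]])
      y <- stats::na.omit(profile[[m]][profile$class == pr[2]])
      if (length(x) < 2 || length(y) < 2) next
      tt <- ranksum_test(x, y)
      tests[[length(tests) + 1]] <- data.frame(
        metric = m, class_a = pr[1], class_b = pr[2],
        p_value = tt$p_value, method = tt$method)
    }
  }
  list(medians = med, tests = do.call(rbind, tests))
}
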