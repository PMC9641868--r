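# Interval algebra on 0-based half-open coordinates. All exported functions
# accept "region frames": data.frames with columns chrom, start, end (and
# optionally subtype). Single-chromosome helpers work on two-column matrices.
# IRanges does the heavy lifting; the half-open <-> 1-based-closed shift is
# confined to .as_iranges()/.from_iranges().

.iv <- function(start, end) {
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("intervals must have end > start (0-based half-open)")
  cbind(start = as.numeric(start), end = as.numeric(end))
}

.as_iranges <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$start, x$end)
  IRanges::IRanges(start = x[, 1] + 1, end = x[, 2])
}

.from_iranges <- function(r) {
  cbind(start = BiocGenerics::start(r) - 1, end = BiocGenerics::end(r))
}

.iv_merge <- function(x) .from_iranges(IRanges::reduce(.as_iranges(x)))

.iv_union_length <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(0)
  sum(BiocGenerics::width(IRanges::reduce(.as_iranges(x))))
}

# per-interval bp of `a` covered by the union of `b` (same chromosome)
.iv_covered <- function(a, b) {
  na <- if (is.data.frame(a)) nrow(a) else nrow(a)
  if (na == 0) return(numeric(0))
  if (is.null(b) || nrow(b) == 0) return(rep(0, na))
  ai <- .as_iranges(a)
  bi <- IRanges::reduce(.as_iranges(b))
  hits <- IRanges::findOverlaps(ai, bi)
  covered <- rep(0, na)
  if (length(hits) > 0) {
    pi <- IRanges::pintersect(ai[S4Vectors::queryHits(hits)],
                              bi[S4Vectors::subjectHits(hits)])
    w <- tapply(BiocGenerics::width(pi), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  covered
}

.check_regions <- function(x, what = "regions") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  if (nrow(x) > 0 && any(x$end <= x$start))
    stop(what, ": all intervals must satisfy end > start (0-based half-open)")
  invisible(x)
}

#' Per-interval coverage by a second interval set
#'
#' For every interval in `a`, computes the number of base pairs covered by the
#' union of the intervals in `b` on the same chromosome, the covered fraction,
#' and an overlap flag. The flag is the rule used for "annotated by" calls,
#' e.g. a promoter counts as annotated by a chromatin state when the overlap
#' reaches `min_overlap_bp` (use 2 for the strict more-than-1-bp chromHMM
#' rule; 1 everywhere else).
#'
#' @param a,b region frames (`chrom`, `start`, `end`; 0-based half-open).
#' @param min_overlap_bp minimum covered bp for the overlap flag.
#' @return data.frame with columns `covered_bp`, `fraction`, `overlaps`,
#'   one row per row of `a`.
#' @export
overlap_fraction <- function(a, b, min_overlap_bp = 1) {
  .check_regions(a, "a"); .check_regions(b, "b")
  covered <- rep(0, nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    covered[ia] <- .iv_covered(a[ia, , drop = FALSE],
                               b[b$chrom == ch, , drop = FALSE])
  }
  len <- a$end - a$start
  data.frame(covered_bp = covered, fraction = covered / len,
             overlaps = covered >= min_overlap_bp)
}

#' Construct a feature track
#'
#' A feature track is a region frame tagged with a feature class
#' (TF binding sites, SNPs, m6A peaks, repeats, chromHMM states, RBP sites).
#' TF and chromHMM tracks must carry a non-empty `subtype` column (the TF
#' name / state name).
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `subtype`.
#' @param class_label one of `"TF"`, `"SNP"`, `"m6A"`, `"repeat"`,
#'   `"chromHMM"`, `"RBP"`.
#' @param layout optional [genome_layout()]; when given, intervals are
#'   checked against chromosome bounds.
#' @return the regions data.frame with class `feature_track` and a
#'   `feature_class` attribute.
#' @export
feature_track <- function(regions, class_label = c("TF", "SNP", "m6A",
                                                   "repeat", "chromHMM", "RBP"),
                          layout = NULL) {
  class_label <- match.arg(class_label)
  .check_regions(regions, "feature track")
  if (class_label %in% c("TF", "chromHMM")) {
    if (is.null(regions$subtype) || any(!nzchar(regions$subtype)))
      stop(class_label, " tracks require a non-empty subtype column")
  }
  if (!is.null(layout)) {
    lens <- stats::setNames(layout$length, layout$chrom)
    bad <- is.na(lens[regions$chrom]) | regions$start < 0 |
      regions$end > lens[regions$chrom]
    if (any(bad))
      stop(sum(bad), " feature interval(s) outside chromosome bounds")
  }
  structure(regions, class = c("feature_track", "data.frame"),
            feature_class = class_label)
}

#' Read a BED track with subtype labels
#'
#' Reads BED (>= 3 columns); column 4, when present, becomes the `subtype`
#' label (TF name, chromHMM state, ...).
#'
#' @inheritParams feature_track
#' @param path BED file.
#' @return a [feature_track()].
#' @export
read_bed_track <- function(path, class_label = "TF", layout = NULL) {
  g <- rtracklayer::import(path, format = "bed")
  regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                        start = BiocGenerics::start(g) - 1,
                        end = BiocGenerics::end(g))
  nm <- g$name
  if (!is.null(nm)) regions$subtype <- as.character(nm)
  feature_track(regions, class_label, layout)
}

#' Write regions as BED6
#'
#' @param regions region frame; optional `name`/`subtype` column used as the
#'   BED name field, optional `strand`.
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  .check_regions(regions)
  nm <- if (!is.null(regions$name)) regions$name
        else if (!is.null(regions$subtype)) regions$subtype else "."
  strand <- if (!is.null(regions$strand)) regions$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", regions$chrom,
                   as.integer(regions$start), as.integer(regions$end),
                   nm, strand)
  writeLines(lines, path)
  invisible(path)
}

# run code under a temporary, restored RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Sample random intergenic control windows
#'
#' Draws `n` non-overlapping windows of exact `length` bp from the intergenic
#' space of the genome — the complement of all annotated gene spans (first
#' exon start to last exon end, introns included). These serve as the
#' shuffled negative-control regions for promoter/regulatory comparisons.
#'
#' @param layout a [genome_layout()].
#' @param annotations an [annotation_set()]; all gene bodies are excluded.
#' @param length window length in bp (default 3000, the promoter-matched
#'   control length).
#' @param n number of windows.
#' @param seed optional integer for reproducible draws.
#' @return region frame with `chrom`, `start`, `end` and `name`.
#' @export
shuffle_intergenic <- function(layout, annotations, length = 3000, n, seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"), length > 0, n >= 1)
  # free space per chromosome = complement of gene spans
  gaps <- list()
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    spans <- gene_spans(annotations, chrom = ch)
    if (nrow(spans) > 0) {
      merged <- .iv_merge(cbind(spans$start, spans$end))
      gp <- .from_iranges(IRanges::gaps(.as_iranges(merged),
                                        start = 1, end = layout$length[i]))
    } else {
      gp <- cbind(start = 0, end = layout$length[i])
    }
    gp <- gp[gp[, 2] - gp[, 1] >= length, , drop = FALSE]
    if (nrow(gp) > 0)
      gaps[[ch]] <- gp
  }
  capacity <- sum(vapply(gaps, function(g)
    sum(floor((g[, 2] - g[, 1]) / length)), numeric(1)))
  if (capacity < n)
    stop("insufficient intergenic space: requested ", n, " windows of ",
         length, " bp but only ", capacity, " fit")
  .with_seed(seed, {
    # free-list sampling: pick a free piece weighted by how many start
    # positions it offers, place a window uniformly, split the remainder
    free <- do.call(rbind, lapply(names(gaps), function(ch)
      data.frame(chrom = ch, start = gaps[[ch]][, 1], end = gaps[[ch]][, 2])))
    out <- vector("list", n)
    for (k in seq_len(n)) {
      ok <- which(free$end - free$start >= length)
      if (length(ok) == 0)
        stop("insufficient intergenic space after placing ", k - 1,
             " of ", n, " windows (fragmentation)")
      w <- (free$end - free$start)[ok] - length + 1
      j <- ok[sample.int(length(ok), 1, prob = w)]
      s <- free$start[j] + sample.int(free$end[j] - free$start[j] - length + 1, 1) - 1
      out[[k]] <- data.frame(chrom = free$chrom[j], start = s, end = s + length)
      left <- data.frame(chrom = free$chrom[j], start = free$start[j], end = s)
      right <- data.frame(chrom = free$chrom[j], start = s + length, end = free$end[j])
      free <- rbind(free[-j, ], left, right)
      free <- free[free$end - free$start > 0, , drop = FALSE]
    }
    res <- do.call(rbind, out)
    res$name <- sprintf("shuffled_%d", seq_len(n))
    rownames(res) <- NULL
    res
  })
}
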