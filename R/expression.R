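# Count normalization (FPKM/CPM) and expression-specificity metrics: the
# tau index over tissues and developmental stages, expressed-proportion
# sweeps, and max-expression tissue calls. Counts are uniquely-mapped-read
# counts by contract; the matrix is the input boundary.

#' Expression tensor
#'
#' Raw counts (gene x sample) with sample metadata and merged exonic gene
#' lengths. Library size is the per-sample total of counted
#' (uniquely mapped, assigned) reads; when absent it falls back to the
#' column sum.
#'
#' @param counts non-negative integer matrix, rownames = gene ids.
#' @param meta data.frame with one row per column of `counts`; recognised
#'   columns: `sample_id`, `tissue`, `stage`, `time_days`, `sex`,
#'   `replicate`, `lib_size`, `cancer_type`, `tumor_normal`.
#' @param lengths named numeric vector of merged exonic lengths (bp);
#'   required for FPKM.
#' @return list of class `expression_tensor`.
#' @export
expression_tensor <- function(counts, meta, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (nrow(meta) != ncol(counts))
    stop("meta rows (", nrow(meta), ") != count columns (", ncol(counts), ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(meta$sample_id)) meta$sample_id <- colnames(counts)
  if (is.null(meta$lib_size) || anyNA(meta$lib_size))
    meta$lib_size <- colSums(counts)
  if (any(meta$lib_size <= 0)) stop("library sizes must be positive")
  if (!is.null(meta$time_days) && any(stats::na.omit(meta$time_days) <= 0))
    stop("developmental time must be positive (days after conception)")
  if (!is.null(lengths)) {
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing) > 0)
      stop("lengths missing for ", length(missing), " gene(s)")
    lengths <- lengths[rownames(counts)]
  }
  structure(list(counts = counts, meta = meta, lengths = lengths),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  cat("expression_tensor:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  if (!is.null(x$meta$tissue))
    cat("  tissues:", paste(unique(x$meta$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' Library-size normalization
#'
#' FPKM_gs = count_gs / (length_g / 1e3) / (libsize_s / 1e6);
#' CPM_gs = count_gs / (libsize_s / 1e6).
#'
#' @param tensor an [expression_tensor()].
#' @param mode `"FPKM"` or `"CPM"`.
#' @return numeric matrix, same shape as the counts.
#' @export
normalize_expression <- function(tensor, mode = c("FPKM", "CPM")) {
  mode <- match.arg(mode)
  lib <- tensor$meta$lib_size
  out <- sweep(tensor$counts, 2, lib / 1e6, "/")
  if (mode == "FPKM") {
    if (is.null(tensor$lengths)) stop("FPKM requires gene lengths")
    if (any(tensor$lengths <= 0)) stop("gene lengths must be positive")
    out <- sweep(out, 1, tensor$lengths / 1e3, "/")
  }
  out
}

#' tau expression-specificity index
#'
#' tau = sum_i (1 - y_i) / (n - 1) with y_i = x_i / max(x), over n >= 2
#' conditions; 0 means broad (uniform) expression, 1 means expression
#' confined to a single condition. An all-zero vector has no defined
#' specificity and returns `NA` with a warning.
#'
#' @param x non-negative expression vector over conditions.
#' @return tau in `[0, 1]`, or `NA` for all-zero input.
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least two conditions")
  if (any(x < 0)) stop("tau is defined for non-negative values")
  m <- max(x)
  if (m == 0) {
    warning("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / m) / (length(x) - 1)
}

# row-wise tau of a matrix (conditions in columns); silent NA for all-zero
.tau_rows <- function(m) {
  mx <- apply(m, 1, max)
  out <- rep(NA_real_, nrow(m))
  nz <- mx > 0
  out[nz] <- rowSums(1 - m[nz, , drop = FALSE] / mx[nz]) / (ncol(m) - 1)
  stats::setNames(out, rownames(m))
}

# per-condition aggregated expression: genes x levels(cond)
.aggregate_cols <- function(norm, cond, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  lev <- sort(unique(as.character(cond)))
  fun <- if (aggregate == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  out <- vapply(lev, function(l)
    fun(norm[, cond == l, drop = FALSE]), numeric(nrow(norm)))
  if (nrow(norm) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(norm), lev))
  out
}

#' Tissue and developmental-stage specificity scores
#'
#' Tissue tau is computed over per-tissue aggregated expression (replicates,
#' sexes and stages pooled; mean by default, median optional). Stage tau is
#' computed within each tissue over per-stage aggregates. Also reports each
#' gene's maximum-expression tissue (deterministic lexicographic tie-break,
#' flagged) and expressed flags at `expressed_cutoff`.
#'
#' @param norm normalized matrix (typically FPKM), genes x samples.
#' @param meta sample metadata with `tissue` and `stage` columns.
#' @param aggregate `"mean"` (default) or `"median"` per-condition summary.
#' @param expressed_cutoff normalized-expression cutoff for the expressed
#'   flag (default FPKM >= 1 in >= 1 sample).
#' @return list of class `specificity_scores`: `tissue_tau` (named vector),
#'   `stage_tau` (genes x tissues matrix), `max_tissue` (data.frame with
#'   tie flag), `expressed` (logical vector), `cutoff`.
#' @export
tissue_and_stage_specificity <- function(norm, meta,
                                         aggregate = c("mean", "median"),
                                         expressed_cutoff = 1) {
  aggregate <- match.arg(aggregate)
  tis <- as.character(meta$tissue)
  if (length(unique(tis)) < 2) stop("tissue tau needs >= 2 tissues")
  by_tissue <- .aggregate_cols(norm, tis, aggregate)
  tissue_tau <- .tau_rows(by_tissue)
  stage_tau <- NULL
  if (!is.null(meta$stage)) {
    tl <- colnames(by_tissue)
    stage_tau <- matrix(NA_real_, nrow(norm), length(tl),
                        dimnames = list(rownames(norm), tl))
    for (t in tl) {
      sel <- tis == t
      stg <- as.character(meta$stage[sel])
      if (length(unique(stg)) >= 2)
        stage_tau[, t] <- .tau_rows(
          .aggregate_cols(norm[, sel, drop = FALSE], stg, aggregate))
    }
  }
  structure(list(tissue_tau = tissue_tau, stage_tau = stage_tau,
                 max_tissue = max_expression_tissue(norm, meta, aggregate),
                 expressed = apply(norm, 1, max) >= expressed_cutoff,
                 cutoff = expressed_cutoff),
            class = "specificity_scores")
}

#' Proportion of expressed genes across cutoffs
#'
#' A gene counts as expressed at cutoff c when its maximum normalized value
#' over all samples is >= c. Proportions are reported per biotype and are
#' monotone non-increasing in the cutoff.
#'
#' @param norm normalized matrix, genes x samples.
#' @param cutoffs numeric vector of thresholds (>= 0).
#' @param biotypes named character vector assigning each gene a biotype;
#'   default one pooled class.
#' @return data.frame with `cutoff`, `biotype`, `n_genes`, `n_expressed`,
#'   `proportion`.
#' @export
expressed_proportion <- function(norm, cutoffs, biotypes = NULL) {
  stopifnot(all(cutoffs >= 0))
  if (is.null(biotypes))
    biotypes <- stats::setNames(rep("all", nrow(norm)), rownames(norm))
  biotypes <- biotypes[rownames(norm)]
  mx <- apply(norm, 1, max)
  out <- list()
  for (c in cutoffs) for (b in unique(biotypes)) {
    sel <- biotypes == b
    expressed <- if (c == 0) mx[sel] > 0 else mx[sel] >= c
    out[[length(out) + 1]] <- data.frame(
      cutoff = c, biotype = b, n_genes = sum(sel),
      n_expressed = sum(expressed), proportion = mean(expressed))
  }
  do.call(rbind, out)
}

#' Maximum-expression tissue per gene
#'
#' The tissue whose aggregated expression is maximal for the gene; exact
#' ties resolve to the lexicographically first tissue and are flagged.
#'
#' @inheritParams tissue_and_stage_specificity
#' @return data.frame with `gene_id`, `max_tissue`, `tie`.
#' @export
max_expression_tissue <- function(norm, meta, aggregate = c("mean", "median")) {
  by_tissue <- .aggregate_cols(norm, as.character(meta$tissue),
                               match.arg(aggregate))
  lev <- colnames(by_tissue)  # sorted, so which.max ties pick lexicographic first
  idx <- apply(by_tissue, 1, which.max)
  tie <- apply(by_tissue, 1, function(r) sum(r == max(r)) > 1)
  data.frame(gene_id = rownames(norm), max_tissue = lev[idx], tie = tie,
             row.names = NULL)
}

#' Read a counts matrix and sample metadata from TSV
#'
#' @param counts_path genes x samples TSV with gene ids in the first column.
#' @param meta_path sample metadata TSV (one row per sample, `sample_id`
#'   first).
#' @param lengths optional named gene-length vector.
#' @return an [expression_tensor()].
#' @export
read_expression <- function(counts_path, meta_path, lengths = NULL) {
  cts <- utils::read.delim(counts_path, row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(meta_path)
  meta <- meta[match(colnames(cts), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  expression_tensor(as.matrix(cts), meta, lengths)
}
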