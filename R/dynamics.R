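# Developmentally dynamic pseudogene (DDP) calling: per-tissue cubic OLS of
# expression on log time-after-conception, an R^2 > 0.3 rule, a parent-gene
# correlation exclusion, and the thresholded pseudogene-coding co-expression
# network. This reimplements the stated computation (polynomial-in-log-time
# OLS plus the R^2 threshold), not the full maSigPro stepwise-significance
# machinery.

#' Fit a polynomial-in-log-time trend for one gene in one tissue
#'
#' Ordinary least squares of the response on {1, ln t, (ln t)^2, ...,
#' (ln t)^degree}. The response is `log1p(CPM)` by default (stabilizes
#' negative-binomial variance) or raw CPM. R^2 = 1 - SS_res / SS_tot; a
#' constant response is defined to have R^2 = 0. Replicates enter as
#' separate observations at the same time value.
#'
#' @param values CPM values for the samples of one tissue.
#' @param times time after conception in days, one per value; all > 0.
#' @param degree polynomial degree (default 3).
#' @param response `"log1p"` (default) or `"raw"`.
#' @return list of class `trend_fit`: `coef`, `r2`, `n`, `degree`.
#' @export
fit_trend <- function(values, times, degree = 3,
                      response = c("log1p", "raw")) {
  response <- match.arg(response)
  if (length(values) != length(times)) stop("values/times length mismatch")
  if (any(times <= 0)) stop("times must be positive")
  if (length(unique(times)) < degree + 2)
    stop("degenerate design: need at least ", degree + 2,
         " distinct time points for degree ", degree)
  y <- if (response == "log1p") log1p(values) else values
  X <- stats::poly(log(times), degree = degree, raw = TRUE)
  fit <- stats::lm(y ~ X)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(coef = unname(stats::coef(fit)),
                 r2 = max(0, min(1, r2)), n = length(y), degree = degree),
            class = "trend_fit")
}

#' Fit trends for all genes across all tissues
#'
#' @param cpm CPM matrix, genes x samples.
#' @param meta sample metadata with `tissue` and `time_days`.
#' @inheritParams fit_trend
#' @return data.frame with `gene_id`, `tissue`, `r2`, `n`.
#' @export
fit_trends <- function(cpm, meta, degree = 3, response = c("log1p", "raw")) {
  response <- match.arg(response)
  out <- list()
  for (t in sort(unique(as.character(meta$tissue)))) {
    sel <- meta$tissue == t
    times <- meta$time_days[sel]
    if (length(unique(times)) < degree + 2)
      stop("degenerate design in tissue ", t, ": need at least ",
           degree + 2, " distinct time points")
    sub <- cpm[, sel, drop = FALSE]
    y <- if (response == "log1p") log1p(sub) else sub
    X <- cbind(1, stats::poly(log(times), degree = degree, raw = TRUE))
    # shared design: one QR for the whole tissue
    q <- qr(X)
    res <- t(y) - X %*% qr.coef(q, t(y))
    ss_res <- colSums(res^2)
    ss_tot <- colSums((t(y) - matrix(colMeans(t(y)), nrow(t(y)), ncol(t(y)),
                                     byrow = TRUE))^2)
    r2 <- ifelse(ss_tot == 0, 0, pmax(0, pmin(1, 1 - ss_res / ss_tot)))
    out[[t]] <- data.frame(gene_id = rownames(cpm), tissue = t,
                           r2 = unname(r2), n = sum(sel))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call developmentally dynamic pseudogenes
#'
#' A gene is dynamic in a tissue when its trend fit has R^2 strictly above
#' `threshold` (default 0.3); a gene dynamic in at least one tissue is a
#' DDP.
#'
#' @param fits data.frame from [fit_trends()].
#' @param threshold R^2 cutoff (strict >).
#' @return data.frame of class `ddp_calls`: one row per gene with
#'   per-tissue `r2_<tissue>` and `dynamic_<tissue>` columns, `ddp` flag,
#'   and placeholders `parent_r`, `excluded` updated by
#'   [parent_correlation_filter()]. Attribute `counts` holds per-tissue and
#'   overall DDP counts.
#' @export
call_ddps <- function(fits, threshold = 0.3) {
  tissues <- sort(unique(fits$tissue))
  genes <- unique(fits$gene_id)
  r2 <- matrix(NA_real_, length(genes), length(tissues),
               dimnames = list(genes, tissues))
  r2[cbind(match(fits$gene_id, genes), match(fits$tissue, tissues))] <- fits$r2
  dyn <- !is.na(r2) & r2 > threshold
  out <- data.frame(gene_id = genes, row.names = NULL)
  for (t in tissues) {
    out[[paste0("r2_", t)]] <- r2[, t]
    out[[paste0("dynamic_", t)]] <- dyn[, t]
  }
  out$ddp <- rowSums(dyn) > 0
  out$parent_r <- NA_real_
  out$excluded <- FALSE
  counts <- c(colSums(dyn), total_ddp = sum(out$ddp))
  structure(out, class = c("ddp_calls", "data.frame"),
            threshold = threshold, counts = counts)
}

#' Exclude DDPs that track their parent gene
#'
#' Pearson correlation between each pseudogene's and its parent coding
#' gene's expression across matched samples; a DDP with signed R >= `cutoff`
#' (default 0.6) is excluded from downstream functional sets as potentially
#' mis-mapped. A missing parent leaves R missing and the gene retained.
#'
#' @param calls a `ddp_calls` data.frame.
#' @param expr normalized expression matrix containing pseudogenes and
#'   parents (same sample columns).
#' @param parent_map named character vector: pseudogene id -> parent id.
#' @param cutoff signed correlation threshold (inclusive).
#' @return the updated `ddp_calls` with `parent_r` and `excluded` filled.
#' @export
parent_correlation_filter <- function(calls, expr, parent_map, cutoff = 0.6) {
  for (i in seq_len(nrow(calls))) {
    gid <- calls$gene_id[i]
    pid <- parent_map[gid]
    if (is.na(pid) || !(gid %in% rownames(expr)) || !(pid %in% rownames(expr)))
      next
    x <- expr[gid, ]; y <- expr[pid, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    calls$parent_r[i] <- r
    calls$excluded[i] <- calls$ddp[i] && r >= cutoff
  }
  calls
}

#' Pseudogene-coding co-expression network
#'
#' Scores every pseudogene x coding-gene pair by Pearson correlation across
#' samples (testis excluded by default for its disproportionate expression)
#' with a two-sided p-value from the exact t-transform
#' (t = R sqrt((n-2)/(1-R^2)), df = n - 2). An edge is kept when |R| >
#' `r_cut` and p < `p_cut`; no multiple-testing correction, matching the
#' raw-threshold rule.
#'
#' @param norm normalized matrix containing both gene groups.
#' @param meta sample metadata (needs `tissue` when `exclude_tissues` is
#'   non-empty).
#' @param pseudo_ids,coding_ids row names of the two groups.
#' @param r_cut absolute-correlation threshold (strict >).
#' @param p_cut p-value threshold (strict <).
#' @param exclude_tissues tissues whose samples are dropped before scoring.
#' @return data.frame of class `coexpression_edges`: `pseudogene`,
#'   `coding_gene`, `r`, `p`, `n`. Attributes: `connectivity` (edge count
#'   per gene), `skipped` (zero-variance genes with reason).
#' @export
coexpression_network <- function(norm, meta, pseudo_ids, coding_ids,
                                 r_cut = 0.90, p_cut = 0.01,
                                 exclude_tissues = "testis") {
  keep <- rep(TRUE, ncol(norm))
  if (length(exclude_tissues) > 0 && !is.null(meta$tissue))
    keep <- !(meta$tissue %in% exclude_tissues)
  m <- norm[, keep, drop = FALSE]
  n <- ncol(m)
  if (n < 4) stop("need >= 4 retained samples for the network")
  pv <- m[pseudo_ids, , drop = FALSE]
  cv <- m[coding_ids, , drop = FALSE]
  sd0_p <- pseudo_ids[apply(pv, 1, stats::sd) == 0]
  sd0_c <- coding_ids[apply(cv, 1, stats::sd) == 0]
  skipped <- rbind(
    if (length(sd0_p)) data.frame(gene_id = sd0_p, reason = "zero variance"),
    if (length(sd0_c)) data.frame(gene_id = sd0_c, reason = "zero variance"))
  pu <- setdiff(pseudo_ids, sd0_p); cu <- setdiff(coding_ids, sd0_c)
  r <- stats::cor(t(m[pu, , drop = FALSE]), t(m[cu, , drop = FALSE]))
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[abs(r) >= 1] <- 0
  hit <- which(abs(r) > r_cut & p < p_cut, arr.ind = TRUE)
  edges <- data.frame(pseudogene = pu[hit[, 1]], coding_gene = cu[hit[, 2]],
                      r = r[hit], p = p[hit], n = rep(n, nrow(hit)))
  edges <- edges[order(edges$pseudogene, edges$coding_gene), , drop = FALSE]
  rownames(edges) <- NULL
  conn <- c(table(factor(edges$pseudogene, levels = pseudo_ids)),
            table(factor(edges$coding_gene, levels = coding_ids)))
  structure(edges, class = c("coexpression_edges", "data.frame"),
            connectivity = conn, skipped = skipped)
}

#' Write DDP calls as TSV
#'
#' One row per gene: per-tissue R^2 and dynamic flags, overall DDP flag,
#' parent correlation, exclusion flag.
#'
#' @param calls a `ddp_calls` data.frame.
#' @param path output file.
#' @export
write_ddp_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
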