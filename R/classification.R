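# Chromosomal traffic enrichment (proportional null models + Fisher's exact
# test by hypergeometric tail summation), cancer-type-specificity labeling,
# cancer-type retention, and translated-candidate calling.

#' Expected pseudogene generation/insertion counts per chromosome
#'
#' Under the proportional null models each chromosome generates pseudogenes
#' in proportion to its protein-coding gene count and receives pseudogene
#' insertions in proportion to its length.
#'
#' @param coding_counts named protein-coding gene counts per chromosome.
#' @param chrom_lengths named chromosome lengths (bp), same chromosomes.
#' @param observed_generation observed pseudogene counts per chromosome by
#'   parent location.
#' @param observed_insertion observed pseudogene counts per chromosome by
#'   pseudogene location.
#' @return data.frame of class `traffic_table` with observed and expected
#'   generation/insertion counts per chromosome.
#' @export
traffic_expectation <- function(coding_counts, chrom_lengths,
                                observed_generation, observed_insertion) {
  chroms <- names(coding_counts)
  stopifnot(setequal(chroms, names(chrom_lengths)),
            setequal(chroms, names(observed_generation)),
            setequal(chroms, names(observed_insertion)))
  if (sum(coding_counts) <= 0 || sum(chrom_lengths) <= 0)
    stop("totals must be positive")
  total <- sum(observed_generation)
  if (total != sum(observed_insertion))
    stop("generation and insertion totals disagree")
  out <- data.frame(
    chrom = chroms,
    coding_genes = as.numeric(coding_counts[chroms]),
    length = as.numeric(chrom_lengths[chroms]),
    observed_generation = as.numeric(observed_generation[chroms]),
    observed_insertion = as.numeric(observed_insertion[chroms]),
    expected_generation = total * coding_counts[chroms] / sum(coding_counts),
    expected_insertion = total * chrom_lengths[chroms] / sum(chrom_lengths),
    row.names = NULL)
  structure(out, class = c("traffic_table", "data.frame"))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by hypergeometric tail summation: with margins fixed,
#' all tables whose conditional probability does not exceed the observed
#' table's (up to a 1e-7 relative tolerance for ties) are summed. The odds
#' ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric distribution. A zero margin leaves the odds
#' ratio undefined (p = 1).
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows: X / autosome; columns: pseudogene class / reference class).
#' @param odds_ratio set `FALSE` to skip the (iterative) conditional-MLE
#'   odds ratio when only the p-value is needed.
#' @return list of class `fisher_result`: `p_value`, `odds_ratio`,
#'   `or_defined`, `table`.
#' @export
traffic_test <- function(tab, odds_ratio = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0)
    return(structure(list(p_value = 1, odds_ratio = NA_real_,
                          or_defined = FALSE, table = tab),
                     class = "fisher_result"))
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  support <- lo:hi
  d <- stats::dhyper(support, r1, r2, c1)
  p <- sum(d[d <= d[support == a] * (1 + 1e-7)])
  structure(list(p_value = min(1, p),
                 odds_ratio = if (odds_ratio) .cond_mle_or(a, r1, r2, c1)
                              else NA_real_,
                 or_defined = TRUE, table = tab),
            class = "fisher_result")
}

# conditional MLE of the odds ratio: psi maximizing the noncentral
# hypergeometric likelihood, i.e. solving E_psi[A] = a
.cond_mle_or <- function(a, r1, r2, c1) {
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  support <- lo:hi
  logw0 <- stats::dhyper(support, r1, r2, c1, log = TRUE)
  mean_a <- function(logpsi) {
    lw <- logw0 + support * logpsi
    w <- exp(lw - max(lw))
    sum(support * w) / sum(w)
  }
  f <- function(logpsi) mean_a(logpsi) - a
  exp(stats::uniroot(f, c(-50, 50), tol = 1e-10)$root)
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (2x2)\n  p =", format(x$p_value, digits = 4),
      " odds ratio =", format(x$odds_ratio, digits = 4), "\n")
  invisible(x)
}

#' Per-type cancer expression shares
#'
#' For each gene, the per-type expression summary (mean over that type's
#' tumor samples by default) divided by the sum over all types. Shares sum
#' to 1 for genes with nonzero total expression.
#'
#' @param expr normalized expression matrix, genes x samples.
#' @param meta sample metadata with `cancer_type` and optionally
#'   `tumor_normal` (`"tumor"`/`"normal"`).
#' @param tumor_only use tumor samples only (default) when `tumor_normal`
#'   is available.
#' @return matrix genes x cancer types of shares (rows of all-zero genes
#'   are all zero).
#' @export
cancer_shares <- function(expr, meta, tumor_only = TRUE) {
  keep <- rep(TRUE, ncol(expr))
  if (tumor_only && !is.null(meta$tumor_normal))
    keep <- meta$tumor_normal == "tumor"
  m <- expr[, keep, drop = FALSE]
  types <- as.character(meta$cancer_type[keep])
  means <- .aggregate_cols(m, types, "mean")
  tot <- rowSums(means)
  shares <- means / ifelse(tot > 0, tot, 1)
  shares[tot == 0, ] <- 0
  shares
}

#' Classify cancer-type specificity from expression shares
#'
#' A gene is type-specific for type t when t's share exceeds
#' `specific_min` (strict >) and every other type's share is below
#' `other_max` (strict <). A gene is ubiquitous when its maximum share is
#' below `ubiquitous_max` (strict <) and each of its top-5 shares exceeds
#' `top5_min` (strict >). Everything else is `other`; all-zero genes are
#' `other` with a zero-expression flag.
#'
#' @param shares share matrix from [cancer_shares()] (rows sum to 1 or 0).
#' @param specific_min focal-type share threshold (default 0.15).
#' @param other_max other-type share bound for specific calls (default 0.05).
#' @param ubiquitous_max maximum-share bound for ubiquitous calls
#'   (default 0.30).
#' @param top5_min per-type share floor for the top 5 types (default 0.05).
#' @return data.frame with `gene_id`, `label`
#'   (`"type_specific"` / `"ubiquitous"` / `"other"`), `specific_type`,
#'   `zero_expression`.
#' @export
classify_cancer_specificity <- function(shares, specific_min = 0.15,
                                        other_max = 0.05,
                                        ubiquitous_max = 0.30,
                                        top5_min = 0.05) {
  if (ncol(shares) < 2) stop("need >= 2 cancer types")
  out <- data.frame(gene_id = rownames(shares), label = "other",
                    specific_type = NA_character_,
                    zero_expression = FALSE, row.names = NULL)
  for (i in seq_len(nrow(shares))) {
    s <- shares[i, ]
    if (all(s == 0)) { out$zero_expression[i] <- TRUE; next }
    top <- which.max(s)
    if (s[top] > specific_min && all(s[-top] < other_max)) {
      out$label[i] <- "type_specific"
      out$specific_type[i] <- colnames(shares)[top]
    } else {
      top5 <- sort(s, decreasing = TRUE)[seq_len(min(5, length(s)))]
      if (max(s) < ubiquitous_max && all(top5 > top5_min))
        out$label[i] <- "ubiquitous"
    }
  }
  out
}

#' Retain cancer types with enough tumor and normal samples
#'
#' A type is retained when it has more than `min_samples` normal AND more
#' than `min_samples` tumor samples (strict >, default 5), so that neither
#' class dominates differential analyses.
#'
#' @param type_counts data.frame with `cancer_type`, `n_normal`, `n_tumor`.
#' @param min_samples strict lower bound on both counts.
#' @return the input with a logical `retained` column.
#' @export
retain_cancer_types <- function(type_counts, min_samples = 5) {
  type_counts$retained <- type_counts$n_normal > min_samples &
    type_counts$n_tumor > min_samples
  type_counts
}

#' Call translated pseudogene candidates
#'
#' A pseudogene is a translated candidate when both sequence-based
#' coding-potential predictors flag it, its maximum ribosome-profiling FPKM
#' across samples is >= 1, and it harbors at least one active ORF.
#'
#' @param cpc_flag,cpat_flag logical coding-potential flags from the two
#'   external predictors (consumed as flags, not recomputed).
#' @param ribo_fpkm maximum FPKM over all Ribo-seq samples (>= 0).
#' @param orf_count number of active ORFs (integer >= 0).
#' @param gene_id optional ids.
#' @param fpkm_min inclusive FPKM threshold (default 1).
#' @return data.frame with the inputs and a `translated` flag.
#' @export
call_translated <- function(cpc_flag, cpat_flag, ribo_fpkm, orf_count,
                            gene_id = NULL, fpkm_min = 1) {
  stopifnot(all(ribo_fpkm >= 0), all(orf_count >= 0),
            all(orf_count == round(orf_count)))
  if (is.null(gene_id)) gene_id <- paste0("pg", seq_along(ribo_fpkm))
  data.frame(gene_id = gene_id, cpc_flag = cpc_flag, cpat_flag = cpat_flag,
             ribo_fpkm = ribo_fpkm, orf_count = orf_count,
             translated = cpc_flag & cpat_flag & ribo_fpkm >= fpkm_min &
               orf_count >= 1)
}
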