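# Synteny/parsimony dating of pseudogene origins. The phylogeny is a ladder
# of successive outgroups of the focal species; presence/absence of
# reciprocal-best alignment blocks over each exon places the exon's origin
# on a branch under a Dollo (single origin, multiple losses) rule, the gene
# takes its most ancient exon's branch, and the age is the branch midpoint
# in myr.

#' Branch table from a species divergence ladder
#'
#' Given outgroup species and their divergence times from the focal species
#' (TimeTree-style), builds the ordered branch table: consecutive divergence
#' times bound each branch, the oldest branch is capped at `root_cap`
#' (default 1.5 x the oldest divergence), and the youngest
#' (focal-lineage-specific) branch runs from the most recent split to the
#' present. Ages are branch midpoints.
#'
#' @param species character vector of outgroup species names.
#' @param divergence_myr divergence time of each species from the focal
#'   lineage, in myr; must be unique (a ladder of successive outgroups).
#' @param root_cap older bound of the oldest branch, myr.
#' @param focal_label label for the youngest branch.
#' @return data.frame of class `branch_table`, ordered old to young, with
#'   columns `branch_id`, `t_old`, `t_young`, `age_myr`; attribute
#'   `divergence` carries the species ladder.
#' @export
branch_table <- function(species, divergence_myr, root_cap = NULL,
                         focal_label = "focal_specific") {
  if (length(species) != length(divergence_myr) || length(species) < 1)
    stop("need matched species and divergence times")
  if (anyDuplicated(divergence_myr) || any(divergence_myr <= 0))
    stop("divergence times must be positive and unique (ladder phylogeny); ",
         "non-ladder trees are not supported")
  o <- order(divergence_myr, decreasing = TRUE)
  species <- as.character(species[o]); tdiv <- divergence_myr[o]
  if (is.null(root_cap)) root_cap <- 1.5 * max(tdiv)
  if (root_cap <= max(tdiv)) stop("root_cap must exceed the oldest divergence")
  t_old <- c(root_cap, tdiv)
  t_young <- c(tdiv, 0)
  branch_id <- c(paste0("pre_", species), focal_label)
  out <- data.frame(branch_id = branch_id, t_old = t_old, t_young = t_young,
                    age_myr = (t_old + t_young) / 2)
  structure(out, class = c("branch_table", "data.frame"),
            divergence = stats::setNames(tdiv, species))
}

#' Read a species divergence-time table
#'
#' TSV with columns `species` and `divergence_myr`.
#'
#' @param path file path.
#' @inheritParams branch_table
#' @return a [branch_table()].
#' @export
read_divergence_table <- function(path, root_cap = NULL) {
  d <- utils::read.delim(path)
  branch_table(d$species, d$divergence_myr, root_cap)
}

#' Read a per-species reciprocal-best alignment block map
#'
#' 8-column TSV: focal_chrom, focal_start, focal_end, target_chrom,
#' target_start, target_end, strand, reciprocal_best (0/1). Focal
#' coordinates are 0-based half-open. Reciprocal-best blocks of one species
#' must not overlap each other on the focal genome.
#'
#' @param path file path.
#' @param species target species name.
#' @param layout optional [genome_layout()] for bounds checking.
#' @return data.frame of class `orthology_map` with attribute `species`.
#' @export
read_orthology_map <- function(path, species, layout = NULL) {
  d <- utils::read.delim(path, header = TRUE)
  need <- c("focal_chrom", "focal_start", "focal_end", "target_chrom",
            "target_start", "target_end", "strand", "reciprocal_best")
  if (!all(need %in% names(d)))
    stop("orthology map ", path, " must have columns: ",
         paste(need, collapse = ", "))
  orthology_map(d, species, layout)
}

#' Construct an orthology map from a block data.frame
#'
#' @param blocks data.frame with the 8 block columns (see
#'   [read_orthology_map()]).
#' @inheritParams read_orthology_map
#' @return data.frame of class `orthology_map`.
#' @export
orthology_map <- function(blocks, species, layout = NULL) {
  blocks$reciprocal_best <- as.logical(blocks$reciprocal_best)
  if (!is.null(layout)) {
    lens <- stats::setNames(layout$length, layout$chrom)
    bad <- is.na(lens[blocks$focal_chrom]) | blocks$focal_start < 0 |
      blocks$focal_end > lens[blocks$focal_chrom]
    if (any(bad)) stop("orthology blocks outside focal genome bounds")
  }
  rb <- blocks[blocks$reciprocal_best, , drop = FALSE]
  for (ch in unique(rb$focal_chrom)) {
    x <- rb[rb$focal_chrom == ch, , drop = FALSE]
    x <- x[order(x$focal_start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$focal_start[-1] < x$focal_end[-nrow(x)]))
      stop("reciprocal-best blocks overlap on focal chromosome ", ch,
           " for species ", species)
  }
  structure(blocks, class = c("orthology_map", "data.frame"),
            species = species)
}

#' Ortholog presence of one exon in one species
#'
#' An exon counts as present in a species when the union of that species'
#' reciprocal-best blocks covers at least `min_cov` of the exon length.
#' Non-reciprocal blocks never contribute.
#'
#' @param exon length-2 numeric (start, end), 0-based half-open.
#' @param chrom focal chromosome of the exon.
#' @param map an [orthology_map()].
#' @param min_cov required covered fraction, in (0, 1].
#' @return list with `present` (logical) and `fraction`.
#' @export
exon_presence <- function(exon, chrom, map, min_cov = 0.5) {
  stopifnot(min_cov > 0, min_cov <= 1)
  b <- map[map$reciprocal_best & map$focal_chrom == chrom, , drop = FALSE]
  if (nrow(b) == 0) return(list(present = FALSE, fraction = 0))
  covered <- .iv_covered(matrix(exon, nrow = 1),
                         cbind(b$focal_start, b$focal_end))
  frac <- covered / (exon[2] - exon[1])
  list(present = frac >= min_cov, fraction = unname(frac))
}

#' Assign the origin branch of one exon from per-species presence
#'
#' Dollo single-origin parsimony: the exon arose once, on the branch just
#' older than the most distant species in which it is still found;
#' absences in younger species are losses or alignment failures. With no
#' presence anywhere the exon is focal-lineage specific (youngest branch).
#'
#' @param presence named logical vector, names = outgroup species known to
#'   the branch table.
#' @param branches a [branch_table()].
#' @return one row of the branch table (the assigned branch).
#' @export
assign_origin_branch <- function(presence, branches) {
  tdiv <- attr(branches, "divergence")
  unknown <- setdiff(names(presence), names(tdiv))
  if (length(unknown) > 0)
    stop("species not in branch table: ", paste(unknown, collapse = ", "))
  pres <- names(presence)[presence]
  if (length(pres) == 0) return(branches[nrow(branches), ])
  tstar <- max(tdiv[pres])
  branches[branches$t_young == tstar, ]
}

#' Partition pseudogenes by the dating filters
#'
#' Applies the two pre-dating exclusions: pseudogenes on the Y chromosome
#' (heavily invaded by transposable elements) and pseudogenes whose merged
#' exonic regions are more than 70% covered by repeats (strict >).
#'
#' @param annotations an [annotation_set()].
#' @param repeats repeat [feature_track()] (may have zero rows).
#' @param max_repeat_frac repeat-coverage fraction above which a pseudogene
#'   is excluded.
#' @return data.frame with `gene_id`, `biotype`, `status`
#'   (`pass` / `excluded_chrY` / `excluded_repeat` / `excluded_unmappable`)
#'   and `repeat_fraction`; attribute `retained` gives count and fraction
#'   retained.
#' @export
filter_for_dating <- function(annotations, repeats, max_repeat_frac = 0.70) {
  genes <- Filter(function(g) g$biotype %in% .PSEUDO_BIOTYPES,
                  annotations$genes)
  if (length(genes) == 0)
    return(structure(data.frame(gene_id = character(0), biotype = character(0),
                                status = character(0),
                                repeat_fraction = numeric(0)),
                     retained = c(n = 0, fraction = NA)))
  out <- do.call(rbind, lapply(genes, function(g) {
    if (!g$chrom %in% annotations$layout$chrom)
      return(data.frame(gene_id = g$gene_id, biotype = g$biotype,
                        status = "excluded_unmappable", repeat_fraction = NA))
    rp <- repeats[repeats$chrom == g$chrom, , drop = FALSE]
    merged <- .iv_merge(g$exons)
    cov <- sum(.iv_covered(merged, if (nrow(rp)) cbind(rp$start, rp$end)
                           else NULL))
    frac <- cov / .iv_union_length(g$exons)
    status <- if (.is_chrY(g$chrom)) "excluded_chrY"
              else if (frac > max_repeat_frac) "excluded_repeat"
              else "pass"
    data.frame(gene_id = g$gene_id, biotype = g$biotype, status = status,
               repeat_fraction = frac)
  }))
  rownames(out) <- NULL
  n_pass <- sum(out$status == "pass")
  structure(out, retained = c(n = n_pass, fraction = n_pass / nrow(out)))
}

#' Date pseudogenes from orthology evidence
#'
#' Runs the full dating pipeline: filter ([filter_for_dating()]), per-exon
#' per-species presence calls ([exon_presence()]), per-exon Dollo branch
#' assignment ([assign_origin_branch()]), then the gene takes the most
#' ancient exon's branch and the branch-midpoint age.
#'
#' @param annotations an [annotation_set()].
#' @param maps named list of [orthology_map()] objects (name = species).
#' @param branches a [branch_table()]; map species must all appear in it.
#' @param repeats repeat [feature_track()] for the filter step.
#' @param min_cov exon coverage threshold for a presence call.
#' @return data.frame of class `age_assignment` with one row per
#'   pseudogene: `gene_id`, `status`, `branch_id`, `t_old`, `t_young`,
#'   `age_myr`. Attribute `exon_branches` holds the per-exon table.
#' @export
date_pseudogenes <- function(annotations, maps, branches, repeats,
                             min_cov = 0.5) {
  tdiv <- attr(branches, "divergence")
  if (!all(names(maps) %in% names(tdiv)))
    stop("orthology maps for species missing from the branch table: ",
         paste(setdiff(names(maps), names(tdiv)), collapse = ", "))
  filt <- filter_for_dating(annotations, repeats)
  res <- filt[, c("gene_id", "status")]
  res$branch_id <- NA_character_
  res$t_old <- res$t_young <- res$age_myr <- NA_real_
  # index reciprocal-best blocks once per species x chromosome
  rb_index <- lapply(maps, function(m) {
    b <- m[m$reciprocal_best, , drop = FALSE]
    lapply(split(seq_len(nrow(b)), b$focal_chrom),
           function(ix) cbind(b$focal_start[ix], b$focal_end[ix]))
  })
  map_tdiv <- tdiv[names(maps)]
  ex_gene <- ex_num <- ex_branch <- list()
  for (i in which(res$status == "pass")) {
    g <- annotations$genes[[res$gene_id[i]]]
    ne <- nrow(g$exons)
    bidx <- integer(ne)
    for (e in seq_len(ne)) {
      exon <- g$exons[e, ]
      pres <- vapply(names(maps), function(sp) {
        blocks <- rb_index[[sp]][[g$chrom]]
        if (is.null(blocks)) return(FALSE)
        # blocks are validated non-overlapping, so clipped overlaps sum
        covered <- sum(pmax(0, pmin(blocks[, 2], exon[2]) -
                              pmax(blocks[, 1], exon[1])))
        covered / (exon[2] - exon[1]) >= min_cov
      }, logical(1))
      # Dollo: branch whose younger bound is the oldest presence
      bidx[e] <- if (!any(pres)) nrow(branches) else
        match(max(map_tdiv[pres]), branches$t_young)
    }
    ex_gene[[length(ex_gene) + 1]] <- rep(g$gene_id, ne)
    ex_num[[length(ex_num) + 1]] <- seq_len(ne)
    ex_branch[[length(ex_branch) + 1]] <- bidx
    best <- min(bidx)  # branches are ordered old to young
    res$status[i] <- "dated"
    res$branch_id[i] <- branches$branch_id[best]
    res$t_old[i] <- branches$t_old[best]
    res$t_young[i] <- branches$t_young[best]
    res$age_myr[i] <- branches$age_myr[best]
  }
  ebi <- unlist(ex_branch)
  exon_branches <- if (length(ebi) > 0)
    data.frame(gene_id = unlist(ex_gene), exon = unlist(ex_num),
               branch_id = branches$branch_id[ebi],
               t_old = branches$t_old[ebi])
  else NULL
  structure(res, class = c("age_assignment", "data.frame"),
            exon_branches = exon_branches,
            branches = branches, retained = attr(filt, "retained"))
}

#' Branch-count and chromosome-class age distributions
#'
#' Per-branch counts of dated pseudogenes and, per chromosome class
#' (X / autosome / other), the proportion of that class's pseudogenes
#' originating on each branch (each class's proportions sum to 1).
#'
#' @param assignments an `age_assignment` from [date_pseudogenes()].
#' @param annotations the [annotation_set()] the assignments came from.
#' @return list with `counts` (named per branch) and `proportions`
#'   (matrix branch x chromosome class).
#' @export
age_distribution <- function(assignments, annotations) {
  dated <- assignments[assignments$status == "dated", , drop = FALSE]
  if (nrow(dated) == 0) stop("no dated pseudogenes")
  branches <- attr(assignments, "branches")
  lev <- branches$branch_id
  counts <- table(factor(dated$branch_id, levels = lev))
  chrom <- vapply(annotations$genes[dated$gene_id], `[[`, character(1), "chrom")
  cls <- ifelse(.is_chrX(chrom), "X",
                ifelse(.is_chrY(chrom), "other", "autosome"))
  tab <- table(factor(dated$branch_id, levels = lev), cls)
  prop <- sweep(tab, 2, colSums(tab), "/")
  list(counts = counts, proportions = prop)
}

#' Write an age assignment table as TSV
#'
#' @param assignments an `age_assignment`.
#' @param path output file.
#' @export
write_age_assignment <- function(assignments, path) {
  utils::write.table(as.data.frame(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
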