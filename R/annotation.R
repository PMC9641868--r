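# Core annotation data model: genome layout, gene records, annotation sets,
# GFF3/BED12 reading, TSS/promoter derivation. Coordinates are 0-based
# half-open internally; GFF3 (1-based closed) is converted on read/write.

.BIOTYPES <- c("protein_coding", "processed_pseudogene",
               "unprocessed_pseudogene", "unitary_pseudogene",
               "polymorphic_pseudogene", "lncRNA")

.PSEUDO_BIOTYPES <- setdiff(.BIOTYPES, c("protein_coding", "lncRNA"))

#' Genome layout
#'
#' Chromosome names, lengths, and a sex-chromosome flag (X and Y). The Y flag
#' drives the chrY exclusion filter of the dating pipeline; the X flag drives
#' X-versus-autosome traffic summaries.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length chromosome lengths in bp, all positive.
#' @param sex_chroms names regarded as sex chromosomes.
#' @return data.frame with class `genome_layout` and columns `chrom`,
#'   `length`, `is_sex`.
#' @export
genome_layout <- function(chrom, length,
                          sex_chroms = c("X", "Y", "chrX", "chrY")) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length = as.numeric(length),
                       is_sex = chrom %in% sex_chroms),
            class = c("genome_layout", "data.frame"))
}

#' Read a UCSC chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @inheritParams genome_layout
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path, sex_chroms = c("X", "Y", "chrX", "chrY")) {
  d <- utils::read.delim(path, header = FALSE, col.names = c("chrom", "length"))
  genome_layout(d$chrom, d$length, sex_chroms)
}

.is_chrY <- function(chrom) chrom %in% c("Y", "chrY")
.is_chrX <- function(chrom) chrom %in% c("X", "chrX")

#' Gene record
#'
#' One gene or pseudogene: id, biotype, chromosome, strand, exons and, for
#' pseudogenes, an optional parent coding-gene id. Exons are 0-based
#' half-open intervals on the record's chromosome; they are sorted on
#' construction and must be non-overlapping once merged.
#'
#' @param gene_id unique identifier.
#' @param biotype one of `protein_coding`, `processed_pseudogene`,
#'   `unprocessed_pseudogene`, `unitary_pseudogene`,
#'   `polymorphic_pseudogene`, `lncRNA`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals.
#' @param parent_id parent coding gene id (pseudogenes only) or `NA`.
#' @return list of class `gene_record`.
#' @export
gene_record <- function(gene_id, biotype, chrom, strand, exons, parent_id = NA) {
  if (!biotype %in% .BIOTYPES)
    stop("unknown biotype '", biotype, "' for gene ", gene_id)
  if (!strand %in% c("+", "-")) stop("strand must be + or - for gene ", gene_id)
  exons <- .iv(exons[, 1], exons[, 2])
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (biotype == "protein_coding" && !is.na(parent_id))
    stop("protein-coding gene ", gene_id, " cannot carry a parent id")
  structure(list(gene_id = as.character(gene_id), biotype = biotype,
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, parent_id = parent_id),
            class = "gene_record")
}

#' Annotation set
#'
#' A genome layout plus a collection of gene records. Validates unique ids,
#' exon bounds against the layout, and parent-link resolution: every parent
#' id must point to a protein-coding record, otherwise the link is flagged
#' unresolved (kept, with a warning).
#'
#' @param layout a [genome_layout()].
#' @param genes list of [gene_record()] objects.
#' @return list of class `annotation_set` with elements `layout`, `genes`
#'   (named by gene id) and attribute `unresolved_parents`.
#' @export
annotation_set <- function(layout, genes) {
  stopifnot(inherits(layout, "genome_layout"))
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- stats::setNames(layout$length, layout$chrom)
  for (g in genes) {
    if (is.na(lens[g$chrom]))
      stop("gene ", g$gene_id, " on unknown chromosome ", g$chrom)
    if (any(g$exons[, 1] < 0) || any(g$exons[, 2] > lens[g$chrom]))
      stop("gene ", g$gene_id, ": exon outside chromosome bounds")
  }
  names(genes) <- ids
  biotype <- vapply(genes, function(g) g$biotype, character(1))
  parent <- vapply(genes, function(g) as.character(g$parent_id), character(1))
  has_par <- !is.na(parent)
  unresolved <- ids[has_par &
    !(parent %in% ids[biotype == "protein_coding"])]
  if (length(unresolved) > 0)
    warning(length(unresolved), " parent link(s) do not resolve to a ",
            "protein-coding gene; flagged unresolved")
  structure(list(layout = layout, genes = genes),
            class = "annotation_set", unresolved_parents = unresolved)
}

#' @export
print.annotation_set <- function(x, ...) {
  bt <- table(vapply(x$genes, function(g) g$biotype, character(1)))
  cat("annotation_set:", length(x$genes), "genes on",
      nrow(x$layout), "chromosomes\n")
  for (b in names(bt)) cat("  ", b, ": ", bt[[b]], "\n", sep = "")
  invisible(x)
}

#' Gene-level summary table of an annotation set
#'
#' @param x an [annotation_set()].
#' @param ... unused.
#' @return data.frame with one row per gene: id, biotype, chromosome,
#'   strand, span, exon count, merged exonic length, parent id.
#' @export
as.data.frame.annotation_set <- function(x, ...) {
  rows <- lapply(x$genes, function(g) data.frame(
    gene_id = g$gene_id, biotype = g$biotype, chrom = g$chrom,
    strand = g$strand, start = min(g$exons[, 1]), end = max(g$exons[, 2]),
    n_exons = nrow(g$exons), exonic_length = merged_exonic_length(g),
    parent_id = as.character(g$parent_id)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# gene spans (first exon start to last exon end) as a region frame
gene_spans <- function(set, chrom = NULL) {
  genes <- set$genes
  if (!is.null(chrom)) genes <- Filter(function(g) g$chrom == chrom, genes)
  if (length(genes) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0)))
  data.frame(chrom = vapply(genes, `[[`, character(1), "chrom"),
             start = vapply(genes, function(g) min(g$exons[, 1]), numeric(1)),
             end = vapply(genes, function(g) max(g$exons[, 2]), numeric(1)),
             gene_id = vapply(genes, `[[`, character(1), "gene_id"),
             row.names = NULL)
}

#' Merged exonic length
#'
#' Length of the non-redundant union of a gene's exon intervals, the length
#' measure used for pseudogenes and their parent genes throughout (FPKM
#' lengths, repeat-coverage fractions, SNP densities).
#'
#' @param gene a [gene_record()].
#' @return length in bp.
#' @export
merged_exonic_length <- function(gene) {
  .iv_union_length(gene$exons)
}

#' Transcription start site of a gene
#'
#' The TSS is the starting coordinate of the first exon. In the default
#' `stranded` mode "first" is read in transcript orientation: the smallest
#' exon start on the plus strand, the largest exon end on the minus strand.
#' `naive_start` ignores strand and always returns the smallest exon start.
#'
#' @param gene a [gene_record()].
#' @param tss_mode `"stranded"` (default) or `"naive_start"`.
#' @return genomic position (0-based).
#' @export
derive_tss <- function(gene, tss_mode = c("stranded", "naive_start")) {
  tss_mode <- match.arg(tss_mode)
  if (tss_mode == "naive_start" || gene$strand == "+")
    min(gene$exons[, 1])
  else
    max(gene$exons[, 2])
}

#' Promoter window of a gene
#'
#' The region from `upstream` bp upstream to `downstream` bp downstream of
#' the TSS (default 2 kb / 1 kb, a 3000-bp window), oriented by strand and
#' clipped to chromosome bounds. The window always contains the TSS.
#'
#' @inheritParams derive_tss
#' @param layout a [genome_layout()] for bounds clipping.
#' @param upstream,downstream window extent in bp.
#' @return one-row region frame (`chrom`, `start`, `end`, `gene_id`).
#' @export
derive_promoter <- function(gene, layout, upstream = 2000, downstream = 1000,
                            tss_mode = c("stranded", "naive_start")) {
  tss_mode <- match.arg(tss_mode)
  tss <- derive_tss(gene, tss_mode)
  strand <- if (tss_mode == "naive_start") "+" else gene$strand
  if (strand == "+") {
    s <- tss - upstream; e <- tss + downstream
  } else {
    s <- tss - downstream; e <- tss + upstream
  }
  len <- layout$length[match(gene$chrom, layout$chrom)]
  data.frame(chrom = gene$chrom, start = max(0, s), end = min(len, e),
             gene_id = gene$gene_id)
}

#' Promoters for all (or selected) genes of a set
#'
#' @param set an [annotation_set()].
#' @param gene_ids subset of gene ids (default all).
#' @inheritParams derive_promoter
#' @return region frame with one row per gene.
#' @export
promoters_of <- function(set, gene_ids = NULL, upstream = 2000,
                         downstream = 1000,
                         tss_mode = c("stranded", "naive_start")) {
  tss_mode <- match.arg(tss_mode)
  genes <- if (is.null(gene_ids)) set$genes else set$genes[gene_ids]
  out <- do.call(rbind, lapply(genes, derive_promoter, layout = set$layout,
                               upstream = upstream, downstream = downstream,
                               tss_mode = tss_mode))
  rownames(out) <- NULL
  out
}

# --- reading / writing -----------------------------------------------------

.scan_delim_fields <- function(path, n_fields, comment = "#") {
  lines <- readLines(path)
  keep <- !startsWith(lines, comment) & nzchar(trimws(lines))
  bad <- which(keep & lengths(strsplit(lines, "\t", fixed = TRUE)) < n_fields)
  if (length(bad) > 0)
    stop("malformed line ", bad[1], " in ", path, ": expected ",
         n_fields, " tab-separated fields")
  sum(keep)
}

.map_biotype <- function(raw, where) {
  bt <- ifelse(raw %in% .BIOTYPES, raw, NA)
  if (anyNA(bt)) {
    bad <- unique(raw[is.na(bt)])
    stop("unknown biotype(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  bt
}

#' Read gene annotations from GFF3 or BED12
#'
#' GFF3 input must carry gene-level features (any type) with `ID` and a
#' biotype attribute (`biotype`, `gene_type` or `gene_biotype`), plus `exon`
#' features linked by `Parent`; an optional `parent_gene` attribute records
#' the pseudogene's parent coding gene. GFF3 coordinates (1-based closed)
#' are converted to the internal 0-based half-open convention. BED12 input
#' encodes exons as blocks and the name field as
#' `gene_id|biotype[|parent_id]`.
#'
#' @param path annotation file.
#' @param layout a [genome_layout()].
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return an [annotation_set()]. An empty file yields an empty set with a
#'   warning.
#' @export
read_annotation <- function(path, layout, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  n <- .scan_delim_fields(path, if (format == "gff3") 9 else 12)
  if (n == 0) {
    warning("empty annotation file: ", path)
    return(annotation_set(layout, list()))
  }
  if (format == "gff3") .read_gff3(path, layout) else .read_bed12(path, layout)
}

.read_gff3 <- function(path, layout) {
  g <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(g)
  bt_col <- intersect(c("biotype", "gene_type", "gene_biotype"), names(meta))
  is_exon <- as.character(meta$type) == "exon"
  is_gene <- !is_exon & !is.na(meta$ID)
  if (length(bt_col) == 0) stop("no biotype attribute found in ", path)
  raw_bt <- as.character(meta[[bt_col[1]]][is_gene])
  bt <- .map_biotype(raw_bt, path)
  gid <- as.character(meta$ID[is_gene])
  strand <- as.character(BiocGenerics::strand(g))[is_gene]
  chrom <- as.character(GenomicRanges::seqnames(g))[is_gene]
  parent <- if ("parent_gene" %in% names(meta))
    as.character(meta$parent_gene[is_gene]) else rep(NA_character_, sum(is_gene))
  # exon features grouped by Parent
  epar <- as.character(sapply(meta$Parent[is_exon], function(p)
    if (length(p)) p[[1]] else NA_character_))
  es <- BiocGenerics::start(g)[is_exon] - 1
  ee <- BiocGenerics::end(g)[is_exon]
  genes <- lapply(seq_along(gid), function(i) {
    sel <- which(epar == gid[i])
    if (length(sel) == 0)
      stop("gene ", gid[i], " has no exon features in ", path)
    gene_record(gid[i], bt[i], chrom[i], strand[i],
                cbind(es[sel], ee[sel]), parent[i])
  })
  annotation_set(layout, genes)
}

.read_bed12 <- function(path, layout) {
  g <- rtracklayer::import(path, format = "bed")
  if (is.null(g$blocks)) stop("BED input lacks block structure (need BED12)")
  bl <- rtracklayer::blocks(g)
  nm <- strsplit(as.character(g$name), "|", fixed = TRUE)
  if (any(lengths(nm) < 2))
    stop("BED12 name field must be gene_id|biotype[|parent_id] in ", path)
  genes <- lapply(seq_along(g), function(i) {
    ex <- bl[[i]]
    gene_record(nm[[i]][1], .map_biotype(nm[[i]][2], path),
                as.character(GenomicRanges::seqnames(g))[i],
                as.character(BiocGenerics::strand(g))[i],
                cbind(BiocGenerics::start(ex) - 1, BiocGenerics::end(ex)),
                if (length(nm[[i]]) >= 3 && nzchar(nm[[i]][3])) nm[[i]][3] else NA)
  })
  annotation_set(layout, genes)
}

#' Write an annotation set as GFF3
#'
#' Emits one gene feature per record (attributes `ID`, `biotype`,
#' `parent_gene`) plus its exon features; coordinates converted back to
#' 1-based closed. [read_annotation()] on the output reproduces coordinates
#' and biotypes exactly.
#'
#' @param set an [annotation_set()].
#' @param path output file.
#' @export
write_annotation <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in set$genes) {
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    attr_gene <- sprintf("ID=%s;biotype=%s%s", g$gene_id, g$biotype,
                         if (!is.na(g$parent_id))
                           sprintf(";parent_gene=%s", g$parent_id) else "")
    writeLines(sprintf("%s\tpsgtools\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, span[1] + 1L, span[2], g$strand, attr_gene), con)
    writeLines(sprintf("%s\tpsgtools\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       g$chrom, g$exons[, 1] + 1L, g$exons[, 2],
                       g$strand, g$gene_id), con)
  }
  invisible(path)
}
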