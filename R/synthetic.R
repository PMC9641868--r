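# Seeded synthetic-data generator. Emits every input the pipeline consumes
# (annotations, repeat track, per-species orthology maps, developmental
# count matrices, feature tracks, cancer matrices) together with the
# planted ground truth, so each stage can be validated end to end without
# external downloads. Counts and coordinates only; no sequence simulation.

#' Scenario configuration with field-realistic defaults
#'
#' The default scenario emulates the shape of the real inputs at desk
#' scale: an 8-outgroup ladder spanning ~6-435 myr, a small genome
#' (4 autosomes + X + Y), 500 pseudogenes / 200 coding genes, a
#' developmental design of 5 tissues x 8 stages x 2 sexes x 2 replicates
#' with negative-binomial counts (variance mu + alpha mu^2, alpha = 0.1),
#' planted cubic-in-log-time trends, planted tissue-specific and
#' testis-enriched genes, feature tracks with planted promoter enrichment,
#' and a 33-type cancer matrix with planted type-specific and ubiquitous
#' genes.
#'
#' @param ... overrides for any default field (see the returned list).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    # dated ladder of successive outgroups (divergence myr from the focal species)
    species = c(chimpanzee = 6, macaque = 29, marmoset = 43, mouse = 90,
                opossum = 160, platypus = 180, chicken = 320, zebrafish = 435),
    root_cap = NULL,                      # default 1.5 x oldest divergence
    chrom_lengths = c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6, chr4 = 3e6,
                      chrX = 2e6, chrY = 1e6),
    n_pseudogenes = 500,
    n_coding = 200,
    branch_weights = NULL,                # default uniform over branches
    biotype_mix = c(processed_pseudogene = 0.72,
                    unprocessed_pseudogene = 0.23,
                    unitary_pseudogene = 0.03,
                    polymorphic_pseudogene = 0.02),
    frac_chrY = 0.02,                     # pseudogenes planted on chrY
    frac_high_repeat = 0.05,              # planted repeat coverage > 0.70
    planted_repeat_cov = 0.80,
    dropout = 0,                          # per-species per-exon presence dropout
    decoy_rate = 0.05,                    # non-reciprocal decoy block rate
    # expression plan
    tissues = c("brain", "cerebellum", "heart", "liver", "testis"),
    stage_times = round(exp(seq(log(10), log(500), length.out = 8))),
    n_replicates = 2,
    sexes = c("female", "male"),
    nb_dispersion = 0.1,
    base_log_mean = 4, base_log_sd = 1,
    frac_dynamic = 0.3,
    trend_amplitude = 2.0,                # planted log-scale dynamic range
    dynamic_min_log_mean = 3,             # planted trends sit on expressed genes
    frac_tissue_specific = 0.2,
    off_tissue_factor = 0.02,
    testis_factor = 5, testis_frac = 0.25,
    # feature-track plan
    n_tf = 50, tf_site_density = 1 / 2000, tf_site_len = c(10, 20),
    ddp_tf_enrichment = 2,
    snp_density_per_kb = 0.05, promoter_snp_factor = 3,
    m6a_density = 1 / 5000, m6a_site_len = 50,
    n_chromhmm_states = 15, chromhmm_mean_len = 1000,
    n_rbp = 30, n_rbp_sites = 2000, rbp_site_len = c(20, 40),
    # cancer plan
    n_cancer_types = 33,
    n_cancer_specific = 20, n_cancer_ubiquitous = 20, n_cancer_other = 210,
    cancer_tumor_range = c(3, 20), cancer_normal_range = c(2, 12),
    cancer_noise = c("nb", "none")[1],
    cancer_base_mean = 400)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  .validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

.validate_scenario <- function(cfg) {
  probs <- c(cfg$frac_chrY, cfg$frac_high_repeat, cfg$dropout,
             cfg$frac_dynamic, cfg$frac_tissue_specific, cfg$testis_frac,
             cfg$decoy_rate)
  if (any(probs < 0 | probs > 1))
    stop("scenario probabilities/fractions must lie in [0, 1]")
  if (any(cfg$stage_times <= 0)) stop("stage times must be positive")
  if (abs(sum(cfg$biotype_mix) - 1) > 1e-8)
    stop("biotype mix must sum to 1")
  if (cfg$n_cancer_types < 2) stop("need >= 2 cancer types")
  invisible(cfg)
}

# place n genes with given exon plans on a chromosome, starting after `from`
.place_genes <- function(n_exons_list, exon_len_range, intron_range,
                         gap_range, chrom_len, from = 0) {
  out <- list(); cursor <- from
  for (i in seq_along(n_exons_list)) {
    cursor <- cursor + round(stats::runif(1, gap_range[1], gap_range[2]))
    ne <- n_exons_list[[i]]
    starts <- ends <- numeric(ne)
    pos <- cursor
    for (e in seq_len(ne)) {
      len <- round(stats::runif(1, exon_len_range[1], exon_len_range[2]))
      starts[e] <- pos; ends[e] <- pos + len
      pos <- ends[e] + if (e < ne)
        round(stats::runif(1, intron_range[1], intron_range[2])) else 0
    }
    if (pos > chrom_len) return(NULL)  # out of space
    out[[i]] <- cbind(starts, ends)
    cursor <- pos
  }
  out
}

#' Generate a full synthetic scenario
#'
#' Draws every pipeline input under `config` and writes them to `out_dir`
#' as plain-text files (GFF3 annotation, BED tracks, TSV maps and
#' matrices), together with ground-truth TSVs and a manifest. The run is
#' fully determined by `seed`: the same seed yields byte-identical files.
#'
#' A pseudogene planted on branch b has reciprocal-best blocks over each
#' exon in exactly the species that diverged after b's older bound, minus
#' independent per-species per-exon dropout; dropout removes evidence but
#' never adds it. Dynamic genes have per-tissue negative-binomial means
#' exp(a + sum_k beta_k (ln t)^k), k <= 3, scaled to the configured
#' log-range amplitude.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return list of class `scenario`: in-memory inputs (`layout`,
#'   `annotations`, `repeats`, `maps`, `branches`, `tensor`, `tracks`,
#'   `cancer`), the `truth` tables, the `files` written, and the `config`.
#' @export
generate_scenario <- function(config = scenario_config(), out_dir, seed) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(seed, .generate_scenario_impl(config, out_dir))
}

.generate_scenario_impl <- function(cfg, out_dir) {
  layout <- genome_layout(names(cfg$chrom_lengths), cfg$chrom_lengths)
  branches <- branch_table(names(cfg$species), cfg$species, cfg$root_cap)
  files <- list()

  ## --- gene placement -----------------------------------------------------
  npg <- cfg$n_pseudogenes; ncg <- cfg$n_coding
  pg_ids <- sprintf("PG%04d", seq_len(npg))
  cg_ids <- sprintf("CG%04d", seq_len(ncg))
  pg_biotype <- sample(names(cfg$biotype_mix), npg, replace = TRUE,
                       prob = cfg$biotype_mix)
  pg_exon_n <- ifelse(pg_biotype == "processed_pseudogene", 1L,
                      sample(2:5, npg, replace = TRUE))
  cg_exon_n <- sample(4:8, ncg, replace = TRUE)
  # chromosome assignment: planted chrY subset, the rest by length
  autox <- setdiff(layout$chrom, "chrY")
  wl <- cfg$chrom_lengths[autox] / sum(cfg$chrom_lengths[autox])
  pg_chrom <- sample(autox, npg, replace = TRUE, prob = wl)
  on_y <- seq_len(npg) %in% sample.int(npg, round(cfg$frac_chrY * npg))
  pg_chrom[on_y] <- "chrY"
  cg_chrom <- sample(autox, ncg, replace = TRUE, prob = wl)
  # per-chromosome sequential placement (interleave coding and pseudo)
  all_ids <- c(pg_ids, cg_ids)
  all_chrom <- c(pg_chrom, cg_chrom)
  all_ne <- c(pg_exon_n, cg_exon_n)
  exons <- vector("list", length(all_ids)); names(exons) <- all_ids
  for (ch in unique(all_chrom)) {
    idx <- which(all_chrom == ch)
    placed <- .place_genes(as.list(all_ne[idx]), c(150, 400), c(200, 2000),
                           c(1000, 4000), cfg$chrom_lengths[[ch]])
    if (is.null(placed))
      stop("chromosome ", ch, " too short for the configured gene plan")
    exons[idx] <- placed
  }
  pg_parent <- ifelse(pg_biotype %in% c("processed_pseudogene",
                                        "unprocessed_pseudogene"),
                      sample(cg_ids, npg, replace = TRUE), NA)
  pg_strand <- sample(c("+", "-"), npg, replace = TRUE)
  cg_strand <- sample(c("+", "-"), ncg, replace = TRUE)
  genes <- c(
    lapply(seq_len(npg), function(i)
      gene_record(pg_ids[i], pg_biotype[i], pg_chrom[i], pg_strand[i],
                  exons[[pg_ids[i]]], pg_parent[i])),
    lapply(seq_len(ncg), function(i)
      gene_record(cg_ids[i], "protein_coding", cg_chrom[i], cg_strand[i],
                  exons[[cg_ids[i]]])))
  annotations <- annotation_set(layout, genes)
  files$annotation <- file.path(out_dir, "annotation.gff3")
  write_annotation(annotations, files$annotation)
  files$chrom_sizes <- file.path(out_dir, "genome.chrom.sizes")
  writeLines(sprintf("%s\t%d", layout$chrom, as.integer(layout$length)),
             files$chrom_sizes)

  ## --- planted origins and repeat track -----------------------------------
  bw <- cfg$branch_weights
  if (is.null(bw)) bw <- rep(1, nrow(branches))
  pg_branch <- sample(branches$branch_id, npg, replace = TRUE, prob = bw)
  hi_rep <- seq_len(npg) %in% sample.int(npg, round(cfg$frac_high_repeat * npg))
  rep_rows <- list()
  for (i in which(hi_rep)) {
    ex <- exons[[pg_ids[i]]]
    for (e in seq_len(nrow(ex))) {
      len <- ceiling(cfg$planted_repeat_cov * (ex[e, 2] - ex[e, 1]))
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        chrom = pg_chrom[i], start = ex[e, 1], end = ex[e, 1] + len,
        subtype = "planted_repeat")
    }
  }
  # background repeats confined to intergenic space
  bg_rep <- shuffle_intergenic(layout, annotations, length = 300,
                               n = 100, seed = NULL)
  rep_rows[[length(rep_rows) + 1]] <-
    data.frame(chrom = bg_rep$chrom, start = bg_rep$start, end = bg_rep$end,
               subtype = "background_repeat")
  repeats <- feature_track(do.call(rbind, rep_rows), "repeat", layout)
  files$repeats <- file.path(out_dir, "repeats.bed")
  write_bed(repeats, files$repeats)

  ## --- orthology maps ------------------------------------------------------
  tdiv <- attr(branches, "divergence")
  t_young <- stats::setNames(branches$t_young, branches$branch_id)
  # one row per pseudogene exon, in gene order
  ex_tab <- do.call(rbind, lapply(seq_len(npg), function(i) {
    ex <- exons[[pg_ids[i]]]
    data.frame(gene = i, chrom = pg_chrom[i], start = ex[, 1], end = ex[, 2])
  }))
  maps <- list()
  for (sp in names(tdiv)) {
    present_sp <- tdiv[sp] <= t_young[pg_branch[ex_tab$gene]]
    u <- stats::runif(nrow(ex_tab))
    keep <- present_sp & u >= cfg$dropout
    # paralogous noise: non-reciprocal hits that must be ignored
    decoy <- !present_sp & u < cfg$decoy_rate
    sel <- keep | decoy
    w <- ex_tab$end[sel] - ex_tab$start[sel]
    toff <- c(0, cumsum(w + 100))[seq_along(w)]
    blocks <- data.frame(
      focal_chrom = ex_tab$chrom[sel], focal_start = ex_tab$start[sel],
      focal_end = ex_tab$end[sel],
      target_chrom = ifelse(keep[sel], "scaf1", "scaf9"),
      target_start = toff, target_end = toff + w,
      strand = ifelse(keep[sel], "+", "-"),
      reciprocal_best = as.integer(keep[sel]))
    maps[[sp]] <- orthology_map(blocks, sp, layout)
    files[[paste0("ortho_", sp)]] <-
      file.path(out_dir, sprintf("ortho_%s.tsv", sp))
    utils::write.table(blocks, files[[paste0("ortho_", sp)]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  files$divergence <- file.path(out_dir, "divergence.tsv")
  utils::write.table(data.frame(species = names(tdiv),
                                divergence_myr = as.numeric(tdiv)),
                     files$divergence, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- developmental expression -------------------------------------------
  meta <- expand.grid(replicate = seq_len(cfg$n_replicates), sex = cfg$sexes,
                      time_days = cfg$stage_times, tissue = cfg$tissues,
                      stringsAsFactors = FALSE)
  meta$stage <- paste0("s", match(meta$time_days, cfg$stage_times))
  meta$sample_id <- sprintf("%s_%s_%s_r%d", meta$tissue, meta$stage,
                            substr(meta$sex, 1, 1), meta$replicate)
  all_gids <- c(pg_ids, cg_ids)
  base <- stats::rnorm(length(all_gids), cfg$base_log_mean, cfg$base_log_sd)
  names(base) <- all_gids
  # planted tissue specificity (pseudogenes only)
  spec_genes <- sample(pg_ids, round(cfg$frac_tissue_specific * npg))
  home_tissue <- stats::setNames(sample(cfg$tissues, length(spec_genes),
                                        replace = TRUE), spec_genes)
  # testis enrichment on a random subset of pseudogenes
  testis_genes <- if ("testis" %in% cfg$tissues)
    sample(pg_ids, round(cfg$testis_frac * npg)) else character(0)
  # planted developmental trends (pseudogenes only)
  dyn_genes <- sample(pg_ids, round(cfg$frac_dynamic * npg))
  base[dyn_genes] <- pmax(base[dyn_genes], cfg$dynamic_min_log_mean)
  ddp_truth <- matrix(FALSE, length(all_gids), length(cfg$tissues),
                      dimnames = list(all_gids, cfg$tissues))
  lt <- log(cfg$stage_times)
  z <- lt - mean(lt)
  trend <- list()  # per gene: tissue -> planted log-trend over stages
  for (g in dyn_genes) {
    allowed <- if (g %in% spec_genes) home_tissue[g] else cfg$tissues
    k <- sample(seq_along(allowed), 1)
    in_tissues <- sample(allowed, k)
    tr <- list()
    for (t in in_tissues) {
      b <- stats::rnorm(3)
      f <- b[1] * z + b[2] * z^2 + b[3] * z^3
      f <- f / diff(range(f)) * cfg$trend_amplitude
      tr[[t]] <- f - mean(f)
      ddp_truth[g, t] <- TRUE
    }
    trend[[g]] <- tr
  }
  counts <- matrix(0L, length(all_gids), nrow(meta),
                   dimnames = list(all_gids, meta$sample_id))
  stage_idx <- match(meta$time_days, cfg$stage_times)
  for (gi in seq_along(all_gids)) {
    g <- all_gids[gi]
    logmu <- rep(base[g], nrow(meta))
    if (g %in% spec_genes)
      logmu[meta$tissue != home_tissue[g]] <-
        logmu[meta$tissue != home_tissue[g]] + log(cfg$off_tissue_factor)
    if (g %in% testis_genes)
      logmu[meta$tissue == "testis"] <-
        logmu[meta$tissue == "testis"] + log(cfg$testis_factor)
    if (!is.null(trend[[g]]))
      for (t in names(trend[[g]])) {
        sel <- meta$tissue == t
        logmu[sel] <- logmu[sel] + trend[[g]][[t]][stage_idx[sel]]
      }
    counts[gi, ] <- stats::rnbinom(nrow(meta), mu = exp(logmu),
                                   size = 1 / cfg$nb_dispersion)
  }
  lengths <- vapply(annotations$genes, merged_exonic_length, numeric(1))
  meta$lib_size <- colSums(counts)
  tensor <- expression_tensor(counts, meta, lengths)
  files$counts <- file.path(out_dir, "counts.tsv")
  utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                check.names = FALSE),
                     files$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$sample_meta <- file.path(out_dir, "sample_meta.tsv")
  utils::write.table(meta, files$sample_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- feature tracks ------------------------------------------------------
  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tf))
  total_len <- sum(cfg$chrom_lengths)
  wchr <- cfg$chrom_lengths / total_len
  rand_sites <- function(n, len_range) {
    ch <- sample(layout$chrom, n, replace = TRUE, prob = wchr)
    len <- round(stats::runif(n, len_range[1], len_range[2]))
    start <- floor(stats::runif(n) * (cfg$chrom_lengths[ch] - len))
    data.frame(chrom = ch, start = start, end = start + len,
               row.names = NULL)
  }
  n_tf_bg <- round(total_len * cfg$tf_site_density)
  tf_bg <- rand_sites(n_tf_bg, cfg$tf_site_len)
  tf_bg$subtype <- sample(tf_names, n_tf_bg, replace = TRUE)
  # planted enrichment at the promoters of truly dynamic pseudogenes
  tf_extra <- NULL
  if (length(dyn_genes) > 0 && cfg$ddp_tf_enrichment > 1) {
    dyn_prom <- promoters_of(annotations, dyn_genes)
    extra_per_prom <- (cfg$ddp_tf_enrichment - 1) *
      cfg$tf_site_density * (dyn_prom$end - dyn_prom$start)
    n_extra <- stats::rpois(nrow(dyn_prom), extra_per_prom)
    tf_extra <- do.call(rbind, lapply(which(n_extra > 0), function(i) {
      len <- round(stats::runif(n_extra[i], cfg$tf_site_len[1],
                                cfg$tf_site_len[2]))
      start <- floor(stats::runif(n_extra[i],
                                  dyn_prom$start[i], dyn_prom$end[i] - len))
      data.frame(chrom = dyn_prom$chrom[i], start = start, end = start + len,
                 subtype = sample(tf_names, n_extra[i], replace = TRUE))
    }))
  }
  tf_track <- feature_track(rbind(tf_bg, tf_extra), "TF", layout)
  files$tf <- file.path(out_dir, "tf_sites.bed")
  write_bed(tf_track, files$tf)
  # SNPs: genome background plus promoter enrichment
  n_snp_bg <- round(total_len / 1000 * cfg$snp_density_per_kb)
  snp_bg <- rand_sites(n_snp_bg, c(1, 1))
  all_prom <- promoters_of(annotations)
  prom_bp <- sum(all_prom$end - all_prom$start)
  n_snp_extra <- round((cfg$promoter_snp_factor - 1) *
                         cfg$snp_density_per_kb * prom_bp / 1000)
  pi <- sample.int(nrow(all_prom), n_snp_extra, replace = TRUE,
                   prob = all_prom$end - all_prom$start)
  spos <- floor(stats::runif(n_snp_extra, all_prom$start[pi],
                             all_prom$end[pi] - 1))
  snp_extra <- data.frame(chrom = all_prom$chrom[pi], start = spos,
                          end = spos + 1)
  snp_track <- feature_track(rbind(snp_bg, snp_extra), "SNP", layout)
  files$snp <- file.path(out_dir, "snps.bed")
  write_bed(snp_track, files$snp)
  m6a_track <- feature_track(
    rand_sites(round(total_len * cfg$m6a_density),
               rep(cfg$m6a_site_len, 2)), "m6A", layout)
  files$m6a <- file.path(out_dir, "m6a_sites.bed")
  write_bed(m6a_track, files$m6a)
  # chromHMM segmentation: alternating random-length state segments
  states <- sprintf("E%d", seq_len(cfg$n_chromhmm_states))
  hmm_rows <- lapply(layout$chrom, function(ch) {
    L <- cfg$chrom_lengths[[ch]]
    lens <- numeric(0)
    while (sum(lens) < L)
      lens <- c(lens, pmax(200, round(stats::rexp(
        ceiling(L / cfg$chromhmm_mean_len) + 10, 1 / cfg$chromhmm_mean_len))))
    ends <- pmin(cumsum(lens), L)
    n <- which(ends == L)[1]
    data.frame(chrom = ch, start = c(0, ends[seq_len(n - 1)]),
               end = ends[seq_len(n)],
               subtype = sample(states, n, replace = TRUE))
  })
  hmm_track <- feature_track(do.call(rbind, hmm_rows), "chromHMM", layout)
  files$chromhmm <- file.path(out_dir, "chromhmm.bed")
  write_bed(hmm_track, files$chromhmm)
  rbp_track <- rand_sites(cfg$n_rbp_sites, cfg$rbp_site_len)
  rbp_track$subtype <- sample(sprintf("RBP%02d", seq_len(cfg$n_rbp)),
                              cfg$n_rbp_sites, replace = TRUE)
  rbp_track <- feature_track(rbp_track, "RBP", layout)
  files$rbp <- file.path(out_dir, "rbp_sites.bed")
  write_bed(rbp_track, files$rbp)

  ## --- cancer matrix -------------------------------------------------------
  cancer <- .gen_cancer(cfg)
  files$cancer_counts <- file.path(out_dir, "cancer_counts.tsv")
  utils::write.table(data.frame(gene_id = rownames(cancer$counts),
                                cancer$counts, check.names = FALSE),
                     files$cancer_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$cancer_meta <- file.path(out_dir, "cancer_meta.tsv")
  utils::write.table(cancer$meta, files$cancer_meta, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- truth tables and manifest ------------------------------------------
  truth <- list(
    pseudogenes = data.frame(
      gene_id = pg_ids, biotype = pg_biotype, chrom = pg_chrom,
      branch_id = pg_branch,
      age_myr = branches$age_myr[match(pg_branch, branches$branch_id)],
      parent_id = pg_parent, high_repeat = hi_rep, on_chrY = on_y,
      dynamic = pg_ids %in% dyn_genes,
      tissue_specific = pg_ids %in% spec_genes,
      home_tissue = ifelse(pg_ids %in% spec_genes,
                           home_tissue[pg_ids], NA),
      testis_enriched = pg_ids %in% testis_genes,
      row.names = NULL),
    ddp = ddp_truth[pg_ids, , drop = FALSE],
    cancer = cancer$truth,
    tracks = data.frame(ddp_tf_enrichment = cfg$ddp_tf_enrichment,
                        promoter_snp_factor = cfg$promoter_snp_factor))
  files$truth_pseudogenes <- file.path(out_dir, "truth_pseudogenes.tsv")
  utils::write.table(truth$pseudogenes, files$truth_pseudogenes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$truth_ddp <- file.path(out_dir, "truth_ddp.tsv")
  utils::write.table(data.frame(gene_id = rownames(truth$ddp), truth$ddp),
                     files$truth_ddp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$truth_cancer <- file.path(out_dir, "truth_cancer.tsv")
  utils::write.table(truth$cancer, files$truth_cancer, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$manifest <- file.path(out_dir, "MANIFEST.tsv")
  utils::write.table(data.frame(name = names(files),
                                path = basename(unlist(files))),
                     files$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(layout = layout, annotations = annotations,
                 repeats = repeats, maps = maps, branches = branches,
                 tensor = tensor,
                 tracks = list(tf = tf_track, snp = snp_track,
                               m6a = m6a_track, chromhmm = hmm_track,
                               rbp = rbp_track),
                 cancer = cancer, truth = truth, files = files,
                 config = cfg, dir = out_dir),
            class = "scenario")
}

# cancer matrix with planted type-specific / ubiquitous / background genes
.gen_cancer <- function(cfg) {
  nt <- cfg$n_cancer_types
  types <- sprintf("T%02d", seq_len(nt))
  n_spec <- cfg$n_cancer_specific; n_ubi <- cfg$n_cancer_ubiquitous
  n_oth <- cfg$n_cancer_other
  ids <- sprintf("CPG%03d", seq_len(n_spec + n_ubi + n_oth))
  label <- c(rep("type_specific", n_spec), rep("ubiquitous", n_ubi),
             rep("other", n_oth))
  shares <- matrix(0, length(ids), nt, dimnames = list(ids, types))
  spec_type <- rep(NA_character_, length(ids))
  for (i in seq_len(n_spec)) {
    t <- sample(nt, 1)
    s <- rep(0.5 / (nt - 1), nt); s[t] <- 0.5
    shares[i, ] <- s
    spec_type[i] <- types[t]
  }
  for (i in n_spec + seq_len(n_ubi)) {
    top <- sample(nt, 5)
    s <- rep(0.54 / (nt - 5), nt)
    s[top] <- c(0.12, 0.10, 0.09, 0.08, 0.07)
    shares[i, ] <- s
  }
  for (i in n_spec + n_ubi + seq_len(n_oth)) {
    s <- exp(stats::rnorm(nt, 0, 1.5))
    shares[i, ] <- s / sum(s)
  }
  n_tumor <- sample(cfg$cancer_tumor_range[1]:cfg$cancer_tumor_range[2],
                    nt, replace = TRUE)
  n_normal <- sample(cfg$cancer_normal_range[1]:cfg$cancer_normal_range[2],
                     nt, replace = TRUE)
  meta <- do.call(rbind, lapply(seq_len(nt), function(t) rbind(
    data.frame(cancer_type = types[t], tumor_normal = "tumor",
               sample_id = sprintf("%s_T%02d", types[t], seq_len(n_tumor[t]))),
    data.frame(cancer_type = types[t], tumor_normal = "normal",
               sample_id = sprintf("%s_N%02d", types[t], seq_len(n_normal[t]))))))
  mu <- shares[, meta$cancer_type] * cfg$cancer_base_mean
  mu[, meta$tumor_normal == "normal"] <-
    mu[, meta$tumor_normal == "normal"] * 0.7
  counts <- if (cfg$cancer_noise == "none") mu else
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           nrow(mu), dimnames = dimnames(mu))
  colnames(counts) <- meta$sample_id
  list(counts = counts, meta = meta,
       truth = data.frame(gene_id = ids, label = label,
                          specific_type = spec_type, row.names = NULL))
}

#' Empirical null distribution of the trend-fit R^2
#'
#' Simulates pure-noise responses at `n` time points and returns the R^2
#' values of degree-`degree` polynomial fits. Under the null, the OLS R^2
#' with p predictors has mean p / (n - 1); this reference distribution
#' calibrates the DDP R^2 > 0.3 rule.
#'
#' @param n samples per replicate (must exceed degree + 1).
#' @param degree polynomial degree (default 3).
#' @param replicates number of null replicates.
#' @param seed optional seed.
#' @return numeric vector of `replicates` null R^2 values in `[0, 1]`.
#' @export
null_r2_reference <- function(n, degree = 3, replicates = 1000, seed = NULL) {
  if (n <= degree + 1)
    stop("need n > degree + 1 for a nondegenerate null R^2")
  .with_seed(seed, {
    times <- seq_len(n)  # null R^2 does not depend on the design values
    X <- cbind(1, stats::poly(log(times), degree = degree, raw = TRUE))
    q <- qr(X)
    vapply(seq_len(replicates), function(i) {
      y <- stats::rnorm(n)
      res <- y - X %*% qr.coef(q, y)
      1 - sum(res^2) / sum((y - mean(y))^2)
    }, numeric(1))
  })
}
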