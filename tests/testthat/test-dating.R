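# Divergence ladder used throughout: three outgroups at 90, 160, 320 myr.
toy_branches <- function() branch_table(c("mouse", "opossum", "chicken"),
                                        c(90, 160, 320), root_cap = 480)

test_that("branch table orders the ladder and takes midpoint ages", {
  b <- toy_branches()
  expect_equal(b$t_old, c(480, 320, 160, 90))
  expect_equal(b$t_young, c(320, 160, 90, 0))
  expect_equal(b$age_myr, c(400, 240, 125, 45))
  # midpoints strictly inside their branch bounds
  expect_true(all(b$age_myr > b$t_young & b$age_myr < b$t_old))
  expect_error(branch_table(c("a", "b"), c(90, 90)), "ladder")
  expect_error(branch_table("a", 100, root_cap = 50), "root_cap")
})

test_that("exon presence needs reciprocal-best coverage above min_cov", {
  full <- orthology_map(data.frame(
    focal_chrom = "chr1", focal_start = 0, focal_end = 100,
    target_chrom = "s", target_start = 0, target_end = 100,
    strand = "+", reciprocal_best = 1), "mouse")
  expect_true(exon_presence(c(0, 100), "chr1", full)$present)
  expect_equal(exon_presence(c(0, 100), "chr1", full)$fraction, 1.0)

  partial <- orthology_map(data.frame(
    focal_chrom = "chr1", focal_start = c(0, 60), focal_end = c(20, 80),
    target_chrom = "s", target_start = c(0, 100), target_end = c(20, 120),
    strand = "+", reciprocal_best = 1), "mouse")
  res <- exon_presence(c(0, 100), "chr1", partial, min_cov = 0.5)
  expect_false(res$present)
  expect_equal(res$fraction, 0.4)

  # non-reciprocal blocks are ignored even at full coverage
  decoy <- orthology_map(data.frame(
    focal_chrom = "chr1", focal_start = 0, focal_end = 100,
    target_chrom = "s", target_start = 0, target_end = 100,
    strand = "+", reciprocal_best = 0), "mouse")
  expect_false(exon_presence(c(0, 100), "chr1", decoy)$present)
  expect_equal(exon_presence(c(0, 100), "chr2", full)$fraction, 0)
})

test_that("Dollo assignment places the origin above the oldest presence", {
  b <- toy_branches()
  br <- assign_origin_branch(c(mouse = TRUE, opossum = FALSE,
                               chicken = FALSE), b)
  expect_equal(c(br$t_old, br$t_young, br$age_myr), c(160, 90, 125))
  # absence in a younger species is treated as loss under single origin
  br <- assign_origin_branch(c(mouse = FALSE, opossum = TRUE,
                               chicken = FALSE), b)
  expect_equal(c(br$t_old, br$t_young, br$age_myr), c(320, 160, 240))
  br <- assign_origin_branch(c(mouse = FALSE, opossum = FALSE,
                               chicken = FALSE), b)
  expect_equal(c(br$t_old, br$t_young, br$age_myr), c(90, 0, 45))
  expect_error(assign_origin_branch(c(dog = TRUE), b), "not in branch table")
})

test_that("presence in a more distant species never yields a younger branch", {
  b <- toy_branches()
  species <- names(attr(b, "divergence"))
  set.seed(9)
  for (rep in 1:50) {
    pres <- stats::setNames(sample(c(TRUE, FALSE), 3, replace = TRUE), species)
    base <- assign_origin_branch(pres, b)
    for (sp in species[!pres]) {
      more <- pres; more[sp] <- TRUE
      expect_gte(assign_origin_branch(more, b)$t_old, base$t_old)
    }
  }
})

test_that("the dating filters split chrY, repeat-heavy and clean pseudogenes", {
  layout <- toy_layout()
  set <- annotation_set(layout, list(
    toy_gene("y1", chrom = "chrY", exons = cbind(100, 600)),
    toy_gene("heavy", exons = cbind(0, 1000)),
    toy_gene("edge", exons = cbind(2000, 3000)),
    toy_gene("clean", exons = cbind(10000, 11000)),
    toy_gene("cg", biotype = "protein_coding", exons = cbind(50000, 51000))))
  repeats <- feature_track(data.frame(
    chrom = "chr1", start = c(0, 2000), end = c(710, 2700)), "repeat")
  filt <- filter_for_dating(set, repeats)
  status <- stats::setNames(filt$status, filt$gene_id)
  expect_identical(unname(status["y1"]), "excluded_chrY")
  expect_identical(unname(status["heavy"]), "excluded_repeat")   # 0.71 > 0.70
  expect_identical(unname(status["edge"]), "pass")               # exactly 0.70
  expect_identical(unname(status["clean"]), "pass")
  expect_false("cg" %in% filt$gene_id)  # coding genes are not dated
  expect_equal(unname(attr(filt, "retained")["fraction"]), 0.5)  # 2 of 4 pass
})

test_that("a gene takes its most ancient exon's branch", {
  b <- toy_branches()
  layout <- toy_layout()
  # exon 1 present only in mouse; exon 2 present out to opossum
  set <- annotation_set(layout, list(
    toy_gene("pg", biotype = "unprocessed_pseudogene",
             exons = cbind(c(1000, 3000), c(2000, 4000)))))
  blk <- function(s, e) data.frame(
    focal_chrom = "chr1", focal_start = s, focal_end = e,
    target_chrom = "t", target_start = 0, target_end = e - s,
    strand = "+", reciprocal_best = 1)
  maps <- list(mouse = orthology_map(rbind(blk(1000, 2000), blk(3000, 4000)),
                                     "mouse"),
               opossum = orthology_map(blk(3000, 4000), "opossum"),
               chicken = orthology_map(blk(90000, 90100), "chicken"))
  empty_rep <- feature_track(data.frame(chrom = character(0),
                                        start = numeric(0),
                                        end = numeric(0)), "repeat")
  aa <- date_pseudogenes(set, maps, b, empty_rep)
  expect_identical(aa$status, "dated")
  expect_equal(aa$age_myr, 240)  # exon 2's branch (320,160] wins
  eb <- attr(aa, "exon_branches")
  expect_equal(eb$t_old, c(160, 320))
})

test_that("noise-free simulated maps recover every planted branch", {
  sc <- generate_scenario(scenario_config(
    n_pseudogenes = 200, n_coding = 50, frac_chrY = 0, frac_high_repeat = 0),
    out_dir = withr::local_tempdir(), seed = 301)
  aa <- date_pseudogenes(sc$annotations, sc$maps, sc$branches, sc$repeats)
  dated <- as.data.frame(aa)[aa$status == "dated", ]
  expect_equal(nrow(dated), 200)
  truth <- sc$truth$pseudogenes
  expect_identical(dated$branch_id,
                   truth$branch_id[match(dated$gene_id, truth$gene_id)])
  # midpoint ages strictly inside branch bounds
  expect_true(all(dated$age_myr > dated$t_young & dated$age_myr < dated$t_old))
})

test_that("age distributions count branches and normalize within chromosome class", {
  sc <- generate_scenario(scenario_config(
    n_pseudogenes = 120, n_coding = 30, frac_chrY = 0, frac_high_repeat = 0),
    out_dir = withr::local_tempdir(), seed = 302)
  aa <- date_pseudogenes(sc$annotations, sc$maps, sc$branches, sc$repeats)
  dist <- age_distribution(aa, sc$annotations)
  expect_equal(sum(dist$counts), sum(aa$status == "dated"))
  expect_equal(unname(colSums(dist$proportions)),
               rep(1, ncol(dist$proportions)))
  # noise-free: per-branch counts equal the planted histogram
  planted <- table(factor(sc$truth$pseudogenes$branch_id,
                          levels = sc$branches$branch_id))
  expect_equal(as.vector(dist$counts), as.vector(planted))
})
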