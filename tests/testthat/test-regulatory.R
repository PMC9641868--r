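test_that("TF diversity counts distinct factors with qualifying overlap", {
  track <- feature_track(data.frame(
    chrom = "chr1", start = c(100, 150, 400, 900), end = c(120, 170, 450, 950),
    subtype = c("TFA", "TFA", "TFB", "TFC")), "TF")
  region <- data.frame(chrom = "chr1", start = 0, end = 500)
  expect_equal(tf_diversity(region, track), 2)  # TFA (twice) + TFB
  expect_equal(tf_diversity(data.frame(chrom = "chr1", start = 5000,
                                       end = 6000), track), 0)
  expect_equal(tf_diversity(data.frame(chrom = "chr2", start = 0, end = 500),
                            track), 0)
  set.seed(14)
  for (rep in 1:5) {
    ivs <- random_intervals(50, max_len = 100)
    tr <- feature_track(data.frame(chrom = "chr1", start = ivs[, 1],
                                   end = ivs[, 2],
                                   subtype = sample(paste0("TF", 1:8), 50,
                                                    replace = TRUE)), "TF")
    reg <- c(30000, 60000)
    expect_equal(tf_diversity(data.frame(chrom = "chr1", start = reg[1],
                                         end = reg[2]), tr),
                 oracle_tf_diversity(reg, tr))
  }
})

test_that("chromHMM annotation uses the strict more-than-1-bp rule", {
  track <- feature_track(data.frame(
    chrom = "chr1", start = c(0, 200), end = c(101, 300),
    subtype = c("E1", "E2")), "chromHMM")
  # exactly 1 bp overlap with E1: not annotated under the >= 2 bp default
  expect_equal(chromhmm_state_count(
    data.frame(chrom = "chr1", start = 100, end = 250), track), 1)
  expect_equal(chromhmm_state_count(
    data.frame(chrom = "chr1", start = 99, end = 250), track), 2)
})

test_that("SNP densities are per merged kb with single-base validation", {
  snps <- feature_track(data.frame(
    chrom = "chr1", start = c(100, 500, 5000, 20000, 20001),
    end = c(101, 501, 5001, 20001, 20002)), "SNP")
  regions <- data.frame(chrom = "chr1", start = c(0, 4000), end = c(1000, 13000))
  res <- snp_density(regions, snps)
  expect_equal(res$count, 3)
  expect_equal(res$total_kb, 10)
  expect_equal(res$per_kb, 0.3)
  none <- snp_density(data.frame(chrom = "chr1", start = 3e4, end = 4e4), snps)
  expect_equal(none$per_kb, 0)
  expect_error(snp_density(regions, feature_track(
    data.frame(chrom = "chr1", start = 1, end = 10), "SNP")), "single-base")
  # overlapping regions are merged: no double counting
  dup <- snp_density(data.frame(chrom = "chr1", start = c(0, 0),
                                end = c(1000, 1000)), snps)
  expect_equal(dup$count, 2)
  expect_equal(dup$total_kb, 1)
})

test_that("nearest-site distances match the exhaustive oracle", {
  sites <- feature_track(data.frame(chrom = "chr1", start = c(90, 300),
                                    end = c(91, 350)), "m6A")
  expect_equal(nearest_site_distance(
    data.frame(chrom = "chr1", pos = 100), sites), 10)
  expect_equal(nearest_site_distance(
    data.frame(chrom = "chr1", pos = 320), sites), 0)  # inside
  expect_true(is.na(nearest_site_distance(
    data.frame(chrom = "chr9", pos = 5), sites)))
  set.seed(19)
  starts <- sort(sample.int(99000, 40))
  tr <- feature_track(data.frame(chrom = "chr1", start = starts,
                                 end = starts + 50), "m6A")
  anchors <- data.frame(chrom = "chr1", pos = sample.int(1e5, 100))
  got <- nearest_site_distance(anchors, tr)
  for (i in seq_len(100))
    expect_equal(got[i], oracle_nearest(anchors$pos[i], tr))
})

test_that("rank-sum p-values agree with enumeration and wilcox.test", {
  # tied two-value toy groups vs the bitmask permutation oracle
  x <- c(1, 1, 2, 5); y <- c(2, 2, 3, 3)
  expect_equal(ranksum_test(x, y)$p_value, oracle_ranksum_p(x, y))
  x2 <- c(10, 10, 10); y2 <- c(1, 2, 10, 10)
  expect_equal(ranksum_test(x2, y2)$p_value, oracle_ranksum_p(x2, y2))
  expect_warning(res <- ranksum_test(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(res$p_value, 1)
  # untied exact case: wilcox.test is the independent cross-check
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(ranksum_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation tracks wilcox.test's approximation
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(ranksum_test(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("identical class distributions give large p; planted enrichment is detected", {
  set.seed(61)
  prof <- data.frame(class = rep(c("DDP", "non_dynamic"), each = 40),
                     tf_diversity = rep(rpois(40, 5), 2))
  cc <- class_comparison(prof, metrics = "tf_diversity",
                         pairs = list(c("DDP", "non_dynamic")))
  expect_gt(cc$tests$p_value, 0.9)

  sc <- generate_scenario(scenario_config(
    n_pseudogenes = 150, n_coding = 30, frac_dynamic = 0.4),
    out_dir = withr::local_tempdir(), seed = 62)
  truth <- sc$truth$pseudogenes
  dyn <- truth$gene_id[truth$dynamic]
  nondyn <- truth$gene_id[!truth$dynamic]
  prom <- rbind(
    cbind(promoters_of(sc$annotations, dyn), class = "DDP"),
    cbind(promoters_of(sc$annotations, nondyn), class = "non_dynamic"))
  prom$region_id <- prom$gene_id
  prof <- regulatory_profile(prom, list(tf = sc$tracks$tf))
  cc <- class_comparison(prof, metrics = "tf_diversity",
                         pairs = list(c("DDP", "non_dynamic")))
  med <- tapply(prof$tf_diversity, prof$class, median)
  expect_gte(med["DDP"], med["non_dynamic"])
  expect_lt(cc$tests$p_value, 0.05)
})

test_that("shuffled controls carry no TF enrichment when none is planted", {
  sc <- generate_scenario(scenario_config(
    n_pseudogenes = 100, n_coding = 30, ddp_tf_enrichment = 1),
    out_dir = withr::local_tempdir(), seed = 63)
  shuf <- shuffle_intergenic(sc$layout, sc$annotations, n = 60, seed = 64)
  shuf$class <- "shuffled"; shuf$region_id <- shuf$name
  prom <- promoters_of(sc$annotations,
                       sc$truth$pseudogenes$gene_id[sc$truth$pseudogenes$dynamic])
  prom$class <- "DDP"; prom$region_id <- prom$gene_id
  cols <- c("chrom", "start", "end", "class", "region_id")
  prof <- regulatory_profile(rbind(shuf[cols], prom[cols]),
                             list(tf = sc$tracks$tf))
  cc <- class_comparison(prof, metrics = "tf_diversity",
                         pairs = list(c("DDP", "shuffled")))
  expect_gt(cc$tests$p_value, 0.01)
})

test_that("planted promoter SNP enrichment exceeds the transcript rate", {
  sc <- generate_scenario(scenario_config(n_pseudogenes = 200, n_coding = 100),
                          out_dir = withr::local_tempdir(), seed = 65)
  prom <- promoters_of(sc$annotations)
  spans <- as.data.frame(sc$annotations)[, c("chrom", "start", "end")]
  prom_rate <- snp_density(prom, sc$tracks$snp)$per_kb
  span_rate <- snp_density(spans, sc$tracks$snp)$per_kb
  expect_gt(prom_rate, span_rate)
})
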