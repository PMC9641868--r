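test_that("trend fits are exact for nested signals and degenerate inputs", {
  times <- c(10, 14, 20, 28, 40, 57, 80, 113, 160, 226, 320, 452)
  # noise-free log-linear signal: nested in the cubic -> R^2 = 1
  y <- 2 + 0.7 * log(times)
  expect_equal(fit_trend(expm1(y), times)$r2, 1)
  expect_equal(fit_trend(rep(3, 12), times)$r2, 0)     # constant -> 0
  expect_error(fit_trend(1:4, c(1, 1, 2, 2)), "degenerate")
  # R^2 never decreases with degree on the same data (nested OLS)
  set.seed(5)
  for (rep in 1:10) {
    v <- rnbinom(12, mu = 60, size = 10)
    r2s <- vapply(1:3, function(d) fit_trend(v, times, degree = d)$r2,
                  numeric(1))
    expect_true(all(diff(r2s) >= -1e-12))
  }
})

test_that("null R^2 has mean degree/(n-1) and fit_trends matches fit_trend", {
  r2 <- null_r2_reference(n = 12, degree = 3, replicates = 2000, seed = 4)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_lt(abs(mean(r2) - 3 / 11), 0.02)
  expect_error(null_r2_reference(n = 2, degree = 1), "n > degree")
  expect_length(null_r2_reference(n = 8, replicates = 1, seed = 1), 1)

  meta <- toy_meta(times = c(10, 20, 40, 80, 160, 320), reps = 2)
  set.seed(8)
  cpm <- matrix(rnbinom(5 * nrow(meta), mu = 80, size = 10), 5,
                dimnames = list(paste0("g", 1:5), meta$sample_id))
  fits <- fit_trends(cpm, meta)
  for (i in 1:5) for (t in c("brain", "liver")) {
    sel <- meta$tissue == t
    expect_equal(fits$r2[fits$gene_id == rownames(cpm)[i] & fits$tissue == t],
                 fit_trend(cpm[i, sel], meta$time_days[sel])$r2)
  }
})

test_that("DDP calls use a strict R^2 > 0.3 rule across tissues", {
  fits <- data.frame(
    gene_id = rep(c("a", "b", "c"), each = 2),
    tissue = rep(c("brain", "liver"), 3),
    r2 = c(0.30, 0.29, 0.31, 0.1, 0.05, 0.02), n = 12)
  calls <- call_ddps(fits)
  expect_false(calls$ddp[calls$gene_id == "a"])  # 0.30 exactly: not dynamic
  expect_true(calls$ddp[calls$gene_id == "b"])
  expect_false(calls$ddp[calls$gene_id == "c"])
  expect_true(calls$dynamic_brain[calls$gene_id == "b"])
  expect_false(calls$dynamic_liver[calls$gene_id == "b"])
  expect_equal(unname(attr(calls, "counts")["total_ddp"]), 1)
})

test_that("DDP calls are invariant to common per-sample CPM scaling", {
  meta <- toy_meta(times = c(10, 20, 40, 80, 160, 320), reps = 2)
  set.seed(12)
  cpm <- matrix(rnbinom(20 * nrow(meta), mu = 100, size = 10), 20,
                dimnames = list(paste0("g", 1:20), meta$sample_id))
  cpm[1, ] <- cpm[1, ] + 40 * log(meta$time_days)
  a <- call_ddps(fit_trends(cpm, meta, response = "raw"))
  b <- call_ddps(fit_trends(cpm * 7.3, meta, response = "raw"))
  expect_identical(a$ddp, b$ddp)
})

test_that("parent-correlation exclusion is signed with missing parents kept", {
  calls <- data.frame(gene_id = c("pg1", "pg2", "pg3"),
                      ddp = c(TRUE, TRUE, TRUE),
                      parent_r = NA_real_, excluded = FALSE)
  class(calls) <- c("ddp_calls", "data.frame")
  t <- seq(0.1, 2, length.out = 10)
  expr <- rbind(pg1 = sin(t), pg2 = -sin(t), pg3 = cos(t),
                par1 = sin(t))
  out <- parent_correlation_filter(calls, expr,
                                   c(pg1 = "par1", pg2 = "par1", pg3 = NA))
  expect_equal(out$parent_r[1], 1)
  expect_true(out$excluded[1])          # identical profile: R = 1 -> excluded
  expect_equal(out$parent_r[2], -1)
  expect_false(out$excluded[2])         # anti-correlated: retained (signed rule)
  expect_true(is.na(out$parent_r[3]))   # missing parent: not excluded
  expect_false(out$excluded[3])
})

test_that("null exclusion rate at R >= 0.6 matches the analytic t-tail", {
  n <- 10
  set.seed(33)
  r <- replicate(4000, cor(rnorm(n), rnorm(n)))
  emp <- mean(r >= 0.6)
  # one-sided tail of the null correlation via the exact t-transform
  tcut <- 0.6 * sqrt((n - 2) / (1 - 0.6^2))
  ana <- pt(tcut, df = n - 2, lower.tail = FALSE)
  expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / 4000) + 0.005)
})

test_that("co-expression edges equal the all-pairs cor.test oracle", {
  set.seed(44)
  n_s <- 10
  m <- matrix(rnorm(20 * n_s), 20,
              dimnames = list(c(paste0("pg", 1:10), paste0("cg", 1:10)),
                              paste0("s", 1:n_s)))
  m[11, ] <- m[1, ] + rnorm(n_s, sd = 0.01)   # plant one strong pair
  m[2, ] <- 5                                  # zero variance: skipped
  meta <- data.frame(sample_id = colnames(m),
                     tissue = rep("brain", n_s))
  net <- coexpression_network(m, meta, paste0("pg", 1:10), paste0("cg", 1:10),
                              r_cut = 0.5, p_cut = 0.05)
  oracle <- list()
  for (p in paste0("pg", c(1, 3:10))) for (cg in paste0("cg", 1:10)) {
    ct <- cor.test(m[p, ], m[cg, ])
    if (abs(ct$estimate) > 0.5 && ct$p.value < 0.05)
      oracle[[length(oracle) + 1]] <- data.frame(
        pseudogene = p, coding_gene = cg,
        r = unname(ct$estimate), p = ct$p.value)
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$pseudogene, oracle$coding_gene), ]
  expect_equal(net$pseudogene, oracle$pseudogene)
  expect_equal(net$coding_gene, oracle$coding_gene)
  expect_equal(net$r, oracle$r, tolerance = 1e-12)
  expect_equal(net$p, oracle$p, tolerance = 1e-10)
  expect_identical(attr(net, "skipped")$gene_id, "pg2")
  # duplicate profile edge was kept with r ~ 1
  expect_true(any(net$pseudogene == "pg1" & net$coding_gene == "cg1"))
})

test_that("testis columns are excluded before scoring the network", {
  set.seed(45)
  m <- matrix(rnorm(6 * 12), 6,
              dimnames = list(c(paste0("pg", 1:3), paste0("cg", 1:3)),
                              paste0("s", 1:12)))
  meta <- data.frame(sample_id = colnames(m),
                     tissue = rep(c("brain", "testis"), each = 6))
  # huge planted signal confined to testis columns
  m2 <- m
  m2[, meta$tissue == "testis"] <- rep(seq_len(6) * 100, 6)
  a <- coexpression_network(m, meta, paste0("pg", 1:3), paste0("cg", 1:3),
                            r_cut = 0.3, p_cut = 0.5)
  b <- coexpression_network(m2, meta, paste0("pg", 1:3), paste0("cg", 1:3),
                            r_cut = 0.3, p_cut = 0.5)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c <- coexpression_network(m[, meta$tissue == "brain"],
                            meta[meta$tissue == "brain", ],
                            paste0("pg", 1:3), paste0("cg", 1:3),
                            r_cut = 0.3, p_cut = 0.5)
  expect_equal(as.data.frame(a), as.data.frame(c))
})
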