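test_that("the low-count filter applies the strict every-library rule", {
  counts <- matrix(50L, nrow = 3, ncol = 6,
                   dimnames = list(c("ok", "one_low", "boundary"), NULL))
  counts["one_low", 4] <- 9L
  counts["boundary", ] <- 10L
  exp <- make_experiment(counts, n_rep = 1)
  kept <- filter_low_counts(exp)
  expect_setequal(rownames(kept$counts), c("ok", "boundary"))
  # the lenient rule keeps a gene reaching 10 in at least one library
  low <- counts
  low["one_low", ] <- 0L
  low["one_low", 1] <- 10L
  exp2 <- make_experiment(low, n_rep = 1)
  expect_true("one_low" %in%
                rownames(filter_low_counts(exp2, rule = "any")$counts))
  expect_false("one_low" %in% rownames(filter_low_counts(exp2)$counts))
  # identity when everything passes
  expect_identical(filter_low_counts(kept)$counts, kept$counts)
})

test_that("TMM factors are unity for identical or depth-scaled libraries", {
  set.seed(77)
  base <- rnbinom(400, mu = 200, size = 10) + 10L
  counts <- matrix(rep(base, 6), ncol = 6)
  exp <- make_experiment(counts, n_rep = 1)
  f <- normalization_factors(exp)
  expect_equal(unname(f), rep(1, 6), tolerance = 1e-12)

  # doubling every count is pure sequencing depth: still factor 1
  counts2 <- counts
  counts2[, 2] <- counts[, 2] * 2L
  f2 <- normalization_factors(make_experiment(counts2, n_rep = 1))
  expect_equal(unname(f2), rep(1, 6), tolerance = 1e-6)
  expect_equal(prod(f2), 1, tolerance = 1e-9)

  zero <- counts
  zero[, 3] <- 0L
  expect_error(normalization_factors(make_experiment(zero, n_rep = 1)),
               "all-zero")
})

test_that("log-CPM follows the offset formula and its invariances", {
  counts <- matrix(1000000L, nrow = 1, ncol = 6,
                   dimnames = list("g1", NULL))
  exp <- make_experiment(counts, n_rep = 1)
  lc <- log_cpm(exp, factors = rep(1, 6))
  expected <- log2((1e6 + 0.5) / (1e6 + 1) * 1e6)
  expect_equal(unname(lc[1, ]), rep(expected, 6), tolerance = 1e-12)
  expect_equal(expected, 19.93, tolerance = 1e-3)

  set.seed(41)
  counts <- matrix(rnbinom(100 * 6, mu = 100, size = 5), ncol = 6)
  counts[1, 1] <- 0L
  exp <- make_experiment(counts, n_rep = 1)
  lc <- log_cpm(exp, factors = rep(1, 6))
  expect_true(all(is.finite(lc)))
  # doubling counts and depth leaves log-CPM essentially unchanged
  lc2 <- log_cpm(make_experiment(counts * 2L, n_rep = 1),
                 factors = rep(1, 6))
  expect_equal(lc2, lc, tolerance = 1e-3)
})

test_that("the cell-means fit recovers planted effects and residual variance", {
  # noiseless +1 log2 effect in WT ACC only
  meta_exp <- make_experiment(matrix(10L, 2, 12), n_rep = 2)
  meta <- meta_exp$library_meta
  base <- matrix(5, nrow = 2, ncol = 12,
                 dimnames = list(c("hit", "flat"), meta$library))
  base["hit", meta$genotype == "WT" & meta$treatment == "ACC"] <- 6
  fit <- fit_genewise_model(base, meta)
  expect_equal(unname(fit$coefficients["hit", ]), c(1, 0, 0))
  expect_equal(unname(fit$coefficients["flat", ]), c(0, 0, 0))
  expect_equal(fit$df_residual, 12 - 6)

  # residual variance agrees with direct per-cell OLS on a noisy toy
  set.seed(3)
  noisy <- base + matrix(rnorm(24, sd = 0.3), 2, 12)
  fit2 <- fit_genewise_model(noisy, meta)
  grp <- paste(meta$genotype, meta$treatment)
  for (g in rownames(noisy)) {
    resid <- unlist(lapply(split(noisy[g, ], grp),
                           function(x) x - mean(x)))
    expect_equal(fit2$sigma2[[g]], sum(resid^2) / 6, tolerance = 1e-9)
  }
  # balanced design: coefficients are differences of cell means
  wt_acc <- mean(noisy["hit", meta$genotype == "WT" &
                         meta$treatment == "ACC"])
  wt_mock <- mean(noisy["hit", meta$genotype == "WT" &
                          meta$treatment == "mock"])
  expect_equal(unname(fit2$coefficients["hit", "WT"]), wt_acc - wt_mock,
               tolerance = 1e-9)
})

test_that("variance moderation shrinks toward the prior and honours overrides", {
  s2 <- rep(0.5, 100)
  m <- moderate_variances(s2, df = 6)
  expect_true(is.infinite(m$d0))
  expect_equal(m$s2_post, s2)

  set.seed(21)
  s2v <- 2 * 4 / rchisq(500, 4) * rchisq(500, 6) / 6
  m0 <- moderate_variances(s2v, df = 6, d0 = 0)
  expect_identical(m0$s2_post, s2v)
  m4 <- moderate_variances(s2v, df = 6, d0 = 4, s02 = 2)
  expect_equal(m4$s2_post, (4 * 2 + 6 * s2v) / 10, tolerance = 1e-12)
  expect_error(moderate_variances(rep(0, 5), 4), "zero")
})

test_that("BH adjustment reproduces the worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(6)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), 1:50)  # q preserves the p order
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the ethylene-responsive call needs WT response and receptor dependence", {
  tab <- data.frame(
    gene = c("wt_only", "all_geno", "weak", "one_sided", "repressed"),
    log2fc_WT = c(2, 2, 0.5, 2, -2),
    q_WT = c(0.001, 0.001, 0.001, 0.001, 0.001),
    log2fc_etr1_LMX5 = c(0, 2, 0, 0, 0),
    log2fc_etr1_35S = c(0, 2, 0, 1.5, -0.5))
  hits <- call_ethylene_responsive(tab)
  expect_setequal(hits, c("wt_only", "repressed"))

  # a significant but receptor-independent gene never qualifies
  tab$q_WT[1] <- 0.5
  expect_false("wt_only" %in% call_ethylene_responsive(tab))
  expect_error(call_ethylene_responsive(tab[, 1:3]), "contrast")
})

test_that("the full response pipeline is deterministic and finds planted responders", {
  cfg <- count_sim_config(seed = 8, n_genes = 500,
                          responder_genes = sprintf("G%04d", 1:25))
  sim <- generate_count_experiment(cfg)
  t1 <- response_table(sim$experiment)
  t2 <- response_table(sim$experiment)
  expect_identical(t1, t2)
  expect_true(all(t1$q_WT >= t1$p_WT - 1e-12))
  called <- t1$gene[t1$responsive]
  expect_gt(mean(sim$truth$responders %in% called), 0.8)
  expect_lt(mean(!called %in% sim$truth$responders), 0.2)
  # planted log2 fold changes are estimated near their true value of 2
  est <- t1$log2fc_WT[t1$gene %in% sim$truth$responders]
  expect_equal(mean(est), 2, tolerance = 0.15)
})

test_that("relative expression follows the 2^-dCt rule", {
  expect_equal(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(18, 20), 4)
  expect_equal(relative_expression(c(20, 21), 20), c(1, 0.5))
  expect_error(relative_expression(NA, 20), "finite")
})

test_that("count experiments round-trip through TSV", {
  sim <- generate_count_experiment(count_sim_config(seed = 3, n_genes = 40))
  cp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_count_experiment(sim$experiment, cp, mp)
  back <- read_count_experiment(cp, mp)
  expect_equal(back$counts, sim$experiment$counts)
  expect_equal(back$library_meta$genotype,
               sim$experiment$library_meta$genotype)
})
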