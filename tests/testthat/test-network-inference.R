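test_that("mutual information is exact on the diagonal case and degenerate inputs", {
  x <- sort(rnorm(100))
  expect_equal(mutual_information(x, x, bins = 10), log(10),
               tolerance = 1e-12)
  # any strictly increasing y concentrates the joint mass identically
  expect_equal(mutual_information(x, exp(x), bins = 10), log(10),
               tolerance = 1e-12)
  expect_identical(mutual_information(rep(2, 50), rnorm(50)), 0)
  expect_error(mutual_information(1:10, 1:9), "equal length")
  expect_error(mutual_information(1:10, 10:1, bins = 1), "bins")
})

test_that("mutual information is symmetric and monotone-invariant", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(60)
    y <- x + rnorm(60)
    expect_identical(mutual_information(x, y), mutual_information(y, x))
    # equal-frequency binning only sees ranks
    expect_equal(mutual_information(x, y),
                 mutual_information(exp(x), y^3 + 2 * y), tolerance = 1e-12)
  }
})

test_that("permutation-null mutual information matches the enumeration oracle", {
  # under a random permutation with 10 equal-count bins of n = 100, each
  # joint cell count is Hypergeometric(100; 10; 10); the exact expected
  # plug-in MI follows by enumeration over the 11 possible counts
  counts <- 0:10
  pr <- dhyper(counts, 10, 90, 10)
  exact <- 100 * sum(pr * (counts / 100) *
                       log(counts * 100 / (10 * 10)), na.rm = TRUE)
  set.seed(17)
  x <- rnorm(100)
  mis <- replicate(100, mutual_information(x, sample(x), bins = 10))
  expect_true(all(mis < log(10)))
  se <- sd(mis) / sqrt(length(mis))
  expect_lt(abs(mean(mis) - exact), 3 * se)
})

test_that("the MI matrix agrees with pairwise calls and flags constants", {
  set.seed(8)
  v <- matrix(rnorm(6 * 40), nrow = 6,
              dimnames = list(paste0("g", 1:6), NULL))
  v[2, ] <- v[1, ] + rnorm(40, sd = 0.1)
  v[5, ] <- 3  # constant gene
  mi <- mi_matrix(v)
  expect_true(isSymmetric(unclass(mi)))
  expect_equal(unname(diag(mi)), rep(0, 6))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(mi[i, j], mutual_information(v[i, ], v[j, ]),
                 tolerance = 1e-12)
  }
  expect_true(all(mi[5, ] == 0))
})

test_that("CLR matches hand-computed scores and the two-pass formula", {
  # all off-diagonal MI equal: no deviation from background, all zeros
  flat <- matrix(0.3, 4, 4,
                 dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  diag(flat) <- 0
  expect_true(all(clr_transform(flat) == 0))

  # 3-gene toy with one raised pair, checked against hand-derived z:
  # row 1 off-diagonal is (0.5, 0.1): mean 0.3, sd = 0.2 sqrt(2), so
  # z_1(2) = (0.5 - 0.3) / (0.2 sqrt 2) = 1/sqrt(2), and by symmetry
  # Z_12 = sqrt(2 * 1/2) = 1; gene 3 has no positive deviation
  mi3 <- matrix(c(0, 0.5, 0.1,
                  0.5, 0, 0.1,
                  0.1, 0.1, 0), 3, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  Z3 <- clr_transform(mi3)
  expect_equal(Z3["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(Z3["g1", "g3"], 0)
  expect_equal(Z3["g2", "g3"], 0)

  set.seed(12)
  for (i in 1:3) {
    m <- matrix(runif(50 * 50), 50, 50)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("g", 1:50), paste0("g", 1:50))
    Z <- clr_transform(m)
    expect_lt(max(abs(unclass(Z) - clr_direct(m))), 1e-12)
    expect_true(isSymmetric(unclass(Z)))
    expect_equal(unname(diag(Z)), rep(0, 50))
    expect_true(all(Z >= 0))
  }
})

test_that("CLR is equivariant under gene reordering", {
  set.seed(23)
  out <- generate_section_series(simulation_config(seed = 5, n_genes = 80))
  mi <- mi_matrix(out$series)
  Z <- clr_transform(mi)
  perm <- sample(rownames(mi))
  Zp <- clr_transform(unclass(mi)[perm, perm])
  expect_equal(unclass(Zp), unclass(Z)[perm, perm], tolerance = 1e-12)
})

test_that("edge signs follow the Pearson correlation with + on ties", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1, -1, 1, -1), e = c(1, 1, -1, -1), f = rep(1, 4))
  s <- make_series(v)
  expect_identical(edge_sign(s, "a", "b"), "+")
  expect_identical(edge_sign(s, "a", "c"), "-")
  expect_identical(edge_sign(s, "d", "e"), "+")  # r = 0 resolves to +
  expect_error(edge_sign(s, "a", "f"), "zero-variance")
  expect_error(edge_sign(s, "a", "nope"), "unknown gene")
})

test_that("network construction thresholds CLR scores and keeps all nodes", {
  genes <- paste0("g", 1:5)
  Z <- matrix(0, 5, 5, dimnames = list(genes, genes))
  Z["g1", "g2"] <- Z["g2", "g1"] <- 6.1
  Z["g3", "g4"] <- Z["g4", "g3"] <- 2.5
  net <- network_from_scores(Z, threshold = 5)
  expect_equal(igraph::vcount(net$graph), 5)
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$gene_a, ed$gene_b), c("g1", "g2"))
  expect_equal(ed$clr, 6.1)

  # threshold 0 links every pair with a positive score
  net0 <- network_from_scores(Z, threshold = 0)
  expect_equal(igraph::ecount(net0$graph), sum(Z[upper.tri(Z)] >= 0))

  # raising the threshold never adds edges
  last <- Inf
  for (th in c(0, 1, 2.5, 5, 7)) {
    ne <- igraph::ecount(network_from_scores(Z, threshold = th)$graph)
    expect_lte(ne, last)
    last <- ne
  }
  expect_error(network_from_scores(Z, threshold = -1), "nonnegative")
})

test_that("threshold-5 edges concentrate within planted modules", {
  for (seed in 1:5) {
    out <- generate_section_series(simulation_config(seed = seed))
    f <- filter_expressed(out$series)
    net <- build_network(clr_transform(mi_matrix(f)), f, threshold = 5)
    ed <- network_edges(net)
    expect_gt(nrow(ed), 0)
    memb <- rep(NA_integer_, nrow(f$values))
    names(memb) <- rownames(f$values)
    for (i in seq_along(out$truth$modules))
      memb[out$truth$modules[[i]]$members] <- i
    within <- !is.na(memb[ed$gene_a]) & !is.na(memb[ed$gene_b]) &
      memb[ed$gene_a] == memb[ed$gene_b]
    G <- nrow(f$values)
    base_rate <- sum(vapply(out$truth$modules, function(m) {
      k <- length(m$members)
      k * (k - 1) / 2
    }, numeric(1))) / (G * (G - 1) / 2)
    expect_gte(mean(within), 5 * base_rate)
  }
})

test_that("networks round-trip as edge lists and GraphML", {
  out <- generate_section_series(simulation_config(seed = 4, n_genes = 80))
  net <- build_network(clr_transform(mi_matrix(out$series)), out$series,
                       threshold = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_edges(net, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), igraph::ecount(net$graph))
  expect_true(all(back$sign %in% c("+", "-")))
  expect_true(all(back$clr >= 4))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_setequal(igraph::vertex_attr(g2, "name"), net$genes)
  expect_equal(sort(igraph::edge_attr(g2, "clr")),
               sort(igraph::edge_attr(net$graph, "clr")), tolerance = 1e-9)
})
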