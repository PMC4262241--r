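test_that("rigid graphs give a constant randomization null", {
  ens <- nea_ensemble(star_net(), n_rand = 5, seed = 1)
  nm <- null_moments(ens, "H", c("A", "B"))
  expect_equal(nm$mean, 2)
  expect_equal(nm$sd, 0)

  # observed equals the degenerate null mean -> z = 0, p = 0.5
  res <- nea_gene_vs_set(ens, "H", c("A", "B"))
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
})

test_that("a degenerate enriched null maps to the permutation bound", {
  # sparse network + few replicas: find a pair whose replica counts are all
  # equal while the observation differs, and check the bounded z
  g <- gen_network(300, 2, "ER", seed = 11)
  ens <- nea_ensemble(g, n_rand = 5, seed = 11)
  target <- igraph::V(g)$name[1:30]
  found <- FALSE
  for (gene in setdiff(igraph::V(g)$name[igraph::degree(g) > 0],
                       target)) {
    nm <- null_moments(ens, gene, target)
    obs <- as.integer(direct_links(g, gene, target))
    if (nm$sd == 0 && obs != nm$mean) {
      res <- nea_gene_vs_set(ens, gene, target)
      expect_equal(abs(res$z), qnorm(1 - 1 / 6), tolerance = 1e-12)
      expect_gte(res$p, 1 / 6 - 1e-9)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("ensembles are deterministic and reused across queries", {
  g <- gen_network(200, 6, "ER", seed = 4)
  e1 <- nea_ensemble(g, n_rand = 8, seed = 3)
  e2 <- nea_ensemble(g, n_rand = 8, seed = 3)
  G <- igraph::V(g)$name[2:21]
  r1 <- nea_gene_vs_set(e1, "G000001", G)
  r2 <- nea_gene_vs_set(e2, "G000001", G)
  expect_identical(r1$z, r2$z)
  expect_identical(null_moments(e1, "G000001", G)$counts,
                   null_moments(e2, "G000001", G)$counts)
  expect_error(nea_ensemble(g, n_rand = 1), "at least 2")
})

test_that("z-scores recompute exactly from their stored moments", {
  g <- gen_network(300, 8, "ER", seed = 9)
  ens <- nea_ensemble(g, n_rand = 10, seed = 9)
  set.seed(1)
  for (k in 1:10) {
    i <- sample(igraph::V(g)$name, 1)
    G <- sample(setdiff(igraph::V(g)$name, i), 30)
    res <- nea_gene_vs_set(ens, i, G)
    if (res$null_sd > 0)
      expect_identical(res$z, (res$observed - res$null_mean) / res$null_sd)
  }
})

test_that("set coherence responds to planted structure", {
  st <- tiny_study(seed = 7)
  ens <- nea_ensemble(st$network, n_rand = 10, seed = 7)
  coh <- nea_set_coherence(ens, st$modules[[1]])
  expect_gt(coh$z, 2.97)

  # a set with no internal edges in a connected graph sits below its null
  tri <- load_edge_list(c("A B", "B C", "C A", "A D", "B E", "C F"))
  ens2 <- nea_ensemble(tri, n_rand = 10, seed = 2)
  coh2 <- nea_set_coherence(ens2, c("D", "E", "F"))
  expect_lte(coh2$observed, coh2$null_mean)
  expect_lte(coh2$z, 0)
})

test_that("coherence z is calibrated on null gene sets", {
  g <- gen_network(500, 8, "ER", seed = 21)
  ens <- nea_ensemble(g, n_rand = 25, seed = 21)
  set.seed(21)
  zs <- replicate(100, {
    G <- sample(igraph::V(g)$name, 15)
    nea_set_coherence(ens, G)$z
  })
  expect_lte(mean(abs(zs) > 1.96), 0.12)  # 5% nominal + MC allowance
  expect_lte(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("members of a planted near-clique are strongly enriched", {
  base <- gen_network(1000, 6, "ER", seed = 5)
  tr <- plant_modules(base, k_modules = 1, module_size = 12, p_intra = 1,
                      seed = 5)
  ens <- nea_ensemble(tr$network, n_rand = 25, seed = 5)
  clique <- tr$modules[[1]]
  z <- vapply(clique, function(i)
    nea_gene_vs_set(ens, i, setdiff(clique, i))$z, numeric(1))
  expect_true(all(z > 2.97))
})

test_that("z_to_p follows the normal tail in both conventions", {
  expect_equal(z_to_p(0), 0.5)
  expect_equal(z_to_p(2.97), pnorm(2.97, lower.tail = FALSE))
  expect_equal(z_to_p(2.97), 0.00149, tolerance = 1e-2)
  # the published z = 1.97 <-> two-tailed p = 0.01 bridge is numerically
  # inconsistent; the actual two-sided p is ~0.0488
  expect_equal(z_to_p(1.97, "two_sided"), 0.0488, tolerance = 1e-3)
  expect_equal(z_to_p(-3, "two_sided"), 2 * pnorm(-3))
  expect_equal(z_to_p(0, "two_sided"), 1)
  expect_error(z_to_p(Inf), "finite")
})

test_that("Fisher combination matches the chi-square oracle", {
  # k = 1 identity
  for (p in c(0.01, 0.3, 1)) expect_equal(fisher_combine(p)$p, p)
  expect_equal(fisher_combine(c(1, 1))$p, 1)

  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$chi2, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(fc$df, 4)
  expect_equal(fc$p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE))

  # df = 4 closed form e^{-x/2}(1 + x/2)
  x <- fc$chi2
  expect_equal(fc$p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)

  expect_error(fisher_combine(numeric()), "no p-values")
  expect_warning(fisher_combine(c(0, 0.5)), "floored")
})

test_that("Fisher combination is monotone in every component", {
  set.seed(8)
  for (k in 1:20) {
    p <- runif(sample(2:5, 1))
    i <- sample(length(p), 1)
    q <- p
    q[i] <- p[i] * runif(1)
    expect_lte(fisher_combine(q)$p, fisher_combine(p)$p)
  }
})

test_that("the exact 2x2 test matches its enumeration oracle and fisher.test", {
  # co-occurrence table printed for FN1 vs MSH6 over 148 genomes
  expect_equal(fisher_exact_2x2(4, 0, 1, 143), 5 / choose(148, 4))
  expect_equal(fisher_exact_2x2(4, 0, 1, 143), 2.6e-7, tolerance = 0.02)

  expect_equal(fisher_exact_2x2(1, 1, 1, 1, sided = "two"), 1)
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 6)

  set.seed(15)
  for (k in 1:25) {
    tb <- as.integer(rmultinom(1, sample(4:40, 1), runif(4, 0.05, 1)))
    one <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    two <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4], sided = "two")
    expect_equal(one, enum_fisher_oracle(tb[1], tb[2], tb[3], tb[4], "one"))
    expect_equal(two, enum_fisher_oracle(tb[1], tb[2], tb[3], tb[4], "two"))
    m <- matrix(tb, 2, byrow = TRUE)
    expect_equal(one, stats::fisher.test(m, alternative = "greater")$p.value)
    expect_equal(two, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(-1, 0, 0, 1), "non-negative")
})
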