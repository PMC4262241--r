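test_that("network generation is deterministic with the requested shape", {
  g1 <- gen_network(10, 2, "ER", seed = 1)
  expect_equal(igraph::vcount(g1), 10)
  expect_equal(igraph::ecount(g1), 10)
  g2 <- gen_network(10, 2, "ER", seed = 1)
  expect_equal(edge_jaccard(g1, g2), 1)

  ba <- gen_network(1000, 6, "BA", seed = 2)
  deg <- igraph::degree(ba)
  expect_gt(max(deg), 5 * median(deg))  # heavy-tailed degrees
})

test_that("planted modules reach the requested internal density", {
  base <- gen_network(300, 4, "ER", seed = 4)
  tr <- plant_modules(base, k_modules = 3, module_size = 10, p_intra = 1,
                      seed = 4)
  for (m in tr$modules)  # p_intra = 1 -> every module is a clique
    expect_equal(as.integer(within_set_links(tr$network, m, "direct")),
                 choose(10, 2))
  expect_false(any(duplicated(unlist(tr$modules))))
  expect_equal(tr$collection$super, "CAN_SUPER")

  tr2 <- plant_modules(base, 3, 10, p_intra = 0.5, seed = 5)
  dens <- vapply(tr2$modules, function(m)
    as.integer(within_set_links(tr2$network, m, "direct")) / choose(10, 2),
    numeric(1))
  # at least the planted probability, minus binomial fluctuation
  expect_true(all(dens > 0.5 - 3 * sqrt(0.25 / choose(10, 2))))
})

test_that("cohort labels account for every generated event", {
  base <- gen_network(200, 4, "ER", seed = 6)
  tr <- plant_modules(base, 2, 8, 0.8, seed = 6)
  co <- gen_cohort(tr, n_samples = 12, drivers_per_sample = 3,
                   passengers_per_sample = 5, seed = 6)
  expect_equal(nrow(co$maf), nrow(co$labels))
  expect_equal(nrow(co$maf), 12 * 8)
  expect_setequal(unique(co$labels$label), c("driver", "passenger"))
  # drivers come from modules, passengers from outside them
  mod_genes <- unlist(tr$modules)
  expect_true(all(co$labels$gene[co$labels$label == "driver"] %in% mod_genes))
  expect_false(any(co$labels$gene[co$labels$label == "passenger"] %in% mod_genes))

  co0 <- gen_cohort(tr, 5, drivers_per_sample = 2,
                    passengers_per_sample = 0, seed = 1)
  expect_true(all(co0$labels$label == "driver"))
  expect_identical(gen_cohort(tr, 12, 3, 5, seed = 6)$maf, co$maf)
})

test_that("CNA segments are contiguous, callable, and co-mutated", {
  base <- gen_network(300, 4, "ER", seed = 8)
  tr <- plant_modules(base, 2, 8, 0.8, seed = 8)
  cp <- gen_cna_profiles(tr, n_samples = 20, segment_length = 6,
                         amplitude = 0.5, noise_sd = 0, seed = 8)
  cc <- call_cna(cp$profile)
  # noiseless carriers: every segment gene called in every carrier, with
  # identical call patterns across genes of one segment
  for (seg in cp$segments) {
    pat <- lapply(seg, function(g) sort(cc$calls$sample[cc$calls$gene == g]))
    expect_true(all(vapply(pat, identical, TRUE, pat[[1]])))
    expect_equal(length(pat[[1]]), 4)  # 20 samples * carrier_fraction 0.2
  }
  # exactly one module gene (the driver) per segment
  for (k in seq_along(cp$segments))
    expect_equal(sum(cp$segments[[k]] %in% unlist(tr$modules)), 1)
  expect_true(all(cp$drivers %in% unlist(tr$modules)))

  # sub-threshold amplitude yields no calls at tau = 0.35
  cp2 <- gen_cna_profiles(tr, 20, 6, amplitude = 0.2, noise_sd = 0, seed = 8)
  expect_equal(nrow(call_cna(cp2$profile)$calls), 0)

  # correlated point mutations land in carrier samples, in module partners
  carriers <- unique(cc$calls$sample)
  expect_true(all(cp$extra_maf$Tumor_Sample_Barcode %in% carriers))
  expect_true(all(cp$extra_maf$Hugo_Symbol %in% unlist(tr$modules)))
})

test_that("written studies parse back through every reader cleanly", {
  sc <- synthetic_cohort(n_nodes = 200, k_modules = 2, module_size = 8,
                         n_samples = 10, drivers_per_sample = 2,
                         passengers_per_sample = 4, seed = 9)
  dir <- withr::local_tempdir()
  expect_no_warning(write_synthetic_cohort(sc, dir))
  expect_no_warning(net <- load_edge_list(file.path(dir, "network.tsv")))
  expect_equal(edge_jaccard(net, sc$network), 1)
  expect_no_warning(rec <- read_maf(file.path(dir, "cohort.maf")))
  expect_equal(sort(unique(rec$sample)), sort(unique(sc$maf$Tumor_Sample_Barcode)))
  expect_no_warning(cna <- read_cna_matrix(file.path(dir, "cna_log2.tsv")))
  expect_equal(dim(cna), dim(sc$cna))
  expect_no_warning(col <- read_pathway_collection(
    file.path(dir, "pathways.gmt"), file.path(dir, "pathway_categories.tsv")))
  expect_identical(col$sets, sc$collection$sets)

  # label bookkeeping: every MAF record is labeled driver xor passenger
  key_maf <- paste(sc$maf$Tumor_Sample_Barcode, sc$maf$Hugo_Symbol)
  key_lab <- paste(sc$point_labels$sample, sc$point_labels$gene)
  expect_setequal(unique(key_maf), key_lab)
  expect_false(any(duplicated(key_lab)))
})

test_that("the whole study generation is reproducible from one seed", {
  a <- synthetic_cohort(n_nodes = 150, k_modules = 2, module_size = 6,
                        n_samples = 6, seed = 12)
  b <- synthetic_cohort(n_nodes = 150, k_modules = 2, module_size = 6,
                        n_samples = 6, seed = 12)
  expect_identical(a$maf, b$maf)
  expect_identical(a$cna, b$cna)
  expect_equal(edge_jaccard(a$network, b$network), 1)
})
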