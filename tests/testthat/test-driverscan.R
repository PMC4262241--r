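test_that("MAF parsing collapses per-sample duplicates and validates columns", {
  maf <- data.frame(Hugo_Symbol = c("TP53", "tp53", "PTEN", "EGFR"),
                    Tumor_Sample_Barcode = c("S1", "S1", "S1", "S2"),
                    Variant_Classification = c("Missense_Mutation", "Silent",
                                               "Nonsense_Mutation", "Silent"))
  rec <- read_maf(maf)
  expect_message(mgs <- build_mgs(rec), "collapsed 1")
  expect_setequal(mgs$S1, c("TP53", "PTEN"))
  expect_equal(mgs$S2, "EGFR")
  expect_length(mgs, 2)

  path <- withr::local_tempfile(fileext = ".maf")
  write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_maf(path), rec)

  expect_error(read_maf(data.frame(Tumor_Sample_Barcode = "S1")),
               "Hugo_Symbol")
})

test_that("CNA calling uses a strict absolute threshold and genome minimum", {
  mat <- rbind(ELIG = c(-0.4, -0.36, -0.5, 0.1),
               WEAK = c(-0.4, -0.2, 0.0, 0.0),
               EDGE = c(0.35, 0.35, 0.35, 0.35))
  colnames(mat) <- paste0("S", 1:4)
  cc <- call_cna(mat, tau = 0.35, min_genomes = 3)
  expect_equal(cc$eligible, "ELIG")
  expect_equal(sum(cc$calls$gene == "ELIG"), 3)
  expect_equal(sum(cc$calls$gene == "WEAK"), 1)
  expect_equal(sum(cc$calls$gene == "EDGE"), 0)  # strict >
  expect_equal(unique(cc$calls$direction[cc$calls$gene == "ELIG"]), "loss")

  path <- withr::local_tempfile(
    lines = c("gene\tS1\tS2", "G1\t0.5\tbad"))
  expect_error(read_cna_matrix(path), "G1.*S2")
})

test_that("small mutated gene sets are skipped, not imputed", {
  st <- tiny_study()
  ens <- nea_ensemble(st$network, n_rand = 8, seed = 1)
  mgs <- list(S1 = c(st$modules[[1]][1:2]),
              S2 = st$modules[[1]][1:6])
  # remaining MGS below the 3-gene rule -> not applicable
  expect_null(test_point_vs_mgs(ens, st$modules[[1]][1], "S1", mgs))
  # usable MGS: a module member is enriched against its partners
  res <- test_point_vs_mgs(ens, st$modules[[1]][1], "S2", mgs)
  expect_s3_class(res, "nea_result")
  expect_gt(res$z, 0)
  expect_error(test_point_vs_mgs(ens, "NOTMUT", "S2", mgs), "not mutated")
})

test_that("1CNA-vs-MGS combines one p per usable carrier genome", {
  st <- tiny_study()
  ens <- nea_ensemble(st$network, n_rand = 8, seed = 2)
  drv <- st$modules[[2]][1]
  mgs <- list(S1 = st$modules[[2]][2:7], S2 = st$modules[[2]][3:8],
              S3 = st$modules[[2]][2:3])  # S3 too small to use
  calls <- data.frame(gene = drv, sample = c("S1", "S2", "S3"),
                      log2 = 0.5, direction = "gain")
  out <- test_cna_vs_mgs(ens, drv, mgs, calls)
  expect_equal(nrow(out$per_genome), 2)
  expect_equal(out$combined$df, 4)
  expect_equal(out$combined$p, fisher_combine(out$per_genome$p)$p)
  # k = 1 identity when only one genome is usable
  out1 <- test_cna_vs_mgs(ens, drv, mgs["S1"], calls[1, ])
  expect_equal(out1$combined$p, out1$per_genome$p[1])
})

test_that("the normalized pathway test reduces to a plain NEA test", {
  st <- tiny_study()
  ens <- nea_ensemble(st$network, n_rand = 8, seed = 3)
  one <- pathway_collection(list(M1 = st$modules[[1]]), "CAN")
  gene <- st$modules[[2]][1]
  cpw <- test_vs_cpw(ens, gene, one, normalization_factor = 1)
  ref <- nea_gene_vs_set(ens, gene, st$modules[[1]])
  expect_equal(cpw$z, ref$z)
  expect_equal(cpw$p, ref$p)

  expect_equal(round(cpw_normalize(30.17), 2), 2.97)
  expect_error(cpw_normalize(1, normalization_factor = 0), "positive")
})

test_that("collection-specific normalization keeps module members significant", {
  st <- tiny_study()
  ens <- nea_ensemble(st$network, n_rand = 10, seed = 4)
  fac <- calibrate_cpw_factor(ens, st$collection, seed = 4)
  expect_gt(fac, 0)
  member <- st$modules[[1]][1]
  hit <- test_vs_cpw(ens, member, st$collection, normalization_factor = fac)
  expect_gt(hit$z, 2.97)
})

test_that("co-occurrence screening reproduces the printed 2x2 case", {
  samples <- sprintf("S%03d", 1:148)
  mgs <- c(lapply(samples[1:4], function(s) "MSH6"),
           list("OTHER"), lapply(samples[6:20], function(s) "NOISE"))
  names(mgs) <- samples[1:20]
  co <- cooccurrence_scan(list(FN1 = samples[1:5]), mgs, samples,
                          alpha = 0.01)
  row <- co$summary[co$summary$gene == "FN1", ]
  expect_equal(row$best_partner, "MSH6")
  expect_equal(row$min_p, 5 / choose(148, 4))
  expect_true(row$pass)
  expect_equal(row$p_co, min(1, row$min_p * row$n_partners))

  # a candidate present in every sample has a degenerate margin
  co2 <- cooccurrence_scan(list(EVR = samples), mgs, samples)
  expect_equal(co2$summary$min_p, 1)
  expect_false(co2$summary$pass)

  # self-pairs are skipped, not errors
  co3 <- cooccurrence_scan(list(MSH6 = samples[1:4]), mgs, samples)
  expect_false("MSH6" %in% co3$pairs$partner)
})

test_that("hierarchical combination drops missing components", {
  expect_equal(combine_point(NA, 0.03)$p, 0.03)
  expect_equal(combine_point(0.5, 0.5)$p,
               pchisq(-4 * log(0.5), 4, lower.tail = FALSE))
  expect_equal(combine_cna(1, 1, 1)$p, 1)
  expect_equal(combine_cna(0.2, NA, NA)$p, 0.2)
  cc <- combine_cna(0.01, 0.01, 0.01)
  expect_equal(cc$chi2, 27.63, tolerance = 1e-3)
  expect_equal(cc$df, 6)
  expect_equal(cc$p, 1.1e-4, tolerance = 0.02)
  expect_true(is.na(combine_point(NA, NA)$p))
})

test_that("BH ranking applies a strict threshold", {
  sc <- data.frame(combined_p = c(0.001, rep(1, 9)))
  out <- rank_and_adjust(sc, threshold = 0.01)
  expect_equal(out$adjusted_p[1], 0.01)
  expect_false(out$driver_call[1])  # boundary: 0.01 is not < 0.01

  expect_false(any(rank_and_adjust(data.frame(combined_p = rep(1, 5)))$driver_call))
  expect_true(rank_and_adjust(data.frame(combined_p = 0.001))$driver_call)
  expect_error(rank_and_adjust(data.frame(combined_p = numeric())), "empty")
})

test_that("reported combinations are reproducible and rows independent", {
  st <- tiny_study()
  cna <- matrix(rnorm(20 * 10, 0, 0.05), nrow = 20,
                dimnames = list(igraph::V(st$network)$name[1:20],
                                sprintf("SAMPLE_%03d", 1:10)))
  cna[1, 1:4] <- 0.6
  rep1 <- suppressMessages(suppressWarnings(
    driver_scan(st$network, st$cohort$maf, cna, st$collection,
                n_rand = 8, seed = 5, cpw_factor = NULL)))
  # round-trip audit: every combined p re-derives from its components
  for (r in seq_len(nrow(rep1$point))) {
    comp <- c(rep1$point$p_mgs[r], rep1$point$p_cpw[r])
    expect_equal(rep1$point$combined_p[r], combine_components(comp)$p)
  }
  if (!is.null(rep1$cna)) {
    for (r in seq_len(nrow(rep1$cna))) {
      comp <- c(rep1$cna$p_co[r], rep1$cna$p_mgs_combined[r],
                rep1$cna$p_cpw[r])
      expect_equal(rep1$cna$combined_p[r], combine_components(comp)$p)
    }
  }
  # removing the CNA component entirely leaves point scores untouched
  rep2 <- suppressMessages(suppressWarnings(
    driver_scan(st$network, st$cohort$maf, NULL, st$collection,
                n_rand = 8, seed = 5, cpw_factor = NULL)))
  m <- match(rep1$point$event_id, rep2$point$event_id)
  expect_equal(rep1$point$combined_p, rep2$point$combined_p[m])

  # report writing
  dir <- withr::local_tempdir()
  write_driver_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("point_drivers.tsv", "gene_track.tsv", "mgs_coherence.tsv")))))
  back <- read.delim(file.path(dir, "point_drivers.tsv"))
  expect_equal(nrow(back), nrow(rep1$point))
})
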