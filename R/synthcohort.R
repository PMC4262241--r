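# Synthetic fixtures with known ground truth: a scale-free-ish network with
# planted dense pathway modules, cohorts of per-sample mutated gene sets
# containing planted drivers drawn from the modules plus random passengers,
# and log2 copy-number matrices with contiguous altered segments each
# containing one planted CNA driver. The generator targets the statistical
# structure the enrichment tests assume (drivers are network-adjacent to
# co-mutated genes and to cancer modules; passengers are degree-random),
# not real mutation spectra.

synth_gene_names <- function(n) sprintf("G%06d", seq_len(n))
synth_sample_ids <- function(n) sprintf("SAMPLE_%03d", seq_len(n))

#' Generate a random gene network
#'
#' Erdos-Renyi (`"ER"`) or Barabasi-Albert preferential attachment (`"BA"`,
#' heavy-tailed degrees, the regime of real interactomes) with the requested
#' mean degree. Deterministic per seed; genes named `G000001...`.
#'
#' @param n_nodes Number of genes (>= 10).
#' @param mean_degree Target mean degree (>= 2).
#' @param model `"ER"` or `"BA"`.
#' @param seed Integer seed.
#' @return A gene network.
#' @export
gen_network <- function(n_nodes, mean_degree, model = c("ER", "BA"),
                        seed = 1) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 10, mean_degree >= 2)
  net <- withr::with_seed(seed, {
    if (model == "ER") {
      igraph::sample_gnm(n_nodes, round(n_nodes * mean_degree / 2))
    } else {
      igraph::sample_pa(n_nodes, m = max(1L, round(mean_degree / 2)),
                        directed = FALSE)
    }
  })
  net <- igraph::simplify(net)
  igraph::V(net)$name <- synth_gene_names(n_nodes)
  assert_gene_network(net)
}

#' Plant dense pathway modules into a network
#'
#' Selects `k_modules` disjoint member sets of size `module_size` and adds
#' each within-module edge with probability `p_intra` (existing edges are
#' kept). Returns the augmented network and the modules as a CAN-tagged
#' pathway collection whose union forms the designated super-pathway.
#'
#' @param net A gene network.
#' @param k_modules Number of modules.
#' @param module_size Genes per module.
#' @param p_intra Intra-module edge probability in (0, 1].
#' @param seed Integer seed.
#' @return List with `network` (augmented), `collection`
#'   (a [pathway_collection()]), and `modules` (named list of members).
#' @export
plant_modules <- function(net, k_modules = 5, module_size = 15,
                          p_intra = 0.6, seed = 1) {
  assert_gene_network(net)
  stopifnot(p_intra > 0, p_intra <= 1,
            k_modules * module_size <= igraph::vcount(net))
  withr::with_seed(seed, {
    members <- sample(igraph::V(net)$name, k_modules * module_size)
    modules <- split(members, rep(seq_len(k_modules), each = module_size))
    names(modules) <- sprintf("MODULE_%02d", seq_len(k_modules))
    new_edges <- do.call(rbind, lapply(modules, function(g) {
      pairs <- t(utils::combn(g, 2L))
      pairs[stats::runif(nrow(pairs)) < p_intra, , drop = FALSE]
    }))
  })
  aug <- igraph::add_edges(net, t(new_edges))
  aug <- igraph::simplify(aug)
  sets <- c(modules, list(CAN_SUPER = unname(unlist(modules))))
  list(network = assert_gene_network(aug),
       collection = pathway_collection(sets, "CAN", super = "CAN_SUPER"),
       modules = modules)
}

#' Generate a point-mutation cohort with planted drivers
#'
#' Per sample, `drivers_per_sample` driver genes are drawn from one or two
#' planted modules and `passengers_per_sample` passengers are drawn
#' uniformly from non-module genes. Emits MAF-style records and a
#' per-event truth table.
#'
#' @param truth Output of [plant_modules()] (network + modules).
#' @param n_samples Number of tumor samples.
#' @param drivers_per_sample,passengers_per_sample Event counts per sample.
#' @param seed Integer seed.
#' @return List with `maf` (data.frame: Hugo_Symbol, Tumor_Sample_Barcode,
#'   Variant_Classification) and `labels` (sample, gene, label).
#' @export
gen_cohort <- function(truth, n_samples = 50, drivers_per_sample = 5,
                       passengers_per_sample = 20, seed = 1) {
  stopifnot(drivers_per_sample >= 0, passengers_per_sample >= 0)
  modules <- truth$modules
  module_genes <- unlist(modules)
  background <- setdiff(igraph::V(truth$network)$name, module_genes)
  samples <- synth_sample_ids(n_samples)
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Silent",
               "Frame_Shift_Del")
  withr::with_seed(seed, {
    rows <- lapply(samples, function(s) {
      k <- sample(min(2L, length(modules)), 1L)
      pool <- unlist(modules[sample(length(modules), k)])
      drv <- sample(pool, min(drivers_per_sample, length(pool)))
      pas <- sample(background, passengers_per_sample)
      genes <- c(drv, pas)
      data.frame(sample = s, gene = genes,
                 label = rep(c("driver", "passenger"),
                             c(length(drv), length(pas))),
                 vc = sample(classes, length(genes), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, rows)
  list(maf = data.frame(Hugo_Symbol = tab$gene,
                        Tumor_Sample_Barcode = tab$sample,
                        Variant_Classification = tab$vc,
                        stringsAsFactors = FALSE),
       labels = tab[, c("sample", "gene", "label")])
}

#' Generate log2 copy-number profiles with planted driver segments
#'
#' Genes are laid out on a synthetic chromosome; for each planted module,
#' one contiguous segment of `segment_length` genes containing exactly one
#' module gene (the planted CNA driver) is shifted by +/-`amplitude` in
#' carrier samples, on top of Gaussian noise everywhere. Carrier samples
#' also receive correlated point mutations in two of the driver's module
#' partners, so that co-occurrence with point mutations is detectable.
#'
#' @param truth Output of [plant_modules()].
#' @param n_samples Number of samples (matching the cohort).
#' @param segment_length Genes per altered segment (>= 3).
#' @param amplitude Absolute log2 shift in carriers (> 0.35 so planted
#'   segments are callable at the default threshold).
#' @param noise_sd Gaussian noise standard deviation.
#' @param carrier_fraction Fraction of samples carrying each segment.
#' @param n_null_genes Extra unaltered background genes in the matrix.
#' @param partner_rate Probability that a carrier sample receives a point
#'   mutation in each designated module partner of the driver (default 0.8).
#' @param seed Integer seed.
#' @return List with `profile` (gene x sample log2 matrix), `labels`
#'   (gene, segment, is_driver), `segments` (named list of segment genes),
#'   `extra_maf` (correlated point-mutation records to append to the
#'   cohort MAF), and `extra_labels`.
#' @export
gen_cna_profiles <- function(truth, n_samples = 50, segment_length = 10,
                             amplitude = 0.5, noise_sd = 0.1,
                             carrier_fraction = 0.2, n_null_genes = 50,
                             partner_rate = 0.8, seed = 1) {
  stopifnot(segment_length >= 3)
  modules <- truth$modules
  module_genes <- unlist(modules)
  background <- setdiff(igraph::V(truth$network)$name, module_genes)
  samples <- synth_sample_ids(n_samples)
  n_carrier <- max(1L, round(carrier_fraction * n_samples))

  withr::with_seed(seed, {
    flank <- sample(background,
                    length(modules) * (segment_length - 1L) + n_null_genes)
    segments <- list()
    drivers <- character(length(modules))
    pos <- 0L
    for (k in seq_along(modules)) {
      drivers[k] <- sample(modules[[k]], 1L)
      seg_flank <- flank[pos + seq_len(segment_length - 1L)]
      pos <- pos + segment_length - 1L
      # driver sits inside the contiguous run of background genes
      at <- sample(segment_length, 1L)
      segments[[names(modules)[k]]] <- append(seg_flank, drivers[k],
                                              after = at - 1L)
    }
    null_genes <- flank[pos + seq_len(n_null_genes)]
    genes <- c(unlist(segments), null_genes)
    profile <- matrix(stats::rnorm(length(genes) * n_samples, 0, noise_sd),
                      nrow = length(genes),
                      dimnames = list(genes, samples))
    extra <- list()
    for (k in seq_along(segments)) {
      carriers <- sample(samples, n_carrier)
      sign_k <- sample(c(-1, 1), 1L)
      profile[segments[[k]], carriers] <-
        profile[segments[[k]], carriers] + sign_k * amplitude
      # partners are module genes functionally coupled to the driver: the
      # co-occurring point mutations a CNA driver accumulates are in its
      # own network neighborhood, which is what makes it recoverable
      nb <- intersect(
        igraph::neighbors(truth$network, drivers[k])$name,
        setdiff(modules[[k]], drivers[k]))
      if (length(nb) < 2L) nb <- setdiff(modules[[k]], drivers[k])
      partners <- sample(nb, 2L)
      for (s in carriers) {
        mut <- partners[stats::runif(2L) < partner_rate]
        if (length(mut))
          extra[[paste(k, s)]] <- data.frame(
            Hugo_Symbol = mut, Tumor_Sample_Barcode = s,
            Variant_Classification = "Missense_Mutation",
            stringsAsFactors = FALSE)
      }
    }
  })
  extra_maf <- if (length(extra)) do.call(rbind, extra) else NULL
  if (!is.null(extra_maf)) rownames(extra_maf) <- NULL
  labels <- data.frame(
    gene = unlist(segments, use.names = FALSE),
    segment = rep(names(segments), lengths(segments)),
    is_driver = unlist(segments, use.names = FALSE) %in% drivers,
    stringsAsFactors = FALSE)
  labels <- rbind(labels,
                  data.frame(gene = null_genes, segment = NA_character_,
                             is_driver = FALSE, stringsAsFactors = FALSE))
  extra_labels <- if (is.null(extra_maf)) NULL else
    data.frame(sample = extra_maf$Tumor_Sample_Barcode,
               gene = extra_maf$Hugo_Symbol, label = "driver",
               stringsAsFactors = FALSE)
  list(profile = profile, labels = labels, segments = segments,
       drivers = drivers, extra_maf = extra_maf,
       extra_labels = extra_labels)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Default scenario: a 1000-node Barabasi-Albert network (mean degree ~6)
#' with 5 planted modules of 15 genes at intra-module edge probability 0.6;
#' 50 samples with 5 planted drivers plus 20 passengers each; and CNA
#' profiles with one callable driver segment per module plus correlated
#' point mutations in carrier samples.
#'
#' @param n_nodes,mean_degree,model Network settings (see [gen_network()]).
#' @param k_modules,module_size,p_intra Module settings
#'   (see [plant_modules()]).
#' @param n_samples,drivers_per_sample,passengers_per_sample Cohort settings.
#' @param segment_length,amplitude,noise_sd,carrier_fraction CNA settings.
#' @param seed Master seed; all stages derive their own stream from it.
#' @return List with `network`, `collection`, `modules`, `maf`,
#'   `point_labels`, `cna` (log2 matrix), `cna_labels`, `segments`,
#'   `cna_drivers`, and `params`.
#' @export
synthetic_cohort <- function(n_nodes = 1000, mean_degree = 6, model = "BA",
                             k_modules = 5, module_size = 15, p_intra = 0.6,
                             n_samples = 50, drivers_per_sample = 5,
                             passengers_per_sample = 20,
                             segment_length = 10, amplitude = 0.5,
                             noise_sd = 0.1, carrier_fraction = 0.2,
                             seed = 1) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  base <- gen_network(n_nodes, mean_degree, model, seed = seeds[1L])
  truth <- plant_modules(base, k_modules, module_size, p_intra,
                         seed = seeds[2L])
  cohort <- gen_cohort(truth, n_samples, drivers_per_sample,
                       passengers_per_sample, seed = seeds[3L])
  cna <- gen_cna_profiles(truth, n_samples, segment_length, amplitude,
                          noise_sd, carrier_fraction, seed = seeds[4L])
  maf <- rbind(cohort$maf, cna$extra_maf)
  point_labels <- unique(rbind(cohort$labels, cna$extra_labels))
  # a gene injected as a correlated driver partner takes precedence over a
  # coincidental passenger draw of the same (sample, gene) event
  key <- paste(point_labels$sample, point_labels$gene)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  point_labels <- point_labels[!(dup & point_labels$label == "passenger"), ]
  point_labels <- unique(point_labels)
  list(network = truth$network, collection = truth$collection,
       modules = truth$modules, maf = maf, point_labels = point_labels,
       cna = cna$profile, cna_labels = cna$labels,
       segments = cna$segments, cna_drivers = cna$drivers,
       params = list(n_nodes = n_nodes, mean_degree = mean_degree,
                     model = model, k_modules = k_modules,
                     module_size = module_size, p_intra = p_intra,
                     n_samples = n_samples,
                     drivers_per_sample = drivers_per_sample,
                     passengers_per_sample = passengers_per_sample,
                     segment_length = segment_length,
                     amplitude = amplitude, noise_sd = noise_sd,
                     carrier_fraction = carrier_fraction, seed = seed))
}

#' Write a synthetic study to disk
#'
#' Writes the network edge list, the pathway GMT plus category manifest, the
#' cohort MAF, the CNA log2 matrix, and the truth labels as plain-text files.
#'
#' @param sc A [synthetic_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(sc$network, file.path(dir, "network.tsv"))
  write_pathway_collection(sc$collection, file.path(dir, "pathways.gmt"),
                           file.path(dir, "pathway_categories.tsv"))
  utils::write.table(sc$maf, file.path(dir, "cohort.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cna <- data.frame(gene = rownames(sc$cna), sc$cna, check.names = FALSE)
  utils::write.table(cna, file.path(dir, "cna_log2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sc$point_labels, file.path(dir, "point_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sc$cna_labels, file.path(dir, "cna_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Area under the driver-vs-passenger ROC from combined p-values
#'
#' Rank-based AUROC (Mann-Whitney statistic) of planted drivers against
#' passengers, ranking events by combined p-value (smaller = more driver-like).
#'
#' @param p Combined p-values (NA allowed; NA ranks worst).
#' @param is_driver Logical truth labels, same length.
#' @return AUROC in \[0, 1\].
#' @export
driver_auroc <- function(p, is_driver) {
  stopifnot(length(p) == length(is_driver))
  score <- -ifelse(is.na(p), Inf, log(pmax(p, 1e-300)))  # larger = better
  score[is.na(p)] <- -Inf
  r <- rank(score)
  n1 <- sum(is_driver); n0 <- sum(!is_driver)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  (sum(r[is_driver]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
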