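# Orchestration of the full scan: one randomization ensemble per network
# serves every test; point events and CNA genes are scored, combined,
# ranked, and written as TSV reports.

#' Run the full driver-prioritization scan on a cohort
#'
#' Executes, against one global network, the three parallel network
#' enrichment tests (1point-vs-MGS per point mutation; 1CNA-vs-MGS and the
#' co-occurrence screen per eligible CNA gene; 1-vs-CPW per gene), combines
#' each event's available p-values with Fisher's method, and ranks events
#' under Benjamini-Hochberg control within each event class.
#'
#' @param network A gene network (igraph) or an edge-list file path.
#' @param maf MAF data.frame/path (see [read_maf()]).
#' @param cna Optional gene x sample log2 matrix or TSV path.
#' @param collection A [pathway_collection()] (used for the 1-vs-CPW test).
#' @param n_rand Number of network randomizations (default 25).
#' @param seed Master seed for the randomization ensemble.
#' @param swap_factor Rewiring swap trials per edge (default 100).
#' @param mode Link metric, `"direct"` or `"shared"`.
#' @param min_mgs Minimum mapped MGS size for MGS-based tests (default 3).
#' @param cpw_factor,cpw_z_cutoff,cpw_mode,floor_negative 1-vs-CPW settings
#'   (see [test_vs_cpw()]).
#' @param cna_tau,min_genomes CNA call settings (see [call_cna()]).
#' @param alpha_co Raw-p threshold of the co-occurrence screen (default 0.01).
#' @param fdr_threshold Adjusted-p driver-call threshold (default 0.01).
#' @param ensemble Optional pre-built [nea_ensemble()] (overrides `network`,
#'   `n_rand`, `seed`, `swap_factor`).
#' @return Object of class `driver_report`: list with `point` and `cna`
#'   ranked score tables, `track` (per-gene -log10 combined p), `coherence`
#'   (per-sample MGS coherence results), and `params`.
#' @export
driver_scan <- function(network, maf, cna = NULL, collection,
                        n_rand = 25, seed = 1, swap_factor = 100,
                        mode = "direct", min_mgs = 3,
                        cpw_factor = 10.16, cpw_z_cutoff = 2.97,
                        cpw_mode = "sum_all_can", floor_negative = FALSE,
                        cna_tau = 0.35, min_genomes = 3, alpha_co = 0.01,
                        fdr_threshold = 0.01, ensemble = NULL) {
  if (is.null(ensemble)) {
    if (is.character(network)) network <- load_edge_list(network)
    ensemble <- nea_ensemble(network, n_rand = n_rand, seed = seed,
                             swap_factor = swap_factor)
  }
  if (is.null(cpw_factor))  # calibrate for this collection (see vignette)
    cpw_factor <- calibrate_cpw_factor(ensemble, collection, seed = seed)
  idx <- ensemble$real
  records <- read_maf(maf)
  mgs <- build_mgs(records)

  ## 1-vs-CPW profile, cached per unique gene
  events <- unique(records[, c("sample", "gene")])
  cpw_genes <- unique(events$gene)

  ## point events: 1point-vs-MGS per (sample, gene)
  point_rows <- vector("list", length(mgs))
  names(point_rows) <- names(mgs)
  for (s in names(mgs)) {
    genes <- mgs[[s]]
    ids <- gene_ids(idx, genes)
    ok <- !is.na(ids)
    rows <- data.frame(sample = s, gene = genes, n_iG = NA_real_,
                       z_mgs = NA_real_, p_mgs = NA_real_,
                       mgs_size = length(genes), stringsAsFactors = FALSE)
    rs <- resolve_set(idx, genes)
    if (any(ok)) {
      # each gene is tested against the rest of its own MGS; batch_nea
      # excludes the query from the membership vector, so the >= min_mgs
      # rule is on the remaining mapped members
      remaining <- rs$n_mapped - 1L
      if (remaining >= min_mgs) {
        res <- batch_nea(ensemble, ids[ok], rs$ids, mode = mode)
        rows$n_iG[ok] <- res$observed
        rows$z_mgs[ok] <- res$z
        rows$p_mgs[ok] <- res$p
      }
    }
    point_rows[[s]] <- rows
  }
  point <- do.call(rbind, point_rows)
  rownames(point) <- NULL

  cpw <- cpw_profile(ensemble, cpw_genes, collection,
                     normalization_factor = cpw_factor,
                     z_cutoff = cpw_z_cutoff, cpw_mode = cpw_mode,
                     mode = mode, floor_negative = floor_negative)
  point$z_cpw <- cpw$z[match(point$gene, cpw$gene)]
  point$p_cpw <- cpw$p[match(point$gene, cpw$gene)]

  comb <- mapply(function(pm, pc) {
    cc <- combine_point(pm, pc)
    c(cc$chi2, cc$df, cc$p)
  }, point$p_mgs, point$p_cpw)
  point$chi2 <- comb[1L, ]
  point$df <- as.integer(comb[2L, ])
  point$combined_p <- comb[3L, ]
  point$event_id <- paste(point$gene, point$sample, sep = "@")
  point <- rank_and_adjust(point, threshold = fdr_threshold)

  ## per-sample MGS coherence (descriptive companion statistic)
  coherence <- do.call(rbind, lapply(names(mgs), function(s) {
    if (resolve_set(idx, mgs[[s]])$n_mapped < max(2L, min_mgs))
      return(data.frame(sample = s, n_genes = length(mgs[[s]]),
                        z = NA_real_, p = NA_real_))
    r <- nea_set_coherence(ensemble, mgs[[s]], mode = mode)
    data.frame(sample = s, n_genes = length(mgs[[s]]), z = r$z, p = r$p)
  }))

  ## CNA genes
  cna_tab <- NULL
  if (!is.null(cna)) {
    profile <- if (is.matrix(cna)) cna else read_cna_matrix(cna)
    cc <- call_cna(profile, tau = cna_tau, min_genomes = min_genomes)
    shared_samples <- intersect(names(mgs), colnames(profile))
    if (length(cc$eligible) > 0L && length(shared_samples) >= 2L) {
      carriers <- lapply(cc$eligible, function(g)
        intersect(cc$calls$sample[cc$calls$gene == g], shared_samples))
      names(carriers) <- cc$eligible
      co <- cooccurrence_scan(carriers, mgs, shared_samples,
                              alpha = alpha_co)
      cna_cpw <- cpw_profile(ensemble, cc$eligible, collection,
                             normalization_factor = cpw_factor,
                             z_cutoff = cpw_z_cutoff, cpw_mode = cpw_mode,
                             mode = mode, floor_negative = floor_negative)
      rows <- lapply(cc$eligible, function(g) {
        mg <- test_cna_vs_mgs(ensemble, g, mgs, cc$calls,
                              mode = mode, min_mgs = min_mgs)
        srow <- co$summary[co$summary$gene == g, , drop = FALSE]
        p_co <- if (nrow(srow)) srow$p_co else NA_real_
        co_pass <- if (nrow(srow)) srow$pass else FALSE
        p_mgs_c <- if (is.null(mg)) NA_real_ else mg$combined$p
        z_cpw <- cna_cpw$z[cna_cpw$gene == g]
        p_cpw <- cna_cpw$p[cna_cpw$gene == g]
        cmb <- combine_cna(p_co, p_mgs_c, p_cpw)
        data.frame(gene = g,
                   n_carriers = length(carriers[[g]]),
                   n_own_mgs = if (is.null(mg)) 0L else nrow(mg$per_genome),
                   p_co = p_co, co_pass = co_pass,
                   p_mgs_combined = p_mgs_c,
                   z_cpw = z_cpw, p_cpw = p_cpw,
                   chi2 = cmb$chi2, df = cmb$df, combined_p = cmb$p,
                   stringsAsFactors = FALSE)
      })
      cna_tab <- do.call(rbind, rows)
      cna_tab <- rank_and_adjust(cna_tab, threshold = fdr_threshold)
      # the screen is a hard gate: candidates failing it are never called
      cna_tab$driver_call <- cna_tab$driver_call & cna_tab$co_pass
      cna_tab$event_id <- paste0("CNA:", cna_tab$gene)
    }
  }

  ## per-gene track: best combined p across an event class
  best_p <- c(tapply(point$combined_p, point$gene, min, na.rm = FALSE),
              if (!is.null(cna_tab))
                tapply(cna_tab$combined_p, cna_tab$gene, min))
  best_p <- tapply(unlist(best_p), names(best_p), min)
  track <- data.frame(gene = names(best_p),
                      neg_log10_combined_p = -log10(as.numeric(best_p)))
  track <- track[order(-track$neg_log10_combined_p), ]
  rownames(track) <- NULL

  structure(list(point = point, cna = cna_tab, track = track,
                 coherence = coherence,
                 params = list(n_rand = ensemble$n_rand,
                               seed = ensemble$seed,
                               swap_factor = ensemble$swap_factor,
                               mode = mode, min_mgs = min_mgs,
                               cpw_factor = cpw_factor,
                               cpw_z_cutoff = cpw_z_cutoff,
                               cpw_mode = cpw_mode, cna_tau = cna_tau,
                               min_genomes = min_genomes,
                               alpha_co = alpha_co,
                               fdr_threshold = fdr_threshold)),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, ...) {
  cat(sprintf("Driver scan: %d point events (%d called)",
              nrow(x$point), sum(x$point$driver_call)))
  if (!is.null(x$cna))
    cat(sprintf("; %d CNA genes (%d called)",
                nrow(x$cna), sum(x$cna$driver_call)))
  cat("\n")
  invisible(x)
}

#' Write a driver report as TSV files
#'
#' Writes `point_drivers.tsv`, `cna_drivers.tsv` (if present),
#' `gene_track.tsv`, and `mgs_coherence.tsv` into `dir`.
#'
#' @param report A [driver_scan()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_driver_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$point, "point_drivers.tsv")
  if (!is.null(report$cna)) wt(report$cna, "cna_drivers.tsv")
  wt(report$track, "gene_track.tsv")
  wt(report$coherence, "mgs_coherence.tsv")
  invisible(dir)
}
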