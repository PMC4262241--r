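# End-to-end driver prioritization: cohort parsing, the three parallel NEA
# tests, the co-occurrence screen, hierarchical Fisher combination, and
# Benjamini-Hochberg ranking.

#' Read somatic point mutations from a MAF-style table
#'
#' Tab-separated with a header containing at least `Hugo_Symbol` and
#' `Tumor_Sample_Barcode`. All records are kept irrespective of their
#' `Variant_Classification` label (the label is retained, never filtered on).
#'
#' @param path MAF file path (or a data.frame already holding the columns).
#' @return data.frame with columns `sample`, `gene`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  tab <- if (is.data.frame(path)) path
         else as.data.frame(data.table::fread(path, sep = "\t",
                                              header = TRUE,
                                              showProgress = FALSE))
  for (col in c("Hugo_Symbol", "Tumor_Sample_Barcode"))
    if (!col %in% names(tab))
      stop(sprintf("MAF is missing required column '%s'", col), call. = FALSE)
  vc <- if ("Variant_Classification" %in% names(tab))
    as.character(tab$Variant_Classification) else NA_character_
  out <- data.frame(sample = as.character(tab$Tumor_Sample_Barcode),
                    gene = toupper(as.character(tab$Hugo_Symbol)),
                    variant_classification = vc,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$sample)) || any(!nzchar(out$gene)))
    stop("MAF contains empty sample barcodes or gene symbols", call. = FALSE)
  out
}

#' Build per-sample mutated gene sets (MGS)
#'
#' Multiple mutations in the same gene are collapsed into one case per
#' sample; the number of collapsed records is reported via `message()`.
#'
#' @param records Output of [read_maf()].
#' @return Named list: sample barcode -> character vector of mutated genes.
#' @export
build_mgs <- function(records) {
  mgs <- lapply(split(records$gene, records$sample), unique)
  n_collapsed <- nrow(records) - sum(lengths(mgs))
  if (n_collapsed > 0)
    message(sprintf("collapsed %d duplicate gene records across samples",
                    n_collapsed))
  mgs
}

#' Read a gene x sample matrix of log2 copy-number values
#'
#' First column holds gene symbols; remaining columns are samples. Every
#' data cell must be numeric.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes as rows (uppercased), samples as columns.
#' @export
read_cna_matrix <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         showProgress = FALSE))
  genes <- toupper(as.character(tab[[1L]]))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric copy-number value at gene '%s', sample '%s'",
                   genes[bad], names(vals)[j]), call. = FALSE)
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  mat
}

#' Call copy-number alterations from a log2 matrix
#'
#' A call is made where `|log2| > tau` (strictly); a gene is eligible for
#' driver analysis when it is called in at least `min_genomes` samples.
#'
#' @param profile Numeric gene x sample matrix of log2 copy-number values.
#' @param tau Call threshold on `|log2|` (default 0.35).
#' @param min_genomes Minimum number of called genomes for eligibility
#'   (default 3).
#' @return List with `calls` (data.frame: gene, sample, log2, direction) and
#'   `eligible` (character vector of genes).
#' @export
call_cna <- function(profile, tau = 0.35, min_genomes = 3) {
  stopifnot(is.matrix(profile), is.numeric(profile))
  hit <- which(abs(profile) > tau, arr.ind = TRUE)
  calls <- data.frame(
    gene = rownames(profile)[hit[, 1L]],
    sample = colnames(profile)[hit[, 2L]],
    log2 = profile[hit],
    direction = ifelse(profile[hit] > 0, "gain", "loss"),
    stringsAsFactors = FALSE)
  counts <- table(calls$gene)
  list(calls = calls,
       eligible = names(counts)[counts >= min_genomes])
}

#' 1point-vs-MGS: test one point mutation against the rest of its sample's
#' mutated gene set
#'
#' Runs the NEA gene-vs-set test of `gene` against `Mgs(sample) \\ gene`.
#' Samples whose remaining MGS maps fewer than `min_mgs` genes to the
#' network are not amenable to this test: `NULL` is returned and the
#' component is simply left out of the downstream combination (a gene can
#' still be called through the pathway test).
#'
#' @param ensemble An [nea_ensemble()].
#' @param gene Mutated gene symbol.
#' @param sample Sample barcode.
#' @param mgs Named list of per-sample mutated gene sets ([build_mgs()]).
#' @param mode Link metric.
#' @param min_mgs Minimum mapped MGS size after removing `gene` (default 3).
#' @return An `nea_result`, or `NULL` when the test is not applicable.
#' @export
test_point_vs_mgs <- function(ensemble, gene, sample, mgs,
                              mode = "direct", min_mgs = 3) {
  gene <- toupper(gene)
  if (!sample %in% names(mgs) || !gene %in% mgs[[sample]])
    stop(sprintf("gene '%s' is not mutated in sample '%s'", gene, sample),
         call. = FALSE)
  target <- setdiff(mgs[[sample]], gene)
  idx <- ensemble$real
  if (is.na(gene_ids(idx, gene))) return(NULL)
  if (resolve_set(idx, target)$n_mapped < min_mgs) return(NULL)
  nea_gene_vs_set(ensemble, gene, target, mode = mode)
}

#' 1CNA-vs-MGS: test a copy-number-altered gene against the mutated gene
#' sets of its carrier genomes
#'
#' For each genome in which `gene` carries a CNA call and whose MGS maps at
#' least `min_mgs` genes, the NEA gene-vs-set test is run; the per-genome
#' one-sided p-values are combined by Fisher's method (df = 2 x number of
#' usable genomes).
#'
#' @inheritParams test_point_vs_mgs
#' @param calls CNA calls as returned in `call_cna()$calls`.
#' @return List with `per_genome` (data.frame: sample, observed, z, p) and
#'   `combined` (a `combined_p`), or `NULL` when no genome is usable.
#' @export
test_cna_vs_mgs <- function(ensemble, gene, mgs, calls,
                            mode = "direct", min_mgs = 3) {
  gene <- toupper(gene)
  idx <- ensemble$real
  gid <- gene_ids(idx, gene)
  if (is.na(gid)) return(NULL)
  carriers <- unique(calls$sample[calls$gene == gene])
  carriers <- intersect(carriers, names(mgs))
  rows <- list()
  for (s in carriers) {
    target <- setdiff(mgs[[s]], gene)
    rs <- resolve_set(idx, target)
    if (rs$n_mapped < min_mgs) next
    res <- batch_nea(ensemble, gid, rs$ids, mode = mode)
    rows[[s]] <- data.frame(sample = s, observed = res$observed,
                            z = res$z, p = res$p)
  }
  if (length(rows) == 0L) return(NULL)
  per_genome <- do.call(rbind, rows)
  rownames(per_genome) <- NULL
  list(per_genome = per_genome, combined = fisher_combine(per_genome$p))
}

#' Normalize a summed 1-vs-CPW z-score
#'
#' The per-pathway NEA z-scores in the cancer-pathway (CAN) collection are
#' strongly correlated, so their plain sum overstates significance. The sum
#' is divided by a regularization factor (default 10.16, the linear-fit
#' coefficient of the super-pathway score against the summed scores of the
#' other cancer pathways), putting it back on an interpretable z scale:
#' 30.17 / 10.16 = 2.97 is the default significance cutoff.
#'
#' @param z_sum Summed per-pathway z-score(s).
#' @param normalization_factor Positive divisor (default 10.16).
#' @return Normalized z-score(s).
#' @export
cpw_normalize <- function(z_sum, normalization_factor = 10.16) {
  if (normalization_factor <= 0)
    stop("normalization_factor must be positive", call. = FALSE)
  z_sum / normalization_factor
}

#' Calibrate the 1-vs-CPW normalization factor for a collection
#'
#' The summed per-pathway z-score is regularized by a factor defined as the
#' slope of the no-intercept linear fit of the summed CAN z-scores on the
#' super-pathway z-score, so that the normalized sum lands back on the
#' interpretable single-test z scale. The default factor 10.16 was derived
#' this way for a large overlapping cancer-pathway collection; collections
#' with different size and overlap structure need their own calibration,
#' which this function performs over a panel of probe genes (all mapped
#' super-pathway members plus an equal number of random non-members).
#'
#' @param ensemble An [nea_ensemble()].
#' @param collection A [pathway_collection()] with a designated super-pathway.
#' @param n_background Number of random non-member probe genes (default: as
#'   many as there are mapped super-pathway members).
#' @param mode Link metric.
#' @param seed Seed for the background probe draw.
#' @return The calibrated positive factor.
#' @export
calibrate_cpw_factor <- function(ensemble, collection, n_background = NULL,
                                 mode = "direct", seed = 1) {
  if (is.null(collection$super))
    stop("calibration needs a designated super-pathway", call. = FALSE)
  idx <- ensemble$real
  super <- collection$sets[[collection$super]]
  members <- super[!is.na(gene_ids(idx, super))]
  if (is.null(n_background)) n_background <- length(members)
  pool <- setdiff(idx$names, toupper(super))
  bg <- withr::with_seed(seed,
    sample(pool, min(n_background, length(pool))))
  probes <- c(members, bg)
  sum_tab <- cpw_profile(ensemble, probes, collection,
                         normalization_factor = 1, cpw_mode = "sum_all_can",
                         mode = mode)
  super_tab <- cpw_profile(ensemble, probes, collection,
                           cpw_mode = "superpathway_only", mode = mode)
  fit <- stats::lm(sum_tab$z ~ 0 + super_tab$z)
  factor <- unname(stats::coef(fit)[1L])
  if (!is.finite(factor) || factor <= 0)
    stop("calibration failed: non-positive fitted factor", call. = FALSE)
  factor
}

#' 1-vs-CPW: test a gene against the cancer-pathway collection
#'
#' In `"sum_all_can"` mode the gene is tested against every CAN-category set
#' (excluding the designated super-pathway, which the normalization factor
#' was calibrated against), the per-set z-scores are summed, divided by
#' `normalization_factor`, and converted to a one-sided p-value. In
#' `"superpathway_only"` mode a single plain NEA test against the
#' super-pathway is used and the factor is not applied.
#'
#' @inheritParams test_point_vs_mgs
#' @param collection A [pathway_collection()] with a non-empty CAN category.
#' @param normalization_factor Divisor for the summed z (default 10.16).
#' @param z_cutoff Normalized-z significance cutoff (default 2.97).
#' @param cpw_mode `"sum_all_can"` or `"superpathway_only"`.
#' @param floor_negative Floor negative per-set z-scores at 0 before summing
#'   (default `FALSE`: negative contributions are kept).
#' @return List with `z` (normalized), `p`, `significant`, and `per_set`
#'   (named per-pathway z-scores; `NULL` in super-pathway mode).
#' @export
test_vs_cpw <- function(ensemble, gene, collection,
                        normalization_factor = 10.16, z_cutoff = 2.97,
                        cpw_mode = c("sum_all_can", "superpathway_only"),
                        mode = "direct", floor_negative = FALSE) {
  cpw_mode <- match.arg(cpw_mode)
  gene <- toupper(gene)
  if (is.na(gene_ids(ensemble$real, gene)))
    stop(sprintf("gene '%s' is not in the network", gene), call. = FALSE)
  tab <- cpw_profile(ensemble, gene, collection,
                     normalization_factor = normalization_factor,
                     z_cutoff = z_cutoff, cpw_mode = cpw_mode, mode = mode,
                     floor_negative = floor_negative)
  list(z = tab$z[1L], p = tab$p[1L], significant = tab$significant[1L],
       per_set = attr(tab, "per_set"))
}

# Vectorized 1-vs-CPW over many genes; one membership vector per pathway is
# shared across all genes and replicas. Genes absent from the network get NA.
cpw_profile <- function(ensemble, genes, collection,
                        normalization_factor = 10.16, z_cutoff = 2.97,
                        cpw_mode = "sum_all_can", mode = "direct",
                        floor_negative = FALSE) {
  genes <- toupper(genes)
  idx <- ensemble$real
  ids <- gene_ids(idx, genes)
  ok <- !is.na(ids)
  if (cpw_mode == "superpathway_only") {
    if (is.null(collection$super))
      stop("collection has no designated super-pathway", call. = FALSE)
    sets <- collection$sets[collection$super]
  } else {
    sets <- collection_sets(collection, "CAN", drop_super = TRUE)
    if (length(sets) == 0L)
      sets <- collection_sets(collection, "CAN")  # only the super exists
    if (length(sets) == 0L)
      stop("collection has no CAN-category sets", call. = FALSE)
  }
  zmat <- matrix(NA_real_, nrow = length(genes), ncol = length(sets),
                 dimnames = list(genes, names(sets)))
  for (s in names(sets)) {
    sids <- gene_ids(idx, sets[[s]])
    sids <- sids[!is.na(sids)]
    if (length(sids) == 0L) next
    res <- batch_nea(ensemble, ids[ok], sids, mode = mode)
    zmat[ok, s] <- res$z
  }
  zs <- zmat
  if (floor_negative) zs[zs < 0] <- 0
  z_norm <- if (cpw_mode == "superpathway_only") zs[, 1L]
            else cpw_normalize(rowSums(zs), normalization_factor)
  out <- data.frame(gene = genes, z = as.numeric(z_norm),
                    p = ifelse(is.na(z_norm), NA_real_,
                               z_to_p(ifelse(is.na(z_norm), 0, z_norm))),
                    significant = !is.na(z_norm) & z_norm >= z_cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "per_set") <- zmat
  out
}

#' Screen candidate genes for co-occurrence with point mutations
#'
#' For every (candidate, point-mutated gene) pair over a common sample
#' universe, builds the 2x2 table (both / candidate-only / partner-only /
#' neither) and applies the one-sided Fisher exact test. A candidate passes
#' the screen when its smallest raw p-value is below `alpha`; the reported
#' per-gene `p_co` is the Bonferroni-corrected minimum over tested partners.
#'
#' @param candidate_carriers Named list: candidate gene -> character vector
#'   of carrier samples.
#' @param mgs Named list of per-sample mutated gene sets (partners are all
#'   point-mutated genes).
#' @param samples Sample universe (character vector, >= 2 samples).
#' @param alpha Raw-p screen threshold (default 0.01).
#' @return List with `summary` (data.frame: gene, n_partners, best_partner,
#'   min_p, p_co, pass) and `pairs` (data.frame of all tested pairs).
#' @export
cooccurrence_scan <- function(candidate_carriers, mgs, samples, alpha = 0.01) {
  samples <- unique(samples)
  if (length(samples) < 2L)
    stop("co-occurrence needs at least 2 samples", call. = FALSE)
  mgs <- mgs[intersect(names(mgs), samples)]
  partners <- sort(unique(unlist(mgs)))
  # samples x partners incidence
  inc <- vapply(partners, function(g)
    samples %in% names(mgs)[vapply(mgs, function(x) g %in% x, TRUE)],
    logical(length(samples)))
  n <- length(samples)
  c1 <- colSums(inc)
  summary_rows <- list()
  pair_rows <- list()
  for (g in names(candidate_carriers)) {
    carr <- samples %in% candidate_carriers[[g]]
    use <- partners != g   # self-pairs skipped
    if (!any(use)) next
    a <- colSums(inc[carr, use, drop = FALSE])
    r1 <- sum(carr)
    p <- stats::phyper(a - 1, c1[use], n - c1[use], r1, lower.tail = FALSE)
    pair_rows[[g]] <- data.frame(gene = g, partner = partners[use],
                                 both = as.integer(a),
                                 candidate_only = r1 - as.integer(a),
                                 partner_only = as.integer(c1[use] - a),
                                 neither = n - r1 - as.integer(c1[use] - a),
                                 p = p, stringsAsFactors = FALSE)
    best <- which.min(p)
    summary_rows[[g]] <- data.frame(
      gene = g, n_partners = sum(use), best_partner = partners[use][best],
      min_p = p[best], p_co = min(1, p[best] * sum(use)),
      pass = p[best] < alpha, stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summary_rows,
                                  list(make.row.names = FALSE))),
       pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))))
}

# Fisher-combine the non-NA components; NA when none are available.
combine_components <- function(...) {
  p <- c(...)
  p <- p[!is.na(p)]
  if (length(p) == 0L)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  fisher_combine(p)
}

#' Combine the p-values of a point-mutation event
#'
#' Fisher combination over the available components (the 1point-vs-MGS and
#' 1-vs-CPW p-values); an `NA` component is dropped and the degrees of
#' freedom shrink accordingly.
#'
#' @param p_mgs,p_cpw Component p-values (either may be `NA`).
#' @return List with `chi2`, `df`, `p`.
#' @export
combine_point <- function(p_mgs, p_cpw) combine_components(p_mgs, p_cpw)

#' Combine the p-values of a CNA gene
#'
#' Fisher combination over the available components among the co-occurrence
#' screen p, the (already chi-square-combined) 1CNA-vs-MGS p, and the
#' 1-vs-CPW p.
#'
#' @param p_co,p_mgs_combined,p_cpw Component p-values (any may be `NA`).
#' @return List with `chi2`, `df`, `p`.
#' @export
combine_cna <- function(p_co, p_mgs_combined, p_cpw)
  combine_components(p_co, p_mgs_combined, p_cpw)

#' Rank events and adjust combined p-values for multiple testing
#'
#' Benjamini-Hochberg adjustment within one event class, ranking by combined
#' p-value; `driver_call` is `adjusted_p < threshold` (strict). Rows with no
#' available combined p keep `NA` and are never called.
#'
#' @param scores data.frame with a `combined_p` column.
#' @param method `stats::p.adjust` method (default `"BH"`).
#' @param threshold Driver-call threshold on the adjusted p (default 0.01).
#' @return `scores` with `adjusted_p` and `driver_call` columns, sorted by
#'   `combined_p`.
#' @export
rank_and_adjust <- function(scores, method = "BH", threshold = 0.01) {
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("empty score table", call. = FALSE)
  stopifnot("combined_p" %in% names(scores))
  adj <- rep(NA_real_, nrow(scores))
  ok <- !is.na(scores$combined_p)
  adj[ok] <- stats::p.adjust(scores$combined_p[ok], method = method)
  scores$adjusted_p <- adj
  scores$driver_call <- !is.na(adj) & adj < threshold
  scores[order(scores$combined_p), , drop = FALSE]
}
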