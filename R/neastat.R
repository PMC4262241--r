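# Randomization-calibrated network enrichment statistics.

# Degenerate randomization null (all replica counts identical): the only
# statement 25 unmoved randomizations support is the one-sided permutation
# bound p = 1/(n_rand + 1), so an observation outside the degenerate null
# maps to the matching normal quantile rather than an arbitrary large z.
degenerate_z <- function(n_rand) stats::qnorm(1 - 1 / (n_rand + 1))

finite_z <- function(observed, null_mean, null_sd, n_rand) {
  ifelse(null_sd > 0, (observed - null_mean) / null_sd,
         ifelse(observed == null_mean, 0,
                sign(observed - null_mean) * degenerate_z(n_rand)))
}

#' Build an ensemble of degree-preserving network randomizations
#'
#' Generates `n_rand` independently rewired replicas of `net` (each by
#' [rewire_network()], with per-replica seeds derived deterministically from
#' the master seed) and pre-indexes them for fast link counting. One ensemble
#' serves every enrichment test in a run, matching the per-network
#' randomization design: the expected link count and its standard deviation
#' for any query are estimated from the same 25 (by default) replicas.
#'
#' @param net A gene network.
#' @param n_rand Number of randomized replicas (default 25).
#' @param seed Master integer seed.
#' @param swap_factor Swap trials per edge passed to [rewire_network()].
#' @return An object of class `nea_ensemble`.
#' @export
nea_ensemble <- function(net, n_rand = 25, seed = 1, swap_factor = 100) {
  assert_gene_network(net)
  if (n_rand < 2) stop("n_rand must be at least 2 (sd undefined otherwise)",
                       call. = FALSE)
  replica_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_rand))
  replicas <- lapply(replica_seeds, function(s)
    graph_index(rewire_network(net, swap_factor = swap_factor, seed = s)))
  structure(list(net = net, real = graph_index(net), replicas = replicas,
                 n_rand = as.integer(n_rand), seed = seed,
                 swap_factor = swap_factor),
            class = "nea_ensemble")
}

#' @export
print.nea_ensemble <- function(x, ...) {
  cat(sprintf("NEA randomization ensemble: %d nodes, %d edges, %d replicas (seed %s)\n",
              x$real$n, x$real$n_edges, x$n_rand, format(x$seed)))
  invisible(x)
}

as_ensemble <- function(x, ...) {
  if (inherits(x, "nea_ensemble")) x else nea_ensemble(x, ...)
}

# Count the test statistic on one index for a resolved query.
ensemble_count <- function(idx, query_ids, target_ids, mode, within) {
  if (within) count_within_set(idx, query_ids, mode)
  else count_gene_vs_set(idx, query_ids, target_ids, mode)
}

#' Null moments of a link count under network randomization
#'
#' Recomputes the link count of interest on every rewired replica of the
#' ensemble and returns the sample mean and standard deviation (`ddof = 1`)
#' of the replica counts -- the \eqn{\bar n_{iG}} and \eqn{\sigma_{iG}} that
#' calibrate the enrichment z-score.
#'
#' @param ensemble An [nea_ensemble()].
#' @param query A single gene symbol, or (when `target` is `NULL`) a gene set
#'   whose within-set coherence count is used.
#' @param target Gene set tested against `query`, or `NULL` for coherence.
#' @param mode `"direct"` or `"shared"` link metric.
#' @return A list with `mean`, `sd`, and the per-replica `counts`.
#' @export
null_moments <- function(ensemble, query, target = NULL,
                         mode = c("direct", "shared")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "nea_ensemble"))
  within <- is.null(target)
  if (within) {
    rs <- resolve_set(ensemble$real, unique(toupper(query)))
    if (rs$n_mapped < 2L)
      stop("coherence test needs >= 2 mapped set members", call. = FALSE)
    qids <- rs$ids; tids <- NULL
  } else {
    qids <- gene_ids(ensemble$real, query)
    if (length(qids) != 1L || is.na(qids))
      stop(sprintf("gene '%s' is not in the network", query), call. = FALSE)
    rs <- resolve_set(ensemble$real, setdiff(toupper(target), toupper(query)))
    if (rs$n_mapped < 1L)
      stop("no target-set genes mapped to the network", call. = FALSE)
    tids <- rs$ids
  }
  # vertex ids are identical across replicas (rewiring preserves vertices)
  counts <- vapply(ensemble$replicas, ensemble_count, numeric(1),
                   query_ids = qids, target_ids = tids,
                   mode = mode, within = within)
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts,
       n_mapped = rs$n_mapped)
}

new_nea_result <- function(observed, null_mean, null_sd, n_rand, mode,
                           query, target, n_mapped,
                           convention = "one_sided") {
  z <- finite_z(observed, null_mean, null_sd, n_rand)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z,
                 p = z_to_p(z, convention), mode = mode,
                 query = query, target = target, n_mapped = n_mapped,
                 convention = convention),
            class = "nea_result")
}

#' @export
print.nea_result <- function(x, ...) {
  cat(sprintf("NEA %s test: %s vs %s\n", x$mode,
              paste(x$query, collapse = ","),
              if (is.null(x$target)) "(within set)" else x$target))
  cat(sprintf("  n = %g, null mean = %.3f, null sd = %.3f, z = %.3f, p = %.3g\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$p))
  invisible(x)
}

#' Network enrichment test of one gene against a gene set
#'
#' The core NEA statistic: the observed link count \eqn{n_{iG}} between gene
#' `i` and set `G` (with `i` always excluded from `G`) is compared to its
#' mean and standard deviation over the rewired replicas,
#' \eqn{z = (n_{iG} - \bar n_{iG}) / \sigma_{iG}}, and converted to a
#' one-sided (enrichment) p-value by default. When the replica counts are
#' constant (rigid degree sequence), z is 0 if the observation equals the
#' null mean and is capped at +/-40 otherwise.
#'
#' @param ensemble An [nea_ensemble()].
#' @param i Query gene symbol (must be in the network).
#' @param G Target gene set (character vector).
#' @param mode `"direct"` or `"shared"` link metric.
#' @param convention p-value convention for [z_to_p()].
#' @return An object of class `nea_result`.
#' @export
nea_gene_vs_set <- function(ensemble, i, G, mode = c("direct", "shared"),
                            convention = "one_sided") {
  mode <- match.arg(mode)
  obs <- link_count(ensemble$real, i, G, mode)
  nm <- null_moments(ensemble, i, G, mode = mode)
  new_nea_result(as.numeric(obs), nm$mean, nm$sd, ensemble$n_rand, mode,
                 toupper(i), paste0("set[", length(G), "]"),
                 attr(obs, "n_mapped"), convention)
}

#' Network coherence test of a gene set
#'
#' Tests whether the members of `G` are more densely interconnected than
#' expected from the degree-preserving null, using [within_set_links()] as
#' the count. Used to ask whether a sample's mutated gene set is functionally
#' coherent at all.
#'
#' @inheritParams nea_gene_vs_set
#' @param G Gene set with at least 2 members mapped to the network.
#' @return An object of class `nea_result`.
#' @export
nea_set_coherence <- function(ensemble, G, mode = c("direct", "shared"),
                              convention = "one_sided") {
  mode <- match.arg(mode)
  obs <- within_set_links(ensemble$real, G, mode)
  nm <- null_moments(ensemble, G, target = NULL, mode = mode)
  new_nea_result(as.numeric(obs), nm$mean, nm$sd, ensemble$n_rand, mode,
                 paste0("set[", length(G), "]"), NULL,
                 attr(obs, "n_mapped"), convention)
}

# Batch NEA: test many query genes against one target set, sharing the
# set-membership vector across all queries and replicas (vertex ids are
# identical across replicas). Each query gene is excluded from the target
# set for its own test. Returns one row per query gene.
batch_nea <- function(ensemble, query_ids, set_ids, mode = "direct",
                      convention = "one_sided") {
  idxs <- c(list(ensemble$real), ensemble$replicas)
  n <- ensemble$real$n
  memb <- logical(n)
  memb[set_ids] <- TRUE
  counts <- matrix(0, nrow = length(query_ids), ncol = length(idxs))
  for (k in seq_along(idxs)) {
    idx <- idxs[[k]]
    for (q in seq_along(query_ids)) {
      gid <- query_ids[q]
      was <- memb[gid]
      memb[gid] <- FALSE
      counts[q, k] <- if (mode == "direct") {
        sum(memb[idx$adj[[gid]]])
      } else {
        tot <- 0L
        for (v in idx$adj[[gid]]) tot <- tot + sum(memb[idx$adj[[v]]])
        tot
      }
      memb[gid] <- was
    }
  }
  obs <- counts[, 1L]
  null_mean <- rowMeans(counts[, -1L, drop = FALSE])
  null_sd <- apply(counts[, -1L, drop = FALSE], 1L, stats::sd)
  z <- finite_z(obs, null_mean, null_sd, ensemble$n_rand)
  data.frame(observed = obs, null_mean = null_mean, null_sd = null_sd,
             z = z, p = z_to_p(z, convention))
}

#' Convert a z-score to a normal-tail p-value
#'
#' `one_sided` gives the upper-tail standard normal probability (enrichment
#' direction); `two_sided` gives twice the upper tail of |z|, capped at 1.
#' Both conventions are exposed because significance bridges in the
#' literature quote either.
#'
#' @param z Finite numeric z-score(s).
#' @param convention `"one_sided"` or `"two_sided"`.
#' @return Probability in \[0, 1\].
#' @export
z_to_p <- function(z, convention = c("one_sided", "two_sided")) {
  convention <- match.arg(convention)
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  if (convention == "one_sided") stats::pnorm(z, lower.tail = FALSE)
  else pmin(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values as \eqn{\chi^2 = -2 \sum \ln p_i},
#' referred to the upper tail of a chi-square distribution with 2k degrees
#' of freedom. Zero p-values are floored at `eps` with a warning so the log
#' is defined.
#'
#' @param p Non-empty numeric vector of p-values in \[0, 1\].
#' @param eps Floor applied to zero components (default 1e-300).
#' @return An object of class `combined_p` with fields `chi2`, `df`, `p`,
#'   and `components`.
#' @export
fisher_combine <- function(p, eps = 1e-300) {
  if (length(p) == 0L) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p))) stop("NA p-values; drop unavailable components first",
                          call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning(sprintf("%d zero p-value(s) floored at %g", sum(p == 0), eps),
            call. = FALSE)
    p[p == 0] <- eps
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
                 components = p),
            class = "combined_p")
}

#' @export
print.combined_p <- function(x, ...) {
  cat(sprintf("Fisher combined p: chi2 = %.4g, df = %d, p = %.4g (k = %d)\n",
              x$chi2, x$df, x$p, length(x$components)))
  invisible(x)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact hypergeometric test for the table
#' \preformatted{            partner+  partner-
#'  candidate+     a         b
#'  candidate-     c         d}
#' One-sided: the probability of a table at least as enriched in cell `a`
#' given fixed margins. Two-sided: the sum of probabilities of all tables
#' whose point probability does not exceed that of the observed table.
#'
#' @param a,b,c,d Non-negative integer cell counts (total >= 1).
#' @param sided `"one"` (enrichment in `a`) or `"two"`.
#' @return The exact p-value.
#' @examples
#' fisher_exact_2x2(4, 0, 1, 143)  # 5 / choose(148, 4)
#' @export
fisher_exact_2x2 <- function(a, b, c, d, sided = c("one", "two")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (sum(cells) < 1) stop("table total must be at least 1", call. = FALSE)
  r1 <- a + b            # candidate carriers
  c1 <- a + c            # partner carriers
  n <- sum(cells)
  if (sided == "one")
    return(stats::phyper(a - 1, c1, n - c1, r1, lower.tail = FALSE))
  support <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
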