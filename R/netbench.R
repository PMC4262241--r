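# ROC benchmarking of candidate global networks: leave-one-out recovery of
# pathway membership, with degree-matched negatives, z-thresholded ROC
# curves terminated at the lowest formally significant z, and the Y/X
# ("odds") ratio at the FDR = 0.1 cross as the headline metric.

#' Pick a degree-matched substitute gene
#'
#' Returns a uniformly sampled gene outside `exclude` whose network degree
#' lies within a relative tolerance window of `member`'s degree; the window
#' widens geometrically until at least one candidate exists.
#'
#' @param net A gene network (or internal index).
#' @param member Gene whose degree is to be matched.
#' @param exclude Genes that may not be picked (typically the tested set).
#' @param tolerance Initial relative degree window (default 0.1, i.e. +/-10%).
#' @param widen Multiplier applied to the window until candidates appear
#'   (default 2); set to 1 to forbid widening.
#' @param seed Optional seed for a deterministic draw.
#' @return A gene symbol.
#' @export
degree_matched_substitute <- function(net, member, exclude = character(),
                                      tolerance = 0.1, widen = 2,
                                      seed = NULL) {
  idx <- if (inherits(net, "nd_graph_index")) net else graph_index(net)
  mid <- gene_ids(idx, member)
  if (is.na(mid))
    stop(sprintf("gene '%s' is not in the network", member), call. = FALSE)
  pool <- setdiff(seq_len(idx$n), gene_ids(idx, unique(c(member, exclude))))
  if (length(pool) == 0L)
    stop("no candidate genes outside the excluded set", call. = FALSE)
  target <- idx$deg[mid]
  tol <- tolerance
  repeat {
    lo <- target * (1 - tol); hi <- target * (1 + tol)
    hit <- pool[idx$deg[pool] >= lo & idx$deg[pool] <= hi]
    if (length(hit) > 0L) break
    if (widen <= 1)
      stop(sprintf("no degree-matched candidate for '%s' at tolerance %g",
                   member, tol), call. = FALSE)
    tol <- if (tol > 0) tol * widen else 0.1
  }
  draw <- function() hit[sample.int(length(hit), 1L)]
  id <- if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  idx$names[id]
}

#' Paired membership-recovery tests over a pathway collection
#'
#' For every set `G` and every member `i` mapped to the network, computes the
#' true-positive NEA z-score of `i` against `G \\ i`, paired with a null test
#' of a degree-matched substitute (never a member of `G`) against the same
#' target. The two returned lists have equal length by construction, so true
#' and false positive axes are on the same scale.
#'
#' @param ensemble An [nea_ensemble()].
#' @param collection A [pathway_collection()]; sets with fewer than 2 mapped
#'   members are skipped with a warning.
#' @param mode Link metric.
#' @param tolerance Degree-matching tolerance (see
#'   [degree_matched_substitute()]).
#' @param seed Seed for the substitute draws.
#' @return List with numeric vectors `true_z` and `null_z` plus a `tests`
#'   data.frame (set, member, substitute, true_z, null_z).
#' @export
membership_tests <- function(ensemble, collection, mode = "direct",
                             tolerance = 0.1, seed = 1) {
  idx <- ensemble$real
  rows <- list()
  withr::with_seed(seed, {
    for (nm in names(collection$sets)) {
      G <- collection$sets[[nm]]
      rs <- resolve_set(idx, G)
      if (rs$n_mapped < 2L) {
        warning(sprintf("set '%s' has <2 mapped members; skipped", nm),
                call. = FALSE)
        next
      }
      members <- idx$names[rs$ids]
      subs <- vapply(members, function(m)
        degree_matched_substitute(idx, m, exclude = G,
                                  tolerance = tolerance), "")
      true_res <- batch_nea(ensemble, rs$ids, rs$ids, mode = mode)
      sub_ids <- gene_ids(idx, subs)
      # null query vs the same leave-one-out target G \ i
      null_z <- vapply(seq_along(sub_ids), function(k) {
        batch_nea(ensemble, sub_ids[k], setdiff(rs$ids, rs$ids[k]),
                  mode = mode)$z
      }, numeric(1))
      rows[[nm]] <- data.frame(set = nm, member = members,
                               substitute = subs,
                               true_z = true_res$z, null_z = null_z,
                               stringsAsFactors = FALSE)
    }
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  list(true_z = tests$true_z, null_z = tests$null_z, tests = tests)
}

#' Build a membership-recovery ROC curve from paired z-scores
#'
#' Sweeps thresholds over the union of observed z-scores at or above
#' `z_min`, in decreasing order; at each threshold `t`, `Y` counts true
#' tests with z >= t and `X` counts null tests with z >= t. The curve is
#' terminated at `z_min`, the lowest formally significant z, which is why
#' area under the curve is not a meaningful summary here.
#'
#' @param true_z,null_z Equal-length numeric vectors of paired z-scores.
#' @param z_min Termination threshold (default 1.97).
#' @return Object of class `roc_curve`: data.frame with columns `threshold`,
#'   `X`, `Y`, plus attributes `n_tests` and `z_min`.
#' @export
build_roc <- function(true_z, null_z, z_min = 1.97) {
  if (length(true_z) == 0L || length(true_z) != length(null_z))
    stop("true_z and null_z must be non-empty and of equal length",
         call. = FALSE)
  thr <- sort(unique(c(true_z, null_z)), decreasing = TRUE)
  thr <- thr[thr >= z_min]
  if (length(thr) == 0L)
    return(structure(data.frame(threshold = numeric(), X = integer(),
                                Y = integer()),
                     n_tests = length(true_z), z_min = z_min,
                     class = c("roc_curve", "data.frame")))
  curve <- data.frame(
    threshold = thr,
    X = vapply(thr, function(t) sum(null_z >= t), integer(1)),
    Y = vapply(thr, function(t) sum(true_z >= t), integer(1)))
  structure(curve, n_tests = length(true_z), z_min = z_min,
            class = c("roc_curve", "data.frame"))
}

#' Sensitivity/specificity ratio at an FDR cross point
#'
#' Walks the ROC curve from its strictest threshold and reports `Y/X` at the
#' first point where the empirical FDR, `X/(X+Y)` under the 1:1 paired
#' design, reaches `fdr`. If the curve never reaches that FDR, the terminal
#' point's ratio is returned flagged as a lower bound; a cross point with
#' `X = 0` yields `Inf`, flagged.
#'
#' @param roc A [build_roc()] curve.
#' @param fdr Target false discovery rate (default 0.1).
#' @return List with `or`, `X`, `Y`, `threshold`, and `flag` (`"ok"`,
#'   `"lower_bound"`, or `"infinite"`).
#' @export
or_at_fdr <- function(roc, fdr = 0.1) {
  if (nrow(roc) == 0L)
    return(list(or = NA_real_, X = NA_integer_, Y = NA_integer_,
                threshold = NA_real_, flag = "empty"))
  fdr_emp <- roc$X / (roc$X + roc$Y)
  hit <- which(fdr_emp >= fdr)
  i <- if (length(hit)) hit[1L] else nrow(roc)
  flag <- if (length(hit)) "ok" else "lower_bound"
  or <- roc$Y[i] / roc$X[i]
  if (!is.finite(or)) flag <- "infinite"
  list(or = or, X = roc$X[i], Y = roc$Y[i],
       threshold = roc$threshold[i], flag = flag)
}

#' Benchmark candidate global networks by pathway-membership recovery
#'
#' Runs [membership_tests()], [build_roc()], and [or_at_fdr()] for each
#' candidate network against one pathway collection and tabulates the
#' results. Total recapitulated true members (true z >= `z_min`) is reported
#' alongside the OR as the sensitivity count.
#'
#' @param networks Named list of gene networks.
#' @param collection A [pathway_collection()].
#' @param n_rand,swap_factor Randomization settings per network.
#' @param z_min ROC termination threshold (default 1.97).
#' @param fdr FDR cross level (default 0.1).
#' @param seed Master seed.
#' @param mode Link metric.
#' @return List with `summary` (data.frame: network, or_at_fdr, flag,
#'   n_true_recovered, n_tests) and `curves` (named list of `roc_curve`s).
#' @export
benchmark_networks <- function(networks, collection, n_rand = 25,
                               swap_factor = 100, z_min = 1.97, fdr = 0.1,
                               seed = 1, mode = "direct") {
  stopifnot(is.list(networks), !is.null(names(networks)))
  curves <- list()
  rows <- lapply(names(networks), function(nm) {
    ens <- nea_ensemble(networks[[nm]], n_rand = n_rand, seed = seed,
                        swap_factor = swap_factor)
    mt <- membership_tests(ens, collection, mode = mode, seed = seed)
    roc <- build_roc(mt$true_z, mt$null_z, z_min = z_min)
    curves[[nm]] <<- roc
    cross <- or_at_fdr(roc, fdr = fdr)
    data.frame(network = nm, or_at_fdr = cross$or, flag = cross$flag,
               n_true_recovered = sum(mt$true_z >= z_min),
               n_tests = length(mt$true_z), stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), curves = curves)
}
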