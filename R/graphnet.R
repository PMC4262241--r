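# The global functional-coupling network is held as a named, undirected,
# simple igraph object. All public functions validate that contract rather
# than wrapping igraph in a new class.

#' Validate a gene network
#'
#' Checks that `net` is a named, undirected, simple igraph graph, the
#' representation used throughout the package for the global
#' functional-coupling network.
#'
#' @param net An igraph object.
#' @return `net`, invisibly, if valid; otherwise an error is thrown.
#' @export
assert_gene_network <- function(net) {
  if (!igraph::is_igraph(net))
    stop("`net` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(net))
    stop("`net` must be undirected", call. = FALSE)
  if (igraph::any_multiple(net) || any(igraph::which_loop(net)))
    stop("`net` must be a simple graph (no self-loops or duplicate edges)",
         call. = FALSE)
  if (is.null(igraph::V(net)$name))
    stop("`net` must have named vertices (gene symbols)", call. = FALSE)
  invisible(net)
}

#' Load a gene-gene edge list as an undirected simple network
#'
#' Reads a whitespace/tab-separated edge list of gene symbols into an
#' undirected simple igraph graph. An optional third numeric column is
#' interpreted as an edge confidence and can be used as a load-time cutoff;
#' confidences are discarded afterwards (edge weights are never used in the
#' enrichment statistics). Symbols are uppercased. Self-loop lines are
#' dropped with a warning; duplicate and reversed-duplicate pairs are
#' collapsed.
#'
#' @param source Path to the edge-list file, or a character vector of lines.
#' @param min_confidence Optional numeric cutoff; lines whose third field is
#'   below it are dropped. Lines without a confidence field are kept.
#' @param format `"edgelist"` (gene gene \[confidence\]) or `"sif"`
#'   (gene relation gene; the relation label is discarded).
#' @return An undirected simple igraph graph with vertex names.
#' @examples
#' net <- load_edge_list(c("A B", "B C"))
#' igraph::degree(net)
#' @export
load_edge_list <- function(source, min_confidence = NULL,
                           format = c("edgelist", "sif")) {
  format <- match.arg(format)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty edge-list input", call. = FALSE)

  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  min_nf <- if (format == "sif") 3L else 2L
  if (any(nf < min_nf))
    stop(sprintf("malformed edge-list line %d: %s",
                 lineno[which(nf < min_nf)[1L]],
                 lines[which(nf < min_nf)[1L]]), call. = FALSE)

  if (format == "sif") {
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 3L)
    conf <- rep(NA_real_, length(fields))
  } else {
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 2L)
    conf <- suppressWarnings(
      as.numeric(vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")))
  }
  a <- toupper(a); b <- toupper(b)

  if (!is.null(min_confidence)) {
    drop <- !is.na(conf) & conf < min_confidence
    a <- a[!drop]; b <- b[!drop]
  }
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-loop line(s)", sum(self)), call. = FALSE)
    a <- a[!self]; b <- b[!self]
  }
  if (length(a) == 0L)
    stop("no edges left after filtering", call. = FALSE)

  net <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  net <- igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  assert_gene_network(net)
}

#' Write a network as a two-column TSV edge list
#'
#' @param net A gene network (see [assert_gene_network()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  assert_gene_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal index: integer adjacency lists plus name lookup. All counting
# statistics run on this structure so that one igraph conversion serves
# many queries (important when 25+ randomized replicas are interrogated
# for thousands of gene/set pairs).
graph_index <- function(net) {
  assert_gene_network(net)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  nm <- igraph::V(net)$name
  names(adj) <- NULL
  structure(list(adj = adj, names = nm, n = length(nm),
                 deg = lengths(adj), n_edges = igraph::ecount(net)),
            class = "nd_graph_index")
}

# Map gene symbols to vertex ids in an index; unknown genes -> NA.
gene_ids <- function(idx, genes) match(toupper(genes), idx$names)

# n_iG in either metric, on an index, with i excluded from G.
count_gene_vs_set <- function(idx, i_id, g_ids, mode) {
  g_ids <- g_ids[g_ids != i_id]
  if (length(g_ids) == 0L) return(0L)
  memb <- logical(idx$n)
  memb[g_ids] <- TRUE
  if (mode == "direct") {
    sum(memb[idx$adj[[i_id]]])
  } else {
    tot <- 0L
    for (v in idx$adj[[i_id]]) tot <- tot + sum(memb[idx$adj[[v]]])
    tot
  }
}

# Within-set link count: direct = edges with both ends in G; shared = sum
# over unordered member pairs of their common-neighbor count, computed as
# sum over all nodes v of choose(#members adjacent to v, 2).
count_within_set <- function(idx, g_ids, mode) {
  if (mode == "direct") {
    memb <- logical(idx$n)
    memb[g_ids] <- TRUE
    s <- 0L
    for (g in g_ids) s <- s + sum(memb[idx$adj[[g]]])
    s %/% 2L
  } else {
    cnt <- integer(idx$n)
    for (g in g_ids) {
      nb <- idx$adj[[g]]
      cnt[nb] <- cnt[nb] + 1L
    }
    sum(choose(cnt, 2L))
  }
}

# Resolve a query-set pair against a network/index, reporting coverage.
resolve_set <- function(idx, genes) {
  ids <- gene_ids(idx, genes)
  list(ids = ids[!is.na(ids)], n_query = length(genes),
       n_mapped = sum(!is.na(ids)), missing = genes[is.na(ids)])
}

#' Count direct network links between a gene and a gene set
#'
#' Returns \eqn{n_{iG}}: the number of edges between gene `i` and any member
#' of `G` other than `i` itself. `i` is always treated as external to `G`.
#' Set members absent from the network are ignored (their number is reported
#' in the `"n_mapped"` attribute).
#'
#' @param net A gene network.
#' @param i A gene symbol present in the network.
#' @param G Character vector of gene symbols (the target set).
#' @return Integer count with attribute `n_mapped` (members of `G`, excluding
#'   `i`, found in the network).
#' @export
direct_links <- function(net, i, G) {
  link_count(net, i, G, mode = "direct")
}

#' Count shared-neighbor links between a gene and a gene set
#'
#' Indirect-connectivity variant of [direct_links()]: returns
#' \eqn{\sum_{j \in G \setminus \{i\}} |N(i) \cap N(j)|}, the total number of
#' common neighbors over all query-member pairs. Useful on sparse networks
#' where direct edges are rare.
#'
#' @inheritParams direct_links
#' @return Integer count with attribute `n_mapped`.
#' @export
shared_neighbor_links <- function(net, i, G) {
  link_count(net, i, G, mode = "shared")
}

link_count <- function(net, i, G, mode) {
  idx <- if (inherits(net, "nd_graph_index")) net else graph_index(net)
  i_id <- gene_ids(idx, i)
  if (length(i_id) != 1L || is.na(i_id))
    stop(sprintf("gene '%s' is not in the network", i), call. = FALSE)
  rs <- resolve_set(idx, setdiff(toupper(G), toupper(i)))
  out <- as.integer(count_gene_vs_set(idx, i_id, rs$ids, mode))
  attr(out, "n_mapped") <- rs$n_mapped
  out
}

#' Count links within a gene set
#'
#' Coherence count for a whole set: with `mode = "direct"`, the number of
#' network edges with both endpoints in `G`; with `mode = "shared"`, the sum
#' over unordered member pairs of their common-neighbor counts.
#'
#' @param net A gene network.
#' @param G Character vector of gene symbols.
#' @param mode `"direct"` or `"shared"`.
#' @return Integer count with attribute `n_mapped`.
#' @export
within_set_links <- function(net, G, mode = c("direct", "shared")) {
  mode <- match.arg(mode)
  idx <- if (inherits(net, "nd_graph_index")) net else graph_index(net)
  rs <- resolve_set(idx, unique(toupper(G)))
  if (rs$n_mapped < 2L)
    stop("within-set count needs at least 2 set members mapped to the network",
         call. = FALSE)
  out <- as.integer(count_within_set(idx, rs$ids, mode))
  attr(out, "n_mapped") <- rs$n_mapped
  out
}

#' Degree-preserving network randomization (Maslov-Sneppen)
#'
#' Randomizes the wiring of a network by repeated double-edge swaps: two
#' edges (a,b), (c,d) are replaced by (a,d), (c,b) whenever the replacement
#' creates no self-loop or duplicate edge. Every node keeps its exact degree
#' and the total edge count is unchanged, so the randomized replicas share
#' the original topology's degree sequence while its specific wiring (the
#' "biological content") is removed.
#'
#' @param net A gene network with at least 2 edges.
#' @param swap_factor Swap trials per edge (default 100); the total trial
#'   budget is `ceiling(swap_factor * ecount(net))`.
#' @param seed Optional integer; when given, the result is deterministic and
#'   the caller's RNG state is left untouched.
#' @return A rewired gene network over the same vertices.
#' @export
rewire_network <- function(net, swap_factor = 100, seed = NULL) {
  assert_gene_network(net)
  if (swap_factor <= 0) stop("swap_factor must be positive", call. = FALSE)
  if (igraph::ecount(net) < 2L)
    stop("rewiring needs at least 2 edges", call. = FALSE)
  niter <- as.integer(ceiling(swap_factor * igraph::ecount(net)))
  do_rewire <- function() {
    igraph::rewire(net, with = igraph::keeping_degseq(loops = FALSE,
                                                      niter = niter))
  }
  if (!is.null(seed)) withr::with_seed(seed, do_rewire()) else do_rewire()
}

#' Jaccard overlap between the edge sets of two networks
#'
#' Diagnostic for rewiring mixing: the fraction of edges shared between two
#' graphs over the union of their edge sets.
#'
#' @param net1,net2 Gene networks.
#' @return A number in \[0, 1\].
#' @export
edge_jaccard <- function(net1, net2) {
  key <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  e1 <- unique(key(net1)); e2 <- unique(key(net2))
  length(intersect(e1, e2)) / length(union(e1, e2))
}
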