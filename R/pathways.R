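# Functional gene sets (pathways) in GMT format, organized into the
# categories used by the pipeline: SIG (signaling), OTH (other basic),
# CAN (cancer-related). The CAN category drives the 1-vs-CPW test; one CAN
# set may be designated the "super-pathway" (union-style set analogous to a
# pan-cancer KEGG pathway) for the alternative superpathway-only mode.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Gene symbols are uppercased.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d (need name, description, >=1 gene)",
                 bad[1L]), call. = FALSE)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in GMT file", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a categorized pathway collection
#'
#' @param sets Named list of gene sets (non-empty, unique names).
#' @param categories Character vector (recycled if length 1) giving each
#'   set's category, e.g. `"SIG"`, `"OTH"`, `"CAN"`; names must match
#'   `names(sets)` if named.
#' @param super Optional name of the designated super-pathway (must be one
#'   of the sets).
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, categories = "CAN", super = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  if (length(categories) == 1L)
    categories <- rep(categories, length(sets))
  if (is.null(names(categories))) names(categories) <- names(sets)
  categories <- categories[names(sets)]
  if (any(is.na(categories)))
    stop("every set needs a category", call. = FALSE)
  if (!is.null(super) && !super %in% names(sets))
    stop(sprintf("super-pathway '%s' is not among the sets", super),
         call. = FALSE)
  structure(list(sets = lapply(sets, toupper), categories = categories,
                 super = super),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("Pathway collection: %d sets (%s)%s\n", length(x$sets),
              paste(sprintf("%s: %d", names(table(x$categories)),
                            table(x$categories)), collapse = ", "),
              if (is.null(x$super)) "" else
                sprintf("; super-pathway: %s", x$super)))
  invisible(x)
}

#' Sets of a collection belonging to a category
#'
#' @param collection A [pathway_collection()].
#' @param category Category tag, e.g. `"CAN"`.
#' @param drop_super Exclude the designated super-pathway.
#' @return Named list of gene sets.
#' @export
collection_sets <- function(collection, category = "CAN", drop_super = FALSE) {
  keep <- names(collection$categories)[collection$categories == category]
  if (drop_super && !is.null(collection$super))
    keep <- setdiff(keep, collection$super)
  collection$sets[keep]
}

#' Read a pathway collection from a GMT file plus a category manifest
#'
#' The manifest maps set names to categories and optionally names the
#' super-pathway. Two formats are accepted: a TSV with columns `set` and
#' `category` (and optional logical column `super`), or a YAML file with
#' keys `categories` (set -> category map) and `super`.
#'
#' @param gmt_path GMT file path.
#' @param manifest_path Manifest path (`.yaml`/`.yml` or TSV).
#' @return A [pathway_collection()].
#' @export
read_pathway_collection <- function(gmt_path, manifest_path) {
  sets <- read_gmt(gmt_path)
  if (grepl("\\.ya?ml$", manifest_path, ignore.case = TRUE)) {
    man <- yaml::read_yaml(manifest_path)
    categories <- unlist(man$categories)
    super <- man$super
  } else {
    tab <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
    if (!all(c("set", "category") %in% names(tab)))
      stop("manifest TSV needs columns 'set' and 'category'", call. = FALSE)
    categories <- stats::setNames(tab$category, tab$set)
    super <- if ("super" %in% names(tab) && any(as.logical(tab$super)))
      tab$set[as.logical(tab$super)][1L] else NULL
  }
  missing <- setdiff(names(sets), names(categories))
  if (length(missing))
    stop(sprintf("manifest lacks categories for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  pathway_collection(sets, categories[names(sets)], super)
}

#' Write a pathway collection (GMT + TSV manifest)
#'
#' @param collection A [pathway_collection()].
#' @param gmt_path,manifest_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_pathway_collection <- function(collection, gmt_path, manifest_path) {
  write_gmt(collection$sets, gmt_path)
  man <- data.frame(set = names(collection$sets),
                    category = unname(collection$categories),
                    super = names(collection$sets) %in%
                      (collection$super %||% character()))
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gmt_path, manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
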