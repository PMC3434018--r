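#' Build an annotation ontology DAG
#'
#' Represents a GO-like hierarchy of annotation terms as a directed acyclic
#' graph with child-to-parent links. Terms with no parents are the roots
#' (e.g. the `biological_process` root of GO).
#'
#' @param terms character vector of term ids (unique, non-empty), or a
#'   data.frame with columns `id` and `name`.
#' @param links data.frame with columns `child` and `parent` giving one
#'   child-to-parent link per row. Both ends must appear in `terms`.
#' @return An object of class `ontology_dag` with elements `ids` (character),
#'   `names` (named character), `parents` (named list, child id -> character
#'   vector of parent ids) and `roots` (character).
#' @examples
#' dag <- ontology_dag(c("a", "b", "c"),
#'                     data.frame(child = c("b", "c"), parent = c("a", "b")))
#' term_depth(dag, "c")
#' @export
ontology_dag <- function(terms, links = NULL) {
  if (is.data.frame(terms)) {
    ids <- as.character(terms$id)
    nms <- if (!is.null(terms$name)) as.character(terms$name) else ids
  } else {
    ids <- as.character(terms)
    nms <- ids
  }
  if (anyDuplicated(ids)) stop("duplicate term ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty term id")
  names(nms) <- ids

  parents <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  if (!is.null(links) && nrow(links)) {
    ch <- as.character(links$child)
    pa <- as.character(links$parent)
    unknown <- setdiff(unique(c(ch, pa)), ids)
    if (length(unknown)) stop("link references unknown term(s): ",
                              paste(unknown, collapse = ", "))
    for (i in seq_along(ch)) {
      if (ch[i] == pa[i]) stop("self-link on term ", ch[i])
      parents[[ch[i]]] <- union(parents[[ch[i]]], pa[i])
    }
  }
  dag <- structure(list(
    ids = ids,
    names = nms,
    parents = parents,
    roots = ids[vapply(parents, length, 1L)[ids] == 0L]
  ), class = "ontology_dag")
  .check_acyclic(dag)
  if (length(dag$ids) && !length(dag$roots)) stop("ontology has no root term")
  dag
}

# Kahn topological sort; errors on a cycle.
.check_acyclic <- function(dag) {
  children <- .children_map(dag)
  ndeps <- vapply(dag$ids, function(t) length(dag$parents[[t]]), 1L)
  ready <- dag$ids[ndeps == 0L]
  seen <- 0L
  ndeps <- stats::setNames(ndeps, dag$ids)
  while (length(ready)) {
    t <- ready[[1L]]; ready <- ready[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      ndeps[[ch]] <- ndeps[[ch]] - 1L
      if (ndeps[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (seen != length(dag$ids)) stop("ontology term hierarchy contains a cycle")
  invisible(TRUE)
}

.children_map <- function(dag) {
  children <- stats::setNames(rep(list(character(0)), length(dag$ids)), dag$ids)
  for (ch in dag$ids) for (pa in dag$parents[[ch]])
    children[[pa]] <- c(children[[pa]], ch)
  children
}

.check_term <- function(dag, t) {
  missing <- setdiff(t, dag$ids)
  if (length(missing)) stop("unknown term id(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Direct parents of a term
#'
#' @param dag an [ontology_dag].
#' @param term a single term id.
#' @return Character vector of the ids reached by one parent link (empty for
#'   a root).
#' @export
term_parents <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"), length(term) == 1L)
  .check_term(dag, term)
  dag$parents[[term]]
}

#' All ancestors of a term
#'
#' Transitive closure of the parent relation; the term itself is excluded.
#'
#' @inheritParams term_parents
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "ontology_dag"), length(term) == 1L)
  .check_term(dag, term)
  out <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  sort(out)
}

#' Term depth (specificity)
#'
#' Distance from a term up to the ontology root. By convention the depth of
#' a root is 0 and deeper terms are more specific. Under multiple parentage
#' the default is the length of the longest directed path to any root, the
#' stricter reading of specificity; `method = "shortest"` measures the
#' shortest such path instead.
#'
#' @inheritParams term_parents
#' @param method `"longest"` (default) or `"shortest"` path to a root.
#' @return Non-negative integer depth.
#' @export
term_depth <- function(dag, term, method = c("longest", "shortest")) {
  stopifnot(inherits(dag, "ontology_dag"), length(term) == 1L)
  method <- match.arg(method)
  .check_term(dag, term)
  memo <- new.env(parent = emptyenv())
  agg <- if (method == "longest") max else min
  rec <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- dag$parents[[t]]
    d <- if (!length(ps)) 0L else agg(vapply(ps, rec, 1L)) + 1L
    memo[[t]] <- d
    d
  }
  rec(term)
}

#' Keep only the most specific terms of a set
#'
#' Drops every term that is an ancestor of another term in the set, the
#' standard pruning applied to a protein's annotation list before any
#' function node is seeded: a protein annotated with both a term and one of
#' its ancestors carries no extra information in the ancestor.
#'
#' @param dag an [ontology_dag].
#' @param terms character vector of term ids (all present in `dag`).
#' @return Character vector (sorted) of the terms that are ancestors of no
#'   other input term. Idempotent.
#' @export
most_specific_terms <- function(dag, terms) {
  stopifnot(inherits(dag, "ontology_dag"))
  terms <- unique(as.character(terms))
  .check_term(dag, terms)
  if (length(terms) <= 1L) return(terms)
  anc <- unique(unlist(lapply(terms, function(t) term_ancestors(dag, t)),
                       use.names = FALSE))
  sort(setdiff(terms, anc))
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag: ", length(x$ids), " terms, ",
      sum(vapply(x$parents, length, 1L)), " links, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Read an ontology from an OBO file
#'
#' Minimal OBO 1.2/1.4 reader: `[Term]` stanzas with `id`, `name`, `is_a`,
#' `relationship: part_of` (relation set configurable) and `is_obsolete`
#' (obsolete terms are skipped). All other tags are ignored. An optional
#' namespace filter restricts the ontology to one aspect (e.g.
#' `"biological_process"`).
#'
#' @param path path to an OBO file.
#' @param relations hierarchy-building relations: subset of the
#'   `relationship:` types to follow in addition to `is_a`.
#' @param namespace optional namespace to keep (others dropped).
#' @return An [ontology_dag].
#' @export
read_obo <- function(path, relations = c("part_of"), namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); nms <- character(0); ns <- character(0)
  links_child <- character(0); links_parent <- character(0)
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return()
    ids <<- c(ids, cur$id)
    nms <<- c(nms, if (is.null(cur$name)) cur$id else cur$name)
    ns <<- c(ns, if (is.null(cur$namespace)) NA_character_ else cur$namespace)
    for (p in cur$parents) {
      links_child <<- c(links_child, cur$id)
      links_parent <<- c(links_parent, p)
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)          # strip OBO comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
    else if (grepl("^is_a:", ln))
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^relationship:", ln)) {
      rest <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1L]]
      if (length(rest) >= 2L && rest[1L] %in% relations)
        cur$parents <- c(cur$parents, rest[2L])
    }
  }
  flush()
  if (!is.null(namespace)) {
    keep <- !is.na(ns) & ns == namespace
    kept_ids <- ids[keep]
    sel <- links_child %in% kept_ids & links_parent %in% kept_ids
    links_child <- links_child[sel]; links_parent <- links_parent[sel]
    nms <- nms[keep]; ids <- kept_ids
  }
  # drop links pointing outside the loaded term set (e.g. filtered namespaces)
  sel <- links_parent %in% ids & links_child %in% ids
  ontology_dag(data.frame(id = ids, name = nms, stringsAsFactors = FALSE),
               data.frame(child = links_child[sel], parent = links_parent[sel],
                          stringsAsFactors = FALSE))
}
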