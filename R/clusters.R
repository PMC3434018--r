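#' Enumerate all k-cliques of a PPI network
#'
#' All complete subgraphs on exactly `k` proteins (maximal or not), each
#' reported once.
#'
#' @param g a [ppi_network].
#' @param k clique order, integer >= 3.
#' @return List of clusters; each cluster is a list with `members` (sorted
#'   protein ids), `kind = "clique"` and `k`.
#' @export
find_k_cliques <- function(g, k) {
  stopifnot(inherits(g, "ppi_network"))
  if (!is.numeric(k) || length(k) != 1L || k < 3) stop("k must be an integer >= 3")
  k <- as.integer(k)
  ig <- .as_igraph(g)
  cl <- igraph::cliques(ig, min = k, max = k)
  out <- lapply(cl, function(v) list(members = sort(igraph::V(ig)$name[v]),
                                     kind = "clique", k = k))
  out[order(vapply(out, function(x) paste(x$members, collapse = "\r"), ""))]
}

#' Clique-percolation communities
#'
#' Communities in the sense of clique percolation: two k-cliques are
#' adjacent when they share k-1 proteins, and each connected component of
#' that clique-adjacency relation yields one community, the union of its
#' cliques' members.
#'
#' @inheritParams find_k_cliques
#' @return List of clusters with `kind = "community"`; each community has at
#'   least `k` members.
#' @export
k_clique_communities <- function(g, k) {
  cl <- find_k_cliques(g, k)            # validates g and k
  if (!length(cl)) return(list())
  k <- as.integer(k)
  members <- lapply(cl, `[[`, "members")
  prot <- sort(unique(unlist(members)))
  M <- matrix(0L, nrow = length(members), ncol = length(prot),
              dimnames = list(NULL, prot))
  for (i in seq_along(members)) M[i, members[[i]]] <- 1L
  shared <- tcrossprod(M)               # clique x clique shared-member counts
  adj <- shared >= (k - 1L)
  gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(gg)$membership
  out <- lapply(split(seq_along(members), comp), function(idx)
    list(members = sort(unique(unlist(members[idx]))), kind = "community", k = k))
  out <- unname(out)
  out[order(vapply(out, function(x) paste(x$members, collapse = "\r"), ""))]
}

#' Build the full cluster set driving PMS and NTS
#'
#' Collects k-cliques and clique-percolation communities for every k in a
#' range; these are the topological patterns a function node is scored
#' against. Duplicate clusters (same kind, k and member set) are removed.
#'
#' @param g a [ppi_network].
#' @param k_min smallest clique order (>= 3).
#' @param k_max largest clique order, or `"auto"` for the largest k with at
#'   least one k-clique.
#' @return Object of class `cluster_set`: list with `clusters` (list of
#'   member/kind/k records) and `index` (named list, protein id -> integer
#'   indices of the clusters containing it).
#' @export
build_cluster_set <- function(g, k_min = 3, k_max = "auto") {
  stopifnot(inherits(g, "ppi_network"))
  if (k_min < 3) stop("k_min must be >= 3")
  if (identical(k_max, "auto")) {
    ig <- .as_igraph(g)
    k_max <- if (igraph::vcount(ig) == 0L) 0L else igraph::clique_num(ig)
  }
  clusters <- list()
  if (k_max >= k_min) {
    for (k in seq(as.integer(k_min), as.integer(k_max))) {
      clusters <- c(clusters, find_k_cliques(g, k), k_clique_communities(g, k))
    }
  }
  key <- vapply(clusters, function(x)
    paste(x$kind, x$k, paste(x$members, collapse = ","), sep = "|"), "")
  clusters <- clusters[!duplicated(key)]
  cluster_set(clusters)
}

#' Assemble a cluster_set from a list of clusters
#'
#' @param clusters list of records with `members`, `kind`, `k`.
#' @return A `cluster_set` (see [build_cluster_set()]).
#' @export
cluster_set <- function(clusters) {
  prot <- sort(unique(unlist(lapply(clusters, `[[`, "members"))))
  index <- stats::setNames(rep(list(integer(0)), length(prot)), prot)
  for (i in seq_along(clusters))
    for (p in clusters[[i]]$members)
      index[[p]] <- c(index[[p]], i)
  structure(list(clusters = clusters, index = index), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  kinds <- vapply(x$clusters, `[[`, "", "kind")
  cat("cluster_set: ", length(x$clusters), " clusters (",
      sum(kinds == "clique"), " cliques, ", sum(kinds == "community"),
      " communities)\n", sep = "")
  invisible(x)
}
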