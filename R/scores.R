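# 2x2 contingency cells between a function-node protein set and a cluster,
# within a fixed protein universe:
#   a = |FN  n C|,  b = |FN n C^c|,  c = |FN^c n C|,  d = |FN^c n C^c|
.overlap_cells <- function(fn, cl, universe) {
  a <- length(intersect(fn, cl))
  b <- length(fn) - a
  c_ <- length(cl) - a
  d <- length(universe) - a - b - c_
  c(a = a, b = b, c = c_, d = d)
}

#' Protein membership score (PMS)
#'
#' Scores how plausibly a protein belongs to a function node, as the best
#' match between the node's protein set and any topological cluster
#' (k-clique or clique-percolation community) containing the protein. The
#' default `simple_matching` score is the proportion of the protein universe
#' on which the node and the cluster agree, 100*(a+d)/|universe| where a is
#' the overlap and d the shared exclusions; it is 100 exactly when the node
#' coincides with the cluster. The `literal` variant evaluates
#' 100*(a+d)/(a + c + 2d), with c the cluster members outside the node.
#'
#' @param p protein id; must be a member of `fn_proteins`.
#' @param fn_proteins character vector, the function node's protein set.
#' @param clusters a `cluster_set` (see [build_cluster_set()]).
#' @param universe character vector of all network protein ids.
#' @param formula `"simple_matching"` (default) or `"literal"`.
#' @return Percentage in \[0, 100\]; 0 when `p` belongs to no cluster.
#' @export
pms <- function(p, fn_proteins, clusters, universe,
                formula = c("simple_matching", "literal")) {
  formula <- match.arg(formula)
  stopifnot(inherits(clusters, "cluster_set"))
  if (!p %in% fn_proteins) stop("protein ", p, " is not a member of the function node")
  idx <- clusters$index[[p]]
  if (is.null(idx) || !length(idx)) return(0)
  best <- 0
  for (i in idx) {
    cells <- .overlap_cells(fn_proteins, clusters$clusters[[i]]$members, universe)
    s <- .pms_score(cells, length(universe), formula)
    if (s > best) best <- s
  }
  best
}

.pms_score <- function(cells, n_universe, formula) {
  a <- cells[["a"]]; c_ <- cells[["c"]]; d <- cells[["d"]]
  if (formula == "simple_matching") {
    if (n_universe == 0L) return(0)
    100 * (a + d) / n_universe
  } else {
    den <- a + c_ + 2 * d
    if (den == 0) return(0)
    100 * (a + d) / den
  }
}

#' Node topological score (NTS)
#'
#' Scores a function node by its best overlap with any topological cluster.
#' The default `jaccard` score is 100*|FN n C|/|FN u C|; the `literal`
#' variant evaluates 100*a/(a + b + d), with b the node proteins outside the
#' cluster and d the proteins in neither set.
#'
#' @param fn_proteins character vector, the function node's protein set.
#' @param clusters a `cluster_set`.
#' @param universe character vector of all network protein ids (used by the
#'   `literal` variant).
#' @param formula `"jaccard"` (default) or `"literal"`.
#' @return Percentage in \[0, 100\]; 0 for an empty cluster set.
#' @export
nts <- function(fn_proteins, clusters, universe,
                formula = c("jaccard", "literal")) {
  formula <- match.arg(formula)
  stopifnot(inherits(clusters, "cluster_set"))
  best <- 0
  for (cl in clusters$clusters) {
    cells <- .overlap_cells(fn_proteins, cl$members, universe)
    a <- cells[["a"]]
    den <- if (formula == "jaccard") a + cells[["b"]] + cells[["c"]]
           else a + cells[["b"]] + cells[["d"]]
    s <- if (den == 0) 0 else 100 * a / den
    if (s > best) best <- s
  }
  best
}
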