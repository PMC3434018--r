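#' Default assay classification table
#'
#' Maps interaction-detection assay names to the two classes used when
#' counting edge evidence: `binary` assays report bona fide direct contacts,
#' `cluster` assays report co-membership in a complex.
#'
#' @return Named character vector, assay name -> `"binary"` or `"cluster"`.
#' @export
default_assay_classes <- function() {
  c("Two-hybrid"              = "binary",
    "Biochemical Activity"    = "binary",
    "PCA"                     = "binary",
    "Affinity Capture-MS"     = "cluster",
    "Affinity Capture-Western" = "cluster",
    "Co-crystal Structure"    = "cluster",
    "Co-fractionation"        = "cluster",
    "Co-localization"         = "cluster",
    "Co-purification"         = "cluster",
    "Far Western"             = "cluster",
    "Reconstituted Complex"   = "cluster")
}

.classify_assays <- function(assays, assay_table,
                             unknown = c("warn_cluster", "warn_binary", "error")) {
  unknown <- match.arg(unknown)
  cls <- unname(assay_table[assays])
  if (anyNA(cls)) {
    bad <- unique(assays[is.na(cls)])
    if (unknown == "error") stop("unknown assay name(s): ", paste(bad, collapse = ", "))
    fill <- if (unknown == "warn_cluster") "cluster" else "binary"
    warning("unknown assay name(s) classified as ", fill, ": ",
            paste(bad, collapse = ", "))
    cls[is.na(cls)] <- fill
  }
  cls
}

#' Build a protein-protein interaction network
#'
#' Constructs a simple undirected protein graph from an edge table. Self
#' interactions are dropped (with a warning) and duplicate records of the
#' same unordered pair are merged, pooling their assay names. Each merged
#' interaction carries the set of assay classes (`binary`, `cluster`) of its
#' assays.
#'
#' @param edges data.frame with columns `a`, `b` (protein ids) and optional
#'   `assay` (assay name; multiple records per pair allowed).
#' @param core optional character vector of core (domain) protein ids;
#'   `NULL` marks every protein as core.
#' @param assay_table named character vector as [default_assay_classes()].
#' @param unknown_assay policy for assay names missing from `assay_table`.
#' @return An object of class `ppi_network`: list with `proteins`
#'   (data.frame `id`, `is_core`), `interactions` (data.frame `a`, `b`,
#'   `assays`, `is_binary`, `is_cluster`; `a < b`) and `log` (named counts of
#'   records read / kept / merged / self-dropped).
#' @export
ppi_network <- function(edges, core = NULL, assay_table = default_assay_classes(),
                        unknown_assay = "warn_cluster") {
  if (!all(c("a", "b") %in% names(edges)))
    stop("edge table must have columns 'a' and 'b'")
  a <- as.character(edges$a); b <- as.character(edges$b)
  assay <- if ("assay" %in% names(edges)) as.character(edges$assay)
           else rep(NA_character_, length(a))
  n_read <- length(a)

  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-interaction(s) dropped")
    a <- a[!self]; b <- b[!self]; assay <- assay[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key)
  lo <- lo[ord]; hi <- hi[ord]; assay <- assay[ord]; key <- key[ord]
  first <- !duplicated(key)
  assays <- split(assay, factor(key, levels = unique(key)))
  assays <- lapply(assays, function(x) sort(unique(x[!is.na(x)])))
  lo <- lo[first]; hi <- hi[first]

  is_binary <- logical(length(lo)); is_cluster <- logical(length(lo))
  for (i in seq_along(assays)) {
    if (length(assays[[i]])) {
      cls <- .classify_assays(assays[[i]], assay_table, unknown_assay)
      is_binary[i] <- any(cls == "binary")
      is_cluster[i] <- any(cls == "cluster")
    }
  }
  prot <- sort(unique(c(lo, hi)))
  is_core <- if (is.null(core)) rep(TRUE, length(prot)) else prot %in% as.character(core)

  structure(list(
    proteins = data.frame(id = prot, is_core = is_core, stringsAsFactors = FALSE),
    interactions = data.frame(a = lo, b = hi,
                              assays = vapply(assays, paste, "", collapse = ";"),
                              is_binary = is_binary, is_cluster = is_cluster,
                              stringsAsFactors = FALSE),
    log = c(read = n_read, self_dropped = sum(self),
            merged = (n_read - sum(self)) - length(lo), kept = length(lo))
  ), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network: ", nrow(x$proteins), " proteins (",
      sum(x$proteins$is_core), " core), ", nrow(x$interactions),
      " interactions\n", sep = "")
  invisible(x)
}

# igraph view of the network (vertices carry protein ids)
.as_igraph <- function(g) {
  stopifnot(inherits(g, "ppi_network"))
  igraph::graph_from_data_frame(
    g$interactions[, c("a", "b")], directed = FALSE,
    vertices = g$proteins$id)
}

#' Descriptive statistics of a PPI network
#'
#' @param g a [ppi_network].
#' @return List with `n_proteins`, `n_interactions`, `mean_degree`
#'   (2 edges / nodes), `clustering` (mean local transitivity; nodes of
#'   degree < 2 contribute 0) and `path_length` (mean shortest-path length
#'   over connected pairs; computed on the largest connected component when
#'   the graph is disconnected, with a message). All statistics are `NA` on
#'   an empty network.
#' @export
network_summary <- function(g) {
  stopifnot(inherits(g, "ppi_network"))
  n <- nrow(g$proteins); m <- nrow(g$interactions)
  if (n == 0L)
    return(list(n_proteins = 0L, n_interactions = 0L, mean_degree = NA_real_,
                clustering = NA_real_, path_length = NA_real_))
  ig <- .as_igraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    message("network is disconnected; path length computed on the largest component")
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(ig, which(comp$membership == big))
    pl <- if (igraph::vcount(sub) > 1L) igraph::mean_distance(sub) else NA_real_
  } else {
    pl <- if (n > 1L) igraph::mean_distance(ig) else NA_real_
  }
  list(n_proteins = n, n_interactions = m,
       mean_degree = 2 * m / n,
       clustering = mean(cc),
       path_length = pl)
}
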