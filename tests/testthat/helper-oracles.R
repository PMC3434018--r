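# Independent brute-force oracles used to cross-check the implementation.
# They share no code with the package internals: ancestors/depth enumerate
# directed paths explicitly, clique and community finders enumerate vertex
# subsets, and the score oracles work on 0/1 membership vectors.

# --- ontology oracles (operate on a plain child -> parents list) -----------

oracle_all_root_paths <- function(parent_list, t) {
  ps <- parent_list[[t]]
  if (is.null(ps) || !length(ps)) return(list(t))
  out <- list()
  for (p in ps)
    for (path in oracle_all_root_paths(parent_list, p))
      out[[length(out) + 1L]] <- c(t, path)
  out
}

oracle_ancestors <- function(parent_list, t) {
  paths <- oracle_all_root_paths(parent_list, t)
  sort(setdiff(unique(unlist(paths)), t))
}

oracle_depth <- function(parent_list, t, longest = TRUE) {
  lens <- vapply(oracle_all_root_paths(parent_list, t), length, 1L) - 1L
  if (longest) max(lens) else min(lens)
}

# random DAG as (ids, links): each term may link to earlier terms only
random_dag <- function(n_terms, p_link = 0.4) {
  ids <- paste0("t", seq_len(n_terms))
  child <- character(0); parent <- character(0)
  for (i in seq_len(n_terms)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p_link) {
        child <- c(child, ids[i]); parent <- c(parent, ids[j])
      }
    }
    if (!length(child) || child[length(child)] != ids[i]) {
      # guarantee connectivity to some earlier term
      child <- c(child, ids[i]); parent <- c(parent, ids[sample.int(i - 1L, 1L)])
    }
  }
  list(ids = ids,
       links = data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
}

parent_list_of <- function(links, ids) {
  pl <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (i in seq_len(nrow(links)))
    pl[[links$child[i]]] <- union(pl[[links$child[i]]], links$parent[i])
  pl
}

# --- clique / community oracles (operate on an edge data.frame) ------------

oracle_adjacent <- function(edges, u, v) {
  any((edges$a == u & edges$b == v) | (edges$a == v & edges$b == u))
}

oracle_k_cliques <- function(edges, vertices, k) {
  if (length(vertices) < k) return(list())
  combos <- utils::combn(sort(vertices), k, simplify = FALSE)
  keep <- Filter(function(s) {
    pairs <- utils::combn(s, 2L)
    all(vapply(seq_len(ncol(pairs)), function(i)
      oracle_adjacent(edges, pairs[1L, i], pairs[2L, i]), TRUE))
  }, combos)
  lapply(keep, sort)
}

oracle_k_clique_communities <- function(edges, vertices, k) {
  cl <- oracle_k_cliques(edges, vertices, k)
  if (!length(cl)) return(list())
  n <- length(cl)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (length(intersect(cl[[i]], cl[[j]])) >= k - 1L && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed || n == 1L) break
  }
  out <- lapply(unique(comp), function(cc) sort(unique(unlist(cl[comp == cc]))))
  out[order(vapply(out, paste, "", collapse = ","))]
}

random_ppi <- function(n, p, binary_fraction = 0.5) {
  v <- paste0("p", seq_len(n))
  a <- character(0); b <- character(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    if (stats::runif(1) < p) { a <- c(a, v[i]); b <- c(b, v[j]) }
  if (!length(a)) { a <- v[1L]; b <- v[2L] }
  assay <- ifelse(stats::runif(length(a)) < binary_fraction,
                  "Two-hybrid", "Affinity Capture-MS")
  ppi_network(data.frame(a = a, b = b, assay = assay, stringsAsFactors = FALSE))
}

cluster_members <- function(cs, kind = NULL, k = NULL) {
  sel <- cs$clusters
  if (!is.null(kind)) sel <- Filter(function(x) x$kind == kind, sel)
  if (!is.null(k)) sel <- Filter(function(x) x$k == k, sel)
  out <- lapply(sel, `[[`, "members")
  out[order(vapply(out, paste, "", collapse = ","))]
}

# --- score oracles on 0/1 membership vectors --------------------------------

oracle_pms <- function(p, fn, clusters_members, universe, formula) {
  in_fn <- as.integer(universe %in% fn)
  best <- 0
  for (cm in clusters_members) {
    if (!(p %in% cm)) next
    in_c <- as.integer(universe %in% cm)
    a <- sum(in_fn == 1 & in_c == 1); c_ <- sum(in_fn == 0 & in_c == 1)
    d <- sum(in_fn == 0 & in_c == 0)
    s <- if (formula == "simple_matching") 100 * (a + d) / length(universe)
         else { den <- a + c_ + 2 * d; if (den == 0) 0 else 100 * (a + d) / den }
    best <- max(best, s)
  }
  best
}

oracle_nts <- function(fn, clusters_members, universe, formula) {
  in_fn <- as.integer(universe %in% fn)
  best <- 0
  for (cm in clusters_members) {
    in_c <- as.integer(universe %in% cm)
    a <- sum(in_fn == 1 & in_c == 1); b <- sum(in_fn == 1 & in_c == 0)
    c_ <- sum(in_fn == 0 & in_c == 1); d <- sum(in_fn == 0 & in_c == 0)
    den <- if (formula == "jaccard") a + b + c_ else a + b + d
    s <- if (den == 0) 0 else 100 * a / den
    best <- max(best, s)
  }
  best
}

# random pipeline inputs for fuzz tests
random_pipeline_inputs <- function(n_prot = 10, n_terms = 8, p_edge = 0.35) {
  ppi <- random_ppi(n_prot, p_edge)
  dag_spec <- random_dag(n_terms, p_link = 0.3)
  dag <- ontology_dag(dag_spec$ids, dag_spec$links)
  prot <- ppi$proteins$id
  ann <- stats::setNames(lapply(prot, function(p)
    sample(dag_spec$ids, sample.int(3L, 1L))), prot)
  list(ppi = ppi, dag = dag, ann = ann)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
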