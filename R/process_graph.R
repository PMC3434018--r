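# Node id convention: numeric tail of a term id ("GO:0045046" -> "45046"),
# mirroring the usual short way of citing GO-derived nodes; non GO-like term
# ids are used verbatim. Merged nodes concatenate ids with "+".
.term_node_id <- function(term) {
  if (grepl("^[A-Za-z_]+:\\d+$", term)) {
    digits <- sub("^[A-Za-z_]+:", "", term)
    digits <- sub("^0+(?=\\d)", "", digits, perl = TRUE)
    digits
  } else term
}

.empty_edges <- function() {
  data.frame(from = character(0), to = character(0),
             shared_proteins = integer(0), crossing_binary = integer(0),
             crossing_total = integer(0), dir_from = character(0),
             dir_to = character(0), rule_tag = integer(0), note = character(0),
             stringsAsFactors = FALSE)
}

.sort_nodes <- function(fns) {
  if (!length(fns)) return(fns)
  fns[order(vapply(fns, `[[`, "", "id"))]
}

#' Pipeline configuration
#'
#' Collects every tunable of the network-to-process-graph pipeline with its
#' default. Thresholds are percentages in \[0, 100\].
#'
#' @param pms_threshold protein membership score above which a protein is
#'   retained in a function node even when another node explains it better
#'   (default 95).
#' @param nts_threshold node topological score below which a function node
#'   is removed in the final reduction (default 0 = keep all).
#' @param k_min,k_max clique-order range for the cluster set; `k_max =
#'   "auto"` uses the largest order with at least one clique.
#' @param membership_mode `"per_protein"` (default: a protein's scores are
#'   compared across the nodes containing it) or `"per_node"` (scores are
#'   compared within each node across its proteins).
#' @param pms_formula,nts_formula score variants, see [pms()] and [nts()].
#' @param edge_policy `"binary_only"` (default: only binary-assay crossing
#'   interactions count as edge evidence) or `"any_assay"`.
#' @param include_parent_seeding also seed function nodes from terms that
#'   are shared parents of two interacting proteins' annotations (default
#'   `TRUE`).
#' @param parent_specificity_filter additionally require injected parent
#'   terms to pass the most-specific filter against the directly shared
#'   terms (default `FALSE`).
#' @param depth_method term-depth convention used when merging labels, see
#'   [term_depth()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pms_threshold = 95, nts_threshold = 0,
                            k_min = 3, k_max = "auto",
                            membership_mode = c("per_protein", "per_node"),
                            pms_formula = c("simple_matching", "literal"),
                            nts_formula = c("jaccard", "literal"),
                            edge_policy = c("binary_only", "any_assay"),
                            include_parent_seeding = TRUE,
                            parent_specificity_filter = FALSE,
                            depth_method = c("longest", "shortest")) {
  stopifnot(pms_threshold >= 0, pms_threshold <= 100,
            nts_threshold >= 0, nts_threshold <= 100, k_min >= 3)
  structure(list(
    pms_threshold = pms_threshold, nts_threshold = nts_threshold,
    k_min = k_min, k_max = k_max,
    membership_mode = match.arg(membership_mode),
    pms_formula = match.arg(pms_formula),
    nts_formula = match.arg(nts_formula),
    edge_policy = match.arg(edge_policy),
    include_parent_seeding = isTRUE(include_parent_seeding),
    parent_specificity_filter = isTRUE(parent_specificity_filter),
    depth_method = match.arg(depth_method)
  ), class = "pipeline_config")
}

#' Seed function nodes from shared annotations of interacting proteins
#'
#' For every interacting protein pair, every term annotating both partners
#' (and, optionally, every term that is a shared direct parent of their
#' annotations) seeds or extends a function node keyed by that term. A
#' function node therefore always contains at least two proteins joined by
#' an internal interaction.
#'
#' @param g a [ppi_network].
#' @param annmap named list, protein id -> character vector of term ids
#'   (expected to be already reduced to most-specific terms).
#' @param dag an [ontology_dag].
#' @param include_parents seed from shared parent terms as well.
#' @param parent_specificity_filter require injected parents to pass
#'   [most_specific_terms()] against the directly shared terms.
#' @return List of function nodes, each a list with `id`, `terms`,
#'   `proteins`, `nts` (NA until scored) and `history`.
#' @export
seed_function_nodes <- function(g, annmap, dag, include_parents = TRUE,
                                parent_specificity_filter = FALSE) {
  stopifnot(inherits(g, "ppi_network"), inherits(dag, "ontology_dag"))
  unknown <- setdiff(names(annmap), g$proteins$id)
  if (length(unknown)) {
    warning("ignoring annotations of ", length(unknown),
            " protein(s) absent from the network")
    annmap <- annmap[setdiff(names(annmap), unknown)]
  }
  parent_union <- function(terms)
    unique(unlist(lapply(terms, function(t) dag$parents[[t]]), use.names = FALSE))

  fn_map <- new.env(parent = emptyenv())
  add <- function(term, v, w) {
    cur <- fn_map[[term]]
    fn_map[[term]] <- if (is.null(cur)) c(v, w) else unique(c(cur, v, w))
  }
  for (i in seq_len(nrow(g$interactions))) {
    v <- g$interactions$a[i]; w <- g$interactions$b[i]
    tv <- annmap[[v]]; tw <- annmap[[w]]
    if (is.null(tv) || is.null(tw)) next
    seeds <- intersect(tv, tw)
    if (include_parents) {
      shared_pa <- intersect(parent_union(tv), parent_union(tw))
      if (length(shared_pa) && parent_specificity_filter)
        shared_pa <- intersect(shared_pa,
                               most_specific_terms(dag, union(seeds, shared_pa)))
      seeds <- union(seeds, shared_pa)
    }
    for (t in seeds) add(t, v, w)
  }
  terms <- sort(ls(fn_map))
  ids <- vapply(terms, .term_node_id, "")
  if (anyDuplicated(ids)) ids[duplicated(ids) | duplicated(ids, fromLast = TRUE)] <-
    terms[duplicated(ids) | duplicated(ids, fromLast = TRUE)]
  fns <- lapply(seq_along(terms), function(i)
    list(id = ids[[i]], terms = terms[[i]],
         proteins = sort(fn_map[[terms[[i]]]]),
         nts = NA_real_, history = "seeded"))
  .sort_nodes(Filter(function(x) length(x$proteins) >= 2L, fns))
}

#' Prune redundant protein-to-node assignments by PMS
#'
#' Each protein is retained only in the function nodes that best overlap the
#' topological clusters it belongs to. In the default `per_protein` mode a
#' protein's scores are compared across all nodes containing it: it is
#' removed from every node where its score is below both its maximum and the
#' retention threshold. In `per_node` mode the comparison is within each
#' node, against the best-scoring of its proteins. Nodes left with fewer
#' than two proteins are discarded.
#'
#' @param fns list of function nodes (see [seed_function_nodes()]).
#' @param clusters a `cluster_set`.
#' @param universe character vector of all network protein ids.
#' @param pms_threshold retention threshold, percent (default 95).
#' @param mode `"per_protein"` or `"per_node"`.
#' @param formula PMS variant, see [pms()].
#' @return Pruned list of function nodes; each node gains a `pms` element,
#'   a named vector of its retained proteins' scores.
#' @export
refine_by_pms <- function(fns, clusters, universe, pms_threshold = 95,
                          mode = c("per_protein", "per_node"),
                          formula = c("simple_matching", "literal")) {
  mode <- match.arg(mode); formula <- match.arg(formula)
  if (!length(fns)) return(fns)
  scores <- lapply(fns, function(fn)
    vapply(fn$proteins, function(p)
      pms(p, fn$proteins, clusters, universe, formula), 0))

  if (mode == "per_protein") {
    pmax_by_protein <- new.env(parent = emptyenv())
    for (i in seq_along(fns)) for (p in fns[[i]]$proteins) {
      s <- scores[[i]][[p]]
      cur <- pmax_by_protein[[p]]
      if (is.null(cur) || s > cur) pmax_by_protein[[p]] <- s
    }
    keep_protein <- function(i, p) {
      s <- scores[[i]][[p]]
      s >= pmax_by_protein[[p]] || s >= pms_threshold
    }
  } else {
    node_max <- vapply(scores, function(s) if (length(s)) max(s) else 0, 0)
    keep_protein <- function(i, p) {
      s <- scores[[i]][[p]]
      s >= node_max[[i]] || s >= pms_threshold
    }
  }

  out <- lapply(seq_along(fns), function(i) {
    fn <- fns[[i]]
    keep <- vapply(fn$proteins, function(p) keep_protein(i, p), TRUE)
    removed <- fn$proteins[!keep]
    fn$proteins <- fn$proteins[keep]
    fn$pms <- scores[[i]][keep]
    if (length(removed))
      fn$history <- c(fn$history,
                      paste0("pruned-by-PMS:", paste(removed, collapse = ",")))
    fn
  })
  .sort_nodes(Filter(function(x) length(x$proteins) >= 2L, out))
}

#' Merge function nodes with identical protein content
#'
#' Nodes covering exactly the same proteins are collapsed into one node that
#' keeps only the most specific (deepest) of their term labels; ties keep
#' all deepest labels, and the merged node id concatenates the retained
#' labels' ids with `"+"`.
#'
#' @param fns list of function nodes.
#' @param dag an [ontology_dag] providing term depths.
#' @param depth_method see [term_depth()].
#' @return List of function nodes with pairwise distinct protein sets.
#' @export
merge_identical <- function(fns, dag, depth_method = "longest") {
  if (length(fns) <= 1L) return(fns)
  key <- vapply(fns, function(x) paste(x$proteins, collapse = "\r"), "")
  groups <- split(seq_along(fns), key)
  out <- lapply(groups, function(idx) {
    if (length(idx) == 1L) return(fns[[idx]])
    members <- fns[idx]
    terms <- sort(unique(unlist(lapply(members, `[[`, "terms"))))
    depths <- vapply(terms, function(t) term_depth(dag, t, depth_method), 1L)
    keep_terms <- terms[depths == max(depths)]
    ids <- sort(vapply(keep_terms, .term_node_id, ""))
    list(id = paste(ids, collapse = "+"),
         terms = keep_terms,
         proteins = members[[1L]]$proteins,
         nts = NA_real_,
         history = c(unlist(lapply(members, `[[`, "history")),
                     paste0("merged-from:",
                            paste(vapply(members, `[[`, "", "id"), collapse = ","))))
  })
  .sort_nodes(unname(out))
}

#' Enucleate nested function nodes
#'
#' Whenever one node's protein set is a proper subset of another's, the
#' nested function is carved out: the subset is removed from the larger
#' node, so each function is represented once. Subtractions are applied in a
#' fixed order (largest node first, ties by id) and iterated to a fixpoint;
#' nodes left with fewer than two proteins are discarded.
#'
#' @param fns list of function nodes with pairwise distinct protein sets
#'   (run [merge_identical()] first).
#' @return List of function nodes with no proper-subset relation left.
#' @export
enucleate <- function(fns) {
  repeat {
    changed <- FALSE
    ord <- order(-vapply(fns, function(x) length(x$proteins), 1L),
                 vapply(fns, `[[`, "", "id"))
    fns <- fns[ord]
    for (h in seq_along(fns)) {
      for (k in seq_along(fns)) {
        if (h == k) next
        ph <- fns[[h]]$proteins; pk <- fns[[k]]$proteins
        if (length(pk) < length(ph) && all(pk %in% ph)) {
          fns[[h]]$proteins <- setdiff(ph, pk)
          fns[[h]]$history <- c(fns[[h]]$history,
                                paste0("enucleated-by:", fns[[k]]$id))
          changed <- TRUE
        }
      }
    }
    fns <- Filter(function(x) length(x$proteins) >= 2L, fns)
    if (!changed) break
  }
  .sort_nodes(fns)
}

# crossing interactions between two protein sets: one endpoint in each,
# excluding interactions internal to either set and any globally excluded ones
.crossing_counts <- function(interactions, p1, p2, excluded = FALSE) {
  a1 <- interactions$a %in% p1; b1 <- interactions$b %in% p1
  a2 <- interactions$a %in% p2; b2 <- interactions$b %in% p2
  crossing <- ((a1 & b2) | (a2 & b1)) & !(a1 & b1) & !(a2 & b2) & !excluded
  c(total = sum(crossing), binary = sum(crossing & interactions$is_binary))
}

# an interaction with both endpoints inside a single function node is an
# internal PPI of that node: it defines the node and is never crossing
# evidence for any node pair
.internal_flags <- function(interactions, fns) {
  flags <- rep(FALSE, nrow(interactions))
  for (fn in fns) {
    inside <- interactions$a %in% fn$proteins & interactions$b %in% fn$proteins
    flags <- flags | inside
  }
  flags
}

#' Build edges among function nodes
#'
#' Two function nodes are linked when they share more than one protein or
#' are joined by more than one qualifying crossing interaction. Every
#' interaction is either internal (both endpoints inside one function node;
#' such interactions define nodes) or crossing; only crossing interactions
#' with one endpoint in each node of the pair provide edge evidence, so a
#' dependency mediated entirely inside a third node never links its two
#' neighbours directly. Under the default `binary_only` policy only
#' crossing interactions detected by a binary assay qualify; a single
#' shared protein or a single crossing interaction is never sufficient.
#'
#' @param fns list of function nodes.
#' @param g a [ppi_network].
#' @param edge_policy `"binary_only"` or `"any_assay"`.
#' @return Edge data.frame (`from`, `to`, evidence counters, empty
#'   direction columns), one row per linked unordered node pair, `from < to`.
#' @export
build_edges <- function(fns, g, edge_policy = c("binary_only", "any_assay")) {
  edge_policy <- match.arg(edge_policy)
  internal <- .internal_flags(g$interactions, fns)
  .edges_impl(fns, g, function(shared, cnt) {
    qualifying <- if (edge_policy == "binary_only") cnt[["binary"]] else cnt[["total"]]
    shared > 1L || qualifying > 1L
  }, excluded = internal)
}

#' Baseline (single-evidence) edges among function nodes
#'
#' Comparison mode reproducing the permissive linkage rule of earlier
#' function-linkage approaches: any single shared protein or any single
#' interaction between the two nodes (any assay class, and regardless of
#' whether it is internal to some third node) links them. Always a
#' superset of [build_edges()] output on the same input.
#'
#' @inheritParams build_edges
#' @return Edge data.frame as in [build_edges()].
#' @export
baseline_edges <- function(fns, g) {
  .edges_impl(fns, g, function(shared, cnt) shared >= 1L || cnt[["total"]] >= 1L)
}

.edges_impl <- function(fns, g, criterion, excluded = FALSE) {
  stopifnot(inherits(g, "ppi_network"))
  fns <- .sort_nodes(fns)
  n <- length(fns)
  rows <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pi_ <- fns[[i]]$proteins; pj <- fns[[j]]$proteins
    shared <- length(intersect(pi_, pj))
    cnt <- .crossing_counts(g$interactions, pi_, pj, excluded)
    if (criterion(shared, cnt))
      rows[[length(rows) + 1L]] <- data.frame(
        from = fns[[i]]$id, to = fns[[j]]$id,
        shared_proteins = shared,
        crossing_binary = cnt[["binary"]], crossing_total = cnt[["total"]],
        dir_from = NA_character_, dir_to = NA_character_,
        rule_tag = NA_integer_, note = NA_character_,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_edges())
  out <- do.call(rbind, rows)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Construct a process graph object
#'
#' @param nodes list of function nodes.
#' @param edges edge data.frame as produced by [build_edges()].
#' @param core character vector of core protein ids (used for core-fraction
#'   selection and reporting).
#' @param config the [pipeline_config()] used.
#' @param report named list of per-stage counts.
#' @return Object of class `process_graph`.
#' @export
process_graph <- function(nodes, edges = .empty_edges(), core = character(0),
                          config = pipeline_config(), report = list()) {
  nodes <- .sort_nodes(nodes)
  ids <- vapply(nodes, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids),
            all(edges$from %in% ids), all(edges$to %in% ids),
            all(edges$from < edges$to))
  structure(list(nodes = nodes, edges = edges, core = core,
                 config = config, report = report),
            class = "process_graph")
}

#' Node table of a process graph
#'
#' @param pg a `process_graph`.
#' @return data.frame with one row per function node: `id`, `terms`
#'   (";"-joined), `n_proteins`, `proteins` (";"-joined), `nts`,
#'   `core_fraction`.
#' @export
pg_nodes <- function(pg) {
  stopifnot(inherits(pg, "process_graph"))
  if (!length(pg$nodes))
    return(data.frame(id = character(0), terms = character(0),
                      n_proteins = integer(0), proteins = character(0),
                      nts = numeric(0), core_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    id = vapply(pg$nodes, `[[`, "", "id"),
    terms = vapply(pg$nodes, function(x) paste(x$terms, collapse = ";"), ""),
    n_proteins = vapply(pg$nodes, function(x) length(x$proteins), 1L),
    proteins = vapply(pg$nodes, function(x) paste(x$proteins, collapse = ";"), ""),
    nts = vapply(pg$nodes, function(x) as.numeric(x$nts), 0),
    core_fraction = vapply(pg$nodes, function(x) {
      if (!length(pg$core)) return(NA_real_)
      length(intersect(x$proteins, pg$core)) / length(x$proteins)
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Score every function node with its NTS
#'
#' @param fns list of function nodes.
#' @param clusters a `cluster_set`.
#' @param universe all network protein ids.
#' @param formula NTS variant, see [nts()].
#' @return The nodes with `nts` filled in.
#' @export
assign_nts <- function(fns, clusters, universe, formula = "jaccard") {
  lapply(fns, function(fn) {
    fn$nts <- nts(fn$proteins, clusters, universe, formula)
    fn
  })
}

#' Reduce a process graph by NTS threshold
#'
#' Removes every function node whose node topological score falls below the
#' threshold, together with its incident edges.
#'
#' @param pg a `process_graph` with NTS assigned.
#' @param threshold percentage in \[0, 100\].
#' @return The reduced `process_graph`.
#' @export
reduce_by_nts <- function(pg, threshold) {
  stopifnot(inherits(pg, "process_graph"))
  keep <- vapply(pg$nodes, function(x) !is.na(x$nts) && x$nts >= threshold, TRUE)
  .subset_pg(pg, keep)
}

.subset_pg <- function(pg, keep) {
  nodes <- pg$nodes[keep]
  ids <- vapply(nodes, `[[`, "", "id")
  edges <- pg$edges[pg$edges$from %in% ids & pg$edges$to %in% ids, , drop = FALSE]
  row.names(edges) <- NULL
  process_graph(nodes, edges, pg$core, pg$config, pg$report)
}

#' Select function nodes by NTS and core-protein content
#'
#' Keeps a node when it satisfies at least one selection rule, each rule a
#' triple (minimum NTS, minimum core fraction, maximum core fraction). The
#' published style of use pairs a moderate NTS bound with a high core
#' fraction (domain-specific functions) and a high NTS bound with a low core
#' fraction (well-clustered neighbour functions).
#'
#' @param pg a `process_graph`.
#' @param rules list of numeric triples `c(nts_min, core_min, core_max)`.
#' @param core core protein ids; defaults to the graph's own core set.
#' @return The selected `process_graph`; an empty rule list returns `pg`
#'   unchanged.
#' @export
select_by_core_fraction <- function(pg, rules, core = pg$core) {
  stopifnot(inherits(pg, "process_graph"))
  if (!length(rules)) return(pg)
  keep <- vapply(pg$nodes, function(x) {
    frac <- if (length(x$proteins))
      length(intersect(x$proteins, core)) / length(x$proteins) else 0
    any(vapply(rules, function(r)
      !is.na(x$nts) && x$nts >= r[[1L]] && frac >= r[[2L]] && frac <= r[[3L]], TRUE))
  }, TRUE)
  .subset_pg(pg, keep)
}

#' Enumerate open triples as testable hypotheses
#'
#' Every open triple A-B-C (edges A-B and B-C present, A-C absent) admits
#' four candidate causal orientations (chain A->B->C, chain A<-B<-C, fork
#' A<-B->C, collider A->B<-C) and one experimental template: manipulate the
#' middle node B and assess A and C.
#'
#' @param pg a `process_graph`.
#' @return data.frame with columns `a`, `b` (the middle node), `c`,
#'   `hypotheses` (the four orientations, "|"-separated), `manipulate` and
#'   `assess`; one row per open triple, `a < c`.
#' @export
enumerate_triples <- function(pg) {
  stopifnot(inherits(pg, "process_graph"))
  ids <- vapply(pg$nodes, `[[`, "", "id")
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (r in seq_len(nrow(pg$edges))) {
    f <- pg$edges$from[r]; t <- pg$edges$to[r]
    adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
  }
  has_edge <- function(x, y) y %in% adj[[x]]
  rows <- list()
  for (b in sort(ids)) {
    nb <- sort(adj[[b]])
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) for (j in seq(i + 1L, length(nb))) {
      a <- nb[i]; c_ <- nb[j]
      if (has_edge(a, c_)) next
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, b = b, c = c_,
        hypotheses = paste(
          paste0(a, "->", b, "->", c_), paste0(a, "<-", b, "<-", c_),
          paste0(a, "<-", b, "->", c_), paste0(a, "->", b, "<-", c_),
          sep = " | "),
        manipulate = b, assess = paste(a, c_, sep = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(a = character(0), b = character(0), c = character(0),
                      hypotheses = character(0), manipulate = character(0),
                      assess = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$b, out$a, out$c), , drop = FALSE]
}

#' Record an expert-supplied edge direction
#'
#' Directions are never inferred by the pipeline; this attaches a direction
#' judged by an expert, tagged with the class of evidence used (rules 1-6:
#' direct manipulation evidence, component-level evidence, logical
#' implication, temporal precedence, domain component knowledge, general
#' cell-biology plausibility).
#'
#' @param pg a `process_graph`.
#' @param from,to node ids of the edge (in either order); the direction
#'   recorded is `from -> to`.
#' @param rule integer 1-6 evidence tag.
#' @param note free-text justification.
#' @return The updated `process_graph`.
#' @export
set_edge_direction <- function(pg, from, to, rule, note = "") {
  stopifnot(inherits(pg, "process_graph"), rule %in% 1:6)
  lo <- pmin(from, to); hi <- pmax(from, to)
  r <- which(pg$edges$from == lo & pg$edges$to == hi)
  if (!length(r)) stop("no edge between ", from, " and ", to)
  pg$edges$dir_from[r] <- from; pg$edges$dir_to[r] <- to
  pg$edges$rule_tag[r] <- as.integer(rule); pg$edges$note[r] <- note
  pg
}

#' NTS threshold sweep
#'
#' Node and edge counts of the reduced graph across a grid of NTS
#' thresholds; both counts are non-increasing in the threshold.
#'
#' @param pg a `process_graph` with NTS assigned.
#' @param thresholds numeric vector of thresholds (default 0..100 by 5).
#' @return data.frame with columns `threshold`, `n_nodes`, `n_edges`.
#' @export
nts_sweep <- function(pg, thresholds = seq(0, 100, by = 5)) {
  stopifnot(inherits(pg, "process_graph"))
  res <- lapply(thresholds, function(t) {
    red <- reduce_by_nts(pg, t)
    data.frame(threshold = t, n_nodes = length(red$nodes),
               n_edges = nrow(red$edges))
  })
  do.call(rbind, res)
}

#' Run the full network-to-process-graph pipeline
#'
#' Executes, in order: reduction of each protein's annotations to their
#' most specific terms; seeding of function nodes from shared annotations of
#' interacting pairs; PMS-based pruning of redundant memberships against the
#' k-clique/community cluster set; merging of identical nodes and
#' enucleation of nested ones (iterated to convergence); NTS scoring; edge
#' construction; and NTS-threshold reduction. Deterministic given inputs
#' and configuration.
#'
#' @param ppi a [ppi_network].
#' @param ontology an [ontology_dag].
#' @param annotations either a named list (protein id -> term ids) or a
#'   data.frame with columns `protein` and `term`.
#' @param config a [pipeline_config()].
#' @param clusters optional precomputed `cluster_set` (built from `ppi` and
#'   the configured k range when omitted).
#' @param mode `"markov"` (default pipeline) or `"baseline"`: the baseline
#'   comparison mode skips PMS pruning and redundancy elimination and links
#'   nodes on any single piece of crossing evidence, reproducing the
#'   permissive behaviour of earlier function-linkage methods.
#' @return A `process_graph`; its `report` element carries node/edge counts
#'   after each stage.
#' @export
run_pipeline <- function(ppi, ontology, annotations, config = pipeline_config(),
                         clusters = NULL, mode = c("markov", "baseline")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ppi, "ppi_network"), inherits(ontology, "ontology_dag"))
  annmap <- .normalize_annotations(annotations)
  universe <- ppi$proteins$id
  core <- ppi$proteins$id[ppi$proteins$is_core]
  report <- list()

  # annotations restricted to the ontology, then most-specific filtering
  annmap <- lapply(annmap, function(terms) {
    known <- intersect(terms, ontology$ids)
    dropped <- setdiff(terms, known)
    if (length(dropped))
      warning("dropping term(s) absent from ontology: ",
              paste(dropped, collapse = ", "))
    known
  })
  annmap <- annmap[vapply(annmap, length, 1L) > 0L]
  annmap <- lapply(annmap, function(terms) most_specific_terms(ontology, terms))
  report$annotated_proteins <- length(annmap)

  if (is.null(clusters))
    clusters <- build_cluster_set(ppi, config$k_min, config$k_max)
  report$n_clusters <- length(clusters$clusters)

  fns <- seed_function_nodes(ppi, annmap, ontology,
                             include_parents = config$include_parent_seeding,
                             parent_specificity_filter = config$parent_specificity_filter)
  report$seeded <- length(fns)

  if (mode == "markov") {
    fns <- refine_by_pms(fns, clusters, universe, config$pms_threshold,
                         config$membership_mode, config$pms_formula)
    report$after_pms <- length(fns)

    # merge/enucleate to convergence: enucleation can create new identical sets
    repeat {
      before <- vapply(fns, function(x) paste(x$id, paste(x$proteins, collapse = ","), sep = "|"), "")
      fns <- merge_identical(fns, ontology, config$depth_method)
      fns <- enucleate(fns)
      after <- vapply(fns, function(x) paste(x$id, paste(x$proteins, collapse = ","), sep = "|"), "")
      if (identical(sort(before), sort(after))) break
    }
    report$after_merge_enucleate <- length(fns)
  }

  fns <- assign_nts(fns, clusters, universe, config$nts_formula)

  edges <- if (mode == "markov") build_edges(fns, ppi, config$edge_policy)
           else baseline_edges(fns, ppi)
  report$edges_built <- nrow(edges)

  pg <- process_graph(fns, edges, core, config, report)
  pg <- reduce_by_nts(pg, config$nts_threshold)
  pg$report <- c(report, list(final_nodes = length(pg$nodes),
                              final_edges = nrow(pg$edges)))
  pg
}

.normalize_annotations <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("protein", "term") %in% names(annotations)))
    ann <- split(as.character(annotations$term), as.character(annotations$protein))
    lapply(ann, unique)
  } else if (is.list(annotations)) {
    if (!length(annotations)) return(list())
    stopifnot(!is.null(names(annotations)))
    lapply(annotations, function(x) unique(as.character(x)))
  } else stop("annotations must be a named list or a protein/term data.frame")
}

#' @export
print.process_graph <- function(x, ...) {
  cat("process_graph: ", length(x$nodes), " function nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
summary.process_graph <- function(object, ...) {
  nt <- pg_nodes(object)
  cat("process_graph with ", nrow(nt), " function nodes and ",
      nrow(object$edges), " edges\n", sep = "")
  if (length(object$report)) {
    cat("pipeline stages:\n")
    for (nm in names(object$report))
      cat(sprintf("  %-24s %s\n", nm, object$report[[nm]]))
  }
  if (nrow(nt)) {
    cat("NTS: min ", format_score(min(nt$nts)), ", median ",
        format_score(stats::median(nt$nts)), ", max ",
        format_score(max(nt$nts)), "\n", sep = "")
  }
  invisible(nt)
}

#' @export
plot.process_graph <- function(x, ...) {
  ids <- vapply(x$nodes, `[[`, "", "id")
  ig <- igraph::graph_from_data_frame(
    if (nrow(x$edges)) x$edges[, c("from", "to")] else data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = ids)
  igraph::plot.igraph(ig, ...)
  invisible(x)
}

#' @export
as.data.frame.process_graph <- function(x, ...) pg_nodes(x)
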