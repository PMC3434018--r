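#' Specify a planted-module network model
#'
#' Describes a synthetic annotated PPI network with planted functional
#' modules arranged in a dependency chain: each module is a densely wired
#' protein set annotated with its own term, consecutive modules share
#' mediator proteins (and at least two guaranteed binary crossing
#' interactions), and annotation noise adds spurious terms that the
#' specificity filter and the PMS pruning are expected to remove. The
#' defaults emulate the modular organisation the method assumes: modules of
#' 6-10 proteins wired at density 0.9 against a sparse 0.02 background,
#' two-protein mediator overlaps, a 10% spurious-annotation rate and a
#' moderate share of binary-assay detections.
#'
#' @param module_sizes integer vector of module sizes (each >= 3).
#' @param p_in within-module interaction probability.
#' @param p_out between-module interaction probability.
#' @param mediator_overlap number of proteins shared by consecutive chain
#'   modules.
#' @param ontology_depth depth of the module terms below the root (>= 1);
#'   each module term sits at the end of its own chain of intermediate
#'   terms.
#' @param extra_annotation_rate probability that a protein gains one
#'   spurious annotation (half drawn from ancestors of its true term, half
#'   from another module's term).
#' @param binary_fraction probability that a random interaction is tagged
#'   with a binary assay.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `planted_model`.
#' @export
planted_model <- function(module_sizes = c(6, 8, 10), p_in = 0.9, p_out = 0.02,
                          mediator_overlap = 2, ontology_depth = 2,
                          extra_annotation_rate = 0.1, binary_fraction = 0.6,
                          seed = 1) {
  stopifnot(length(module_sizes) >= 1, all(module_sizes >= 3),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            mediator_overlap >= 0, ontology_depth >= 1,
            extra_annotation_rate >= 0, extra_annotation_rate <= 1,
            binary_fraction >= 0, binary_fraction <= 1)
  n <- length(module_sizes)
  if (n > 1L) {
    if (mediator_overlap > min(module_sizes[c(1L, n)]))
      stop("mediator_overlap exceeds an end module's size")
    if (n > 2L && any(2 * mediator_overlap > module_sizes[2:(n - 1L)]))
      stop("mediator_overlap too large for a middle module (needs 2*overlap slots)")
  }
  structure(list(module_sizes = as.integer(module_sizes), p_in = p_in,
                 p_out = p_out, mediator_overlap = as.integer(mediator_overlap),
                 ontology_depth = as.integer(ontology_depth),
                 extra_annotation_rate = extra_annotation_rate,
                 binary_fraction = binary_fraction, seed = as.integer(seed)),
            class = "planted_model")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a planted annotated network
#'
#' Realises a [planted_model()]: wires each module internally with
#' probability `p_in` and across modules with probability `p_out`, makes
#' consecutive modules share `mediator_overlap` proteins plus two
#' guaranteed binary crossing interactions, annotates each module's
#' proteins with the module's term (mediators carry both), adds annotation
#' noise, and builds the matching tree ontology. Reproducible: the same
#' model (same seed) always yields identical output.
#'
#' @param model a [planted_model()].
#' @return List with elements `ppi` (a [ppi_network]), `ontology` (an
#'   [ontology_dag]), `annotations` (named list protein -> terms) and
#'   `truth` (list with `module_map`, `chain_edges`, `forbidden_edges`;
#'   edge pairs are term-id pairs of consecutive / mediated module pairs).
#' @export
generate_planted <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  .with_seed(model$seed, .generate_planted_impl(model))
}

.generate_planted_impl <- function(model) {
  sizes <- model$module_sizes
  nmod <- length(sizes)
  ov <- if (nmod > 1L) model$mediator_overlap else 0L

  # protein ids per module; consecutive modules share their boundary block
  n_total <- sum(sizes) - (nmod - 1L) * ov
  prot <- sprintf("P%03d", seq_len(n_total))
  modules <- vector("list", nmod)
  start <- 1L
  for (m in seq_len(nmod)) {
    modules[[m]] <- prot[seq(start, start + sizes[m] - 1L)]
    start <- start + sizes[m] - ov
  }
  leaf <- sprintf("M%d", seq_len(nmod))

  # ontology: one chain of intermediate terms per module below a shared root
  depth <- model$ontology_depth
  ids <- "ROOT"; child <- character(0); parent <- character(0)
  for (m in seq_len(nmod)) {
    chain <- if (depth > 1L) sprintf("M%d_anc%d", m, seq_len(depth - 1L)) else character(0)
    terms_m <- c(chain, leaf[m])
    prev <- "ROOT"
    for (t in terms_m) {
      ids <- c(ids, t); child <- c(child, t); parent <- c(parent, prev)
      prev <- t
    }
  }
  dag <- ontology_dag(ids, data.frame(child = child, parent = parent,
                                      stringsAsFactors = FALSE))

  # wiring
  edges_a <- character(0); edges_b <- character(0); forced_binary <- logical(0)
  seen <- new.env(parent = emptyenv())
  add_edge <- function(u, v, forced = FALSE) {
    key <- paste(min(u, v), max(u, v), sep = "\r")
    if (!is.null(seen[[key]])) {
      if (forced) forced_binary[seen[[key]]] <<- TRUE
      return(invisible(NULL))
    }
    edges_a <<- c(edges_a, u); edges_b <<- c(edges_b, v)
    forced_binary <<- c(forced_binary, forced)
    seen[[key]] <- length(edges_a)
  }
  same_module <- function(u, v)
    any(vapply(modules, function(mm) u %in% mm && v %in% mm, TRUE))
  for (i in seq_len(n_total - 1L)) for (j in seq(i + 1L, n_total)) {
    u <- prot[i]; v <- prot[j]
    p <- if (same_module(u, v)) model$p_in else model$p_out
    if (p > 0 && stats::runif(1) < p) add_edge(u, v)
  }
  # guaranteed binary crossing interactions between consecutive modules,
  # drawn from module-exclusive proteins: an edge touching a mediator would
  # double as evidence for a non-adjacent module pair
  if (nmod > 1L) {
    excl <- lapply(seq_len(nmod), function(m)
      setdiff(modules[[m]], unlist(modules[-m])))
    for (m in seq_len(nmod - 1L)) {
      em <- excl[[m]]; en <- excl[[m + 1L]]
      if (!length(em) || !length(en)) next
      combos <- cbind(rep(seq_along(em), each = length(en)),
                      rep(seq_along(en), times = length(em)))
      for (t in seq_len(min(2L, nrow(combos))))
        add_edge(em[[combos[t, 1L]]], en[[combos[t, 2L]]], forced = TRUE)
    }
  }
  assay <- ifelse(forced_binary | stats::runif(length(edges_a)) < model$binary_fraction,
                  "Two-hybrid", "Affinity Capture-MS")
  ppi <- if (length(edges_a))
    ppi_network(data.frame(a = edges_a, b = edges_b, assay = assay,
                           stringsAsFactors = FALSE))
  else ppi_network(data.frame(a = character(0), b = character(0)))

  # annotations: module term for every member; mediators carry both terms
  ann <- stats::setNames(rep(list(character(0)), n_total), prot)
  for (m in seq_len(nmod)) for (p in modules[[m]])
    ann[[p]] <- union(ann[[p]], leaf[m])
  if (model$extra_annotation_rate > 0) {
    for (p in prot) {
      if (stats::runif(1) >= model$extra_annotation_rate) next
      true_term <- ann[[p]][1L]
      if (stats::runif(1) < 0.5) {
        anc <- term_ancestors(dag, true_term)
        if (length(anc)) ann[[p]] <- union(ann[[p]], sample(anc, 1L))
      } else if (nmod > 1L) {
        others <- setdiff(leaf, ann[[p]])
        if (length(others)) ann[[p]] <- union(ann[[p]], sample(others, 1L))
      }
    }
  }

  pairs <- function(idx) if (length(idx)) data.frame(
    from = leaf[idx[, 1L]], to = leaf[idx[, 2L]], stringsAsFactors = FALSE)
    else data.frame(from = character(0), to = character(0))
  chain_idx <- if (nmod > 1L) cbind(seq_len(nmod - 1L), seq(2L, nmod)) else NULL
  forb_idx <- if (nmod > 2L) {
    all_pairs <- t(utils::combn(nmod, 2L))
    all_pairs[all_pairs[, 2L] - all_pairs[, 1L] > 1L, , drop = FALSE]
  } else NULL
  truth <- list(
    module_map = stats::setNames(modules, leaf),
    chain_edges = if (is.null(chain_idx)) pairs(NULL) else pairs(chain_idx),
    forbidden_edges = if (is.null(forb_idx)) pairs(NULL) else pairs(forb_idx))

  list(ppi = ppi, ontology = dag, annotations = ann, truth = truth)
}

#' Score how well a process graph recovers planted ground truth
#'
#' @param pg a `process_graph` obtained from a generated network.
#' @param truth the `truth` element of [generate_planted()] output.
#' @return List with `module_jaccard` (mean, over planted modules, of the
#'   best Jaccard overlap with any function node), `edge_precision` and
#'   `edge_recall` (predicted module-level edges vs the planted chain;
#'   precision is 1 when nothing is predicted) and `mediation_compliance`
#'   (fraction of forbidden, i.e. mediated, module pairs with no direct
#'   edge). All metrics lie in \[0, 1\].
#' @export
score_recovery <- function(pg, truth) {
  stopifnot(inherits(pg, "process_graph"))
  fn_sets <- lapply(pg$nodes, `[[`, "proteins")
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0L) 0 else length(intersect(x, y)) / u
  }
  best_j <- vapply(truth$module_map, function(mod) {
    if (!length(fn_sets)) return(0)
    max(vapply(fn_sets, function(s) jac(s, mod), 0))
  }, 0)

  # map each function node to its best-overlapping module
  mod_names <- names(truth$module_map)
  fn_module <- vapply(fn_sets, function(s) {
    js <- vapply(truth$module_map, function(mod) jac(s, mod), 0)
    if (max(js) == 0) NA_character_ else mod_names[which.max(js)]
  }, "")
  names(fn_module) <- vapply(pg$nodes, `[[`, "", "id")

  pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  predicted <- character(0)
  if (nrow(pg$edges)) {
    mf <- fn_module[pg$edges$from]; mt <- fn_module[pg$edges$to]
    ok <- !is.na(mf) & !is.na(mt) & mf != mt
    predicted <- unique(pair_key(mf[ok], mt[ok]))
  }
  chain <- if (nrow(truth$chain_edges))
    unique(pair_key(truth$chain_edges$from, truth$chain_edges$to)) else character(0)
  forbidden <- if (nrow(truth$forbidden_edges))
    unique(pair_key(truth$forbidden_edges$from, truth$forbidden_edges$to)) else character(0)

  list(
    module_jaccard = if (length(best_j)) mean(best_j) else 0,
    edge_precision = if (!length(predicted)) 1
                     else length(intersect(predicted, chain)) / length(predicted),
    edge_recall = if (!length(chain)) 1
                  else length(intersect(predicted, chain)) / length(chain),
    mediation_compliance = if (!length(forbidden)) 1
                           else mean(!forbidden %in% predicted))
}

#' Toy network with a doubly annotated protein
#'
#' Deterministic six-edge fixture illustrating PMS-based pruning: a
#' "blue" 3-clique whose third protein also carries the "green"
#' annotation, a green pair reachable through that protein, and a "red"
#' pair linked to the rest only via the doubly annotated protein. The
#' default pipeline retains the shared protein in the blue node only (the
#' blue node overlaps its 3-clique perfectly) and therefore builds no
#' green-red edge; the baseline single-evidence mode does link green and
#' red.
#'
#' @return List with `ppi`, `ontology` and `annotations`, ready for
#'   [run_pipeline()].
#' @export
dual_annotation_fixture <- function() {
  edges <- data.frame(
    a     = c("b1", "b1", "b2", "x",  "g1", "r1", "x",  "x"),
    b     = c("b2", "x",  "x",  "g1", "g2", "r2", "r1", "r2"),
    assay = "Two-hybrid", stringsAsFactors = FALSE)
  ppi <- ppi_network(edges)
  dag <- ontology_dag(c("root", "blue", "green", "red"),
                      data.frame(child = c("blue", "green", "red"),
                                 parent = "root", stringsAsFactors = FALSE))
  ann <- list(b1 = "blue", b2 = "blue", x = c("blue", "green"),
              g1 = "green", g2 = "green", r1 = "red", r2 = "red")
  list(ppi = ppi, ontology = dag, annotations = ann)
}
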