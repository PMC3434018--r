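mk_fn <- function(id, proteins, terms = id)
  list(id = id, terms = terms, proteins = sort(proteins),
       nts = NA_real_, history = "seeded")

flat_dag <- function(leaves)
  ontology_dag(c("root", leaves),
               data.frame(child = leaves, parent = "root"))

test_that("function nodes are seeded from shared terms of interacting pairs", {
  g <- ppi_network(data.frame(a = "p1", b = "p2", assay = "PCA"))
  dag <- flat_dag("t")
  fns <- seed_function_nodes(g, list(p1 = "t", p2 = "t"), dag,
                             include_parents = FALSE)
  expect_length(fns, 1L)
  expect_identical(fns[[1L]]$proteins, c("p1", "p2"))
  # with parent seeding on, the shared parent term also gains a node
  fns_pa <- seed_function_nodes(g, list(p1 = "t", p2 = "t"), dag)
  expect_setequal(vapply(fns_pa, function(x) x$terms[[1L]], ""), c("t", "root"))

  # sharing a term without interacting seeds nothing
  g2 <- ppi_network(data.frame(a = c("p1", "p3"), b = c("p3", "p2")))
  fns2 <- seed_function_nodes(g2, list(p1 = "t", p2 = "t"), dag)
  expect_length(fns2, 0L)
})

test_that("shared parents of sibling annotations seed a node for the parent term", {
  g <- ppi_network(data.frame(a = "p1", b = "p2"))
  dag <- ontology_dag(c("q", "t1", "t2"),
                      data.frame(child = c("t1", "t2"), parent = c("q", "q")))
  fns <- seed_function_nodes(g, list(p1 = "t1", p2 = "t2"), dag)
  expect_length(fns, 1L)
  expect_identical(fns[[1L]]$terms, "q")
  expect_identical(fns[[1L]]$proteins, c("p1", "p2"))
  expect_length(seed_function_nodes(g, list(p1 = "t1", p2 = "t2"), dag,
                                    include_parents = FALSE), 0L)
})

test_that("annotations of proteins missing from the network are ignored with a warning", {
  g <- ppi_network(data.frame(a = "p1", b = "p2"))
  expect_warning(
    fns <- seed_function_nodes(g, list(p1 = "t", p2 = "t", ghost = "t"),
                               flat_dag("t"), include_parents = FALSE),
    "absent from the network")
  expect_length(fns, 1L)
})

test_that("node ids take the numeric tail of GO-style term ids", {
  g <- ppi_network(data.frame(a = "p1", b = "p2"))
  fns <- seed_function_nodes(g, list(p1 = "GO:0045046", p2 = "GO:0045046"),
                             flat_dag("GO:0045046"))
  expect_identical(fns[[1L]]$id, "45046")
})

test_that("PMS pruning keeps a protein where it scores best, or above threshold", {
  # doubly annotated protein in a triangle: retained only in the clique-backed node
  fx <- dual_annotation_fixture()
  cs <- build_cluster_set(fx$ppi)
  universe <- fx$ppi$proteins$id
  fns <- list(mk_fn("blue", c("b1", "b2", "x")),
              mk_fn("green", c("x", "g1", "g2")))
  out <- refine_by_pms(fns, cs, universe)
  prot <- lapply(out, `[[`, "proteins")
  expect_identical(prot[[which(vapply(out, `[[`, "", "id") == "blue")]],
                   c("b1", "b2", "x"))
  expect_identical(prot[[which(vapply(out, `[[`, "", "id") == "green")]],
                   c("g1", "g2"))

  # a protein in exactly one node is always retained
  single <- refine_by_pms(list(mk_fn("green", c("x", "g1", "g2"))), cs, universe)
  expect_true("x" %in% single[[1L]]$proteins)

  # scores above the threshold override the maximum rule: two perfect cliques
  g2 <- ppi_network(data.frame(a = c("p","p","q", "p","p","s"),
                               b = c("q","r","r", "s","t","t")))
  cs2 <- build_cluster_set(g2)
  fns2 <- list(mk_fn("f1", c("p", "q", "r")), mk_fn("f2", c("p", "s", "t")))
  out2 <- refine_by_pms(fns2, cs2, g2$proteins$id)
  expect_true(all(vapply(out2, function(f) "p" %in% f$proteins, TRUE)))
})

test_that("with no clusters every PMS is 0 and nothing is pruned", {
  fns <- list(mk_fn("f1", c("p1", "p2")), mk_fn("f2", c("p1", "p3")))
  out <- refine_by_pms(fns, cluster_set(list()), paste0("p", 1:3))
  expect_identical(lapply(out, `[[`, "proteins"),
                   lapply(fns, `[[`, "proteins"))
})

test_that("retained proteins achieve their maximal PMS or exceed the threshold", {
  set.seed(31)
  for (rep in 1:5) {
    inp <- random_pipeline_inputs()
    cs <- build_cluster_set(inp$ppi)
    universe <- inp$ppi$proteins$id
    ann <- lapply(inp$ann, function(t) most_specific_terms(inp$dag, t))
    fns <- seed_function_nodes(inp$ppi, ann, inp$dag)
    out <- refine_by_pms(fns, cs, universe)
    if (!length(out)) next
    pmax_p <- list()
    for (fn in out) for (p in names(fn$pms))
      pmax_p[[p]] <- max(pmax_p[[p]] %||% 0, fn$pms[[p]])
    for (fn in out) for (p in names(fn$pms))
      expect_true(fn$pms[[p]] >= pmax_p[[p]] || fn$pms[[p]] >= 95)
  }
})

test_that("identical nodes merge keeping all deepest labels, ids joined with +", {
  dag <- ontology_dag(
    c("r", "l1", "l2", "GO:0006094", "GO:0006096", "GO:0006006"),
    data.frame(child  = c("l1", "l2", "GO:0006006", "GO:0006094", "GO:0006096"),
               parent = c("r", "l1", "l2", "GO:0006006", "GO:0006006")))
  fns <- list(mk_fn("6094", c("p1", "p2"), "GO:0006094"),
              mk_fn("6096", c("p1", "p2"), "GO:0006096"),
              mk_fn("6006", c("p1", "p2"), "GO:0006006"))
  out <- merge_identical(fns, dag)
  expect_length(out, 1L)
  expect_setequal(out[[1L]]$terms, c("GO:0006094", "GO:0006096"))
  expect_identical(out[[1L]]$id, "6094+6096")

  # unequal depths keep only the deepest label
  fns2 <- list(mk_fn("l1", c("p1", "p2"), "l1"), mk_fn("l2", c("p1", "p2"), "l2"))
  out2 <- merge_identical(fns2, dag)
  expect_identical(out2[[1L]]$terms, "l2")

  # disjoint protein sets stay untouched
  fns3 <- list(mk_fn("a", c("p1", "p2")), mk_fn("b", c("p3", "p4")))
  expect_length(merge_identical(fns3, dag2 <- flat_dag(c("a", "b"))), 2L)
})

test_that("enucleation subtracts nested nodes to a fixpoint in a fixed order", {
  out <- enucleate(list(mk_fn("A", paste0("p", 1:5)), mk_fn("B", c("p1", "p2"))))
  expect_identical(lapply(out, `[[`, "proteins"),
                   list(mk_fn("A", paste0("p", 3:5))$proteins, c("p1", "p2")))

  # disjoint nodes unchanged
  out2 <- enucleate(list(mk_fn("A", c("p1", "p2")), mk_fn("B", c("p3", "p4"))))
  expect_length(out2, 2L)

  # nested chain: middle node shrinks below two proteins and is discarded
  out3 <- enucleate(list(mk_fn("A", paste0("p", 1:6)),
                         mk_fn("B", paste0("p", 1:3)),
                         mk_fn("C", c("p1", "p2"))))
  expect_identical(vapply(out3, `[[`, "", "id"), c("A", "C"))
  expect_identical(out3[[1L]]$proteins, paste0("p", 4:6))
  expect_identical(out3[[2L]]$proteins, c("p1", "p2"))

  # invariant: no proper-subset pair survives
  set.seed(17)
  for (rep in 1:10) {
    fns <- lapply(1:6, function(i)
      mk_fn(paste0("n", i), sample(paste0("p", 1:8), sample(2:6, 1L))))
    fns <- fns[!duplicated(vapply(fns, function(x) paste(x$proteins, collapse = ","), ""))]
    out <- enucleate(fns)
    sets <- lapply(out, `[[`, "proteins")
    for (i in seq_along(sets)) for (j in seq_along(sets))
      if (i != j)
        expect_false(length(sets[[i]]) < length(sets[[j]]) &&
                       all(sets[[i]] %in% sets[[j]]))
  }
})

test_that("edges require two shared proteins or two qualifying crossing PPI", {
  # one shared protein and one crossing PPI: insufficient
  g <- ppi_network(data.frame(a = c("p1","p3","p2"), b = c("p2","p4","p3"),
                              assay = "Two-hybrid"))
  fns <- list(mk_fn("F1", c("p1", "p2")), mk_fn("F2", c("p2", "p3", "p4")))
  expect_identical(nrow(build_edges(fns, g)), 0L)

  # two shared proteins, no crossing PPI: edge
  g2 <- ppi_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
  fns2 <- list(mk_fn("F1", c("p1", "p2", "p3")), mk_fn("F2", c("p2", "p3")))
  ed2 <- build_edges(fns2, g2)
  expect_identical(nrow(ed2), 1L)
  expect_identical(ed2$shared_proteins, 2L)

  # two cluster-assay crossing PPI: rejected under binary_only, accepted under any_assay
  g3 <- ppi_network(data.frame(a = c("p1","p3","p1","p2"), b = c("p2","p4","p3","p4"),
                               assay = c("PCA","PCA","Affinity Capture-MS",
                                         "Affinity Capture-MS")))
  fns3 <- list(mk_fn("F1", c("p1", "p2")), mk_fn("F2", c("p3", "p4")))
  expect_identical(nrow(build_edges(fns3, g3, "binary_only")), 0L)
  ed3 <- build_edges(fns3, g3, "any_assay")
  expect_identical(nrow(ed3), 1L)
  expect_identical(ed3$crossing_total, 2L)
  expect_identical(ed3$crossing_binary, 0L)
})

test_that("interactions internal to a third node are not crossing evidence", {
  # m1 and m2 belong to nodes A and C respectively but interact inside node B:
  # their interactions must not create an A-C edge
  g <- ppi_network(data.frame(a = c("a1", "m1", "b0", "b0", "m2", "m1"),
                              b = c("m1", "m2", "m1", "m2", "c1", "b0"),
                              assay = "Two-hybrid"))
  fns <- list(mk_fn("A", c("a1", "m1")), mk_fn("B", c("m1", "b0", "m2")),
              mk_fn("C", c("m2", "c1")))
  ed <- build_edges(fns, g)
  expect_false(any(ed$from == "A" & ed$to == "C"))
})

test_that("baseline edges are a superset of pipeline edges", {
  set.seed(23)
  for (rep in 1:5) {
    g <- random_ppi(9, 0.4)
    fns <- lapply(1:4, function(i)
      mk_fn(paste0("n", i), sample(g$proteins$id, sample(2:5, 1L))))
    strict <- build_edges(fns, g)
    loose <- baseline_edges(fns, g)
    strict_keys <- paste(strict$from, strict$to)
    expect_true(all(strict_keys %in% paste(loose$from, loose$to)))
  }
})

test_that("NTS reduction removes low-scoring nodes and is monotone", {
  fns <- list(mk_fn("a", c("p1", "p2")), mk_fn("b", c("p3", "p4")))
  fns[[1L]]$nts <- 80; fns[[2L]]$nts <- 20
  pg <- process_graph(fns)
  expect_length(reduce_by_nts(pg, 0)$nodes, 2L)
  expect_length(reduce_by_nts(pg, 50)$nodes, 1L)
  expect_length(reduce_by_nts(pg, 101)$nodes, 0L)

  sw <- nts_sweep(pg, seq(0, 100, 10))
  expect_true(all(diff(sw$n_nodes) <= 0))
  expect_true(all(diff(sw$n_edges) <= 0))
})

test_that("core-fraction selection keeps nodes satisfying at least one rule", {
  fns <- list(mk_fn("hi_core", c("c1", "c2", "c3", "n1")),   # 3/4 core
              mk_fn("half", c("c1", "n1")),                  # 1/2 core
              mk_fn("lo_core", c("c1", "n1", "n2", "n3", "n4")))  # 1/5 core
  fns[[1L]]$nts <- 35; fns[[2L]]$nts <- 35; fns[[3L]]$nts <- 65
  pg <- process_graph(fns, core = c("c1", "c2", "c3"))
  rules <- list(c(30, 2/3, 1), c(60, 0, 1/3))
  kept <- vapply(select_by_core_fraction(pg, rules)$nodes, `[[`, "", "id")
  expect_setequal(kept, c("hi_core", "lo_core"))
  expect_length(select_by_core_fraction(pg, list())$nodes, 3L)
})

test_that("open triples yield four orientations and a manipulate-middle design", {
  fns <- lapply(c("A", "B", "C", "D"), function(i) mk_fn(i, c("p1", "p2")))
  mk_pg <- function(nodes, pairs) {
    ed <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(from = min(p), to = max(p), shared_proteins = 2L,
                 crossing_binary = 0L, crossing_total = 0L,
                 dir_from = NA_character_, dir_to = NA_character_,
                 rule_tag = NA_integer_, note = NA_character_)
    }))
    process_graph(nodes, ed)
  }
  path <- mk_pg(fns[1:3], list(c("A", "B"), c("B", "C")))
  tr <- enumerate_triples(path)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$b, "B")
  expect_identical(tr$manipulate, "B")
  expect_length(strsplit(tr$hypotheses, " | ", fixed = TRUE)[[1L]], 4L)

  tri <- mk_pg(fns[1:3], list(c("A","B"), c("B","C"), c("A","C")))
  expect_identical(nrow(enumerate_triples(tri)), 0L)

  star <- mk_pg(fns, list(c("B","A"), c("B","C"), c("B","D")))
  expect_identical(nrow(enumerate_triples(star)), 3L)
})

test_that("edge directions are user-supplied annotations with a rule tag", {
  fns <- list(mk_fn("A", c("p1", "p2")), mk_fn("B", c("p1", "p2", "p3")))
  ed <- data.frame(from = "A", to = "B", shared_proteins = 2L,
                   crossing_binary = 0L, crossing_total = 0L,
                   dir_from = NA_character_, dir_to = NA_character_,
                   rule_tag = NA_integer_, note = NA_character_)
  pg <- process_graph(fns, ed)
  pg2 <- set_edge_direction(pg, "B", "A", rule = 4, note = "B precedes A")
  expect_identical(pg2$edges$dir_from, "B")
  expect_identical(pg2$edges$dir_to, "A")
  expect_identical(pg2$edges$rule_tag, 4L)
  expect_error(set_edge_direction(pg, "A", "Z", 1), "no edge")
})

test_that("the full pipeline is deterministic and handles empty input", {
  empty <- ppi_network(data.frame(a = character(0), b = character(0)))
  pg0 <- run_pipeline(empty, flat_dag("t"), list())
  expect_length(pg0$nodes, 0L)
  expect_identical(nrow(pg0$edges), 0L)

  set.seed(77)
  inp <- random_pipeline_inputs()
  run_once <- function() {
    pg <- suppressWarnings(run_pipeline(inp$ppi, inp$dag, inp$ann))
    f <- tempfile(fileext = ".graphml")
    write_pg(pg, f)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run_once(), run_once())
})

test_that("stored edge evidence satisfies the active criterion and is reproducible", {
  set.seed(41)
  inp <- random_pipeline_inputs(n_prot = 12)
  pg <- suppressWarnings(run_pipeline(inp$ppi, inp$dag, inp$ann))
  fns <- pg$nodes
  ed <- build_edges(fns, inp$ppi)   # recompute from the network
  cols <- c("from", "to", "shared_proteins", "crossing_binary", "crossing_total")
  got <- pg$edges[, cols]; want <- ed[, cols]
  row.names(got) <- NULL; row.names(want) <- NULL
  expect_identical(got, want)
  for (i in seq_len(nrow(ed)))
    expect_true(ed$shared_proteins[i] > 1L || ed$crossing_binary[i] > 1L)
})
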