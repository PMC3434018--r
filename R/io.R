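#' Format a score for reporting
#'
#' One-decimal, half-up rounding with a dot separator (so 10.85 prints as
#' "10.9" and a mean degree of 10.813 prints as "10.8").
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return Character vector.
#' @export
format_score <- function(x, digits = 1) {
  f <- 10^digits
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), floor(x * f + 0.5) / f))
}

.norm_colname <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a PPI edge table
#'
#' Reads a tab-separated interaction file in either a generic dialect
#' (columns naming the two interactors plus an optional assay column) or
#' the BioGRID tab3 dialect (Official Symbol / Systematic Name interactor
#' columns, Experimental System, Experimental System Type; rows are
#' restricted to physical interactions when the type column is present).
#'
#' @param path file path.
#' @param core optional character vector of core protein ids, or the path
#'   of a one-id-per-line file.
#' @param assay_table assay classification, see [default_assay_classes()].
#' @param unknown_assay policy for unknown assay names (`"warn_cluster"`,
#'   `"warn_binary"` or `"error"`).
#' @return A [ppi_network].
#' @export
read_ppi <- function(path, core = NULL, assay_table = default_assay_classes(),
                     unknown_assay = "warn_cluster") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  norm <- .norm_colname(names(df))
  pick <- function(keys) {
    for (k in keys) {
      hit <- which(norm == k)
      if (length(hit)) return(hit[1L])
    }
    NA_integer_
  }
  ia <- pick(c("a", "proteina", "interactora", "officialsymbolinteractora",
               "systematicnameinteractora", "idinteractora"))
  ib <- pick(c("b", "proteinb", "interactorb", "officialsymbolinteractorb",
               "systematicnameinteractorb", "idinteractorb"))
  if (is.na(ia)) stop("cannot identify the 'interactor A' column")
  if (is.na(ib)) stop("cannot identify the 'interactor B' column")
  iassay <- pick(c("assay", "experimentalsystem"))
  itype <- pick("experimentalsystemtype")
  if (!is.na(itype)) {
    keep <- tolower(df[[itype]]) == "physical"
    df <- df[keep, , drop = FALSE]
  }
  edges <- data.frame(a = as.character(df[[ia]]), b = as.character(df[[ib]]),
                      stringsAsFactors = FALSE)
  if (!is.na(iassay)) edges$assay <- as.character(df[[iassay]])
  if (is.character(core) && length(core) == 1L && file.exists(core))
    core <- readLines(core, warn = FALSE)
  ppi_network(edges, core = core, assay_table = assay_table,
              unknown_assay = unknown_assay)
}

#' Read protein-to-term annotations
#'
#' Accepts either GAF 2.x (17-column gene association format; comment lines
#' start with `!`) or a 2-column tab-separated file (protein, term; an
#' optional header line naming the first column `protein` is skipped). GAF
#' rows can be filtered by aspect (`"P"`, `"F"`, `"C"`). Terms absent from
#' the ontology are dropped with a warning; malformed lines are skipped
#' with a warning and more than 10% malformed lines is an error.
#'
#' @param path file path.
#' @param dag an [ontology_dag] restricting the admissible terms.
#' @param aspect optional GAF aspect filter (ignored for 2-column input).
#' @param id_col for GAF input, `"id"` (column 2, default) or `"symbol"`
#'   (column 3).
#' @return Named list, protein id -> character vector of term ids.
#' @export
read_annotations <- function(path, dag, aspect = NULL, id_col = c("id", "symbol")) {
  stopifnot(inherits(dag, "ontology_dag"))
  id_col <- match.arg(id_col)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_gaf <- any(grepl("^!gaf-version", lines)) ||
    (length(lines) && length(strsplit(lines[!grepl("^!", lines)][1L], "\t")[[1L]]) >= 15L)
  lines <- lines[!grepl("^!", lines)]
  prot <- character(0); term <- character(0); bad <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (is_gaf) {
      if (length(f) < 9L || !nzchar(f[5L])) {
        warning("skipping malformed annotation line ", i); bad <- bad + 1L; next
      }
      if (!is.null(aspect) && f[9L] != aspect) next
      prot <- c(prot, if (id_col == "id") f[2L] else f[3L])
      term <- c(term, f[5L])
    } else {
      if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
        warning("skipping malformed annotation line ", i); bad <- bad + 1L; next
      }
      if (i == 1L && .norm_colname(f[1L]) == "protein") next
      prot <- c(prot, f[1L]); term <- c(term, f[2L])
    }
  }
  if (length(lines) && bad / length(lines) > 0.1)
    stop("more than 10% malformed annotation lines (", bad, "/", length(lines), ")")
  known <- term %in% dag$ids
  if (any(!known)) {
    warning("dropping annotation term(s) absent from ontology: ",
            paste(unique(term[!known]), collapse = ", "))
    prot <- prot[known]; term <- term[known]
  }
  lapply(split(term, factor(prot, levels = sort(unique(prot)))), unique)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a process graph to file
#'
#' Serialises a `process_graph` in one of four formats. Output is
#' canonical: nodes are ordered by id and edges by sorted endpoint pair, so
#' identical graphs always produce byte-identical files, and a GraphML
#' write -> [read_pg()] -> write round trip reproduces the file exactly.
#'
#' @param pg a `process_graph`.
#' @param path output file path.
#' @param format `"graphml"`, `"sif"`, `"dot"` or `"tsv"` (node table).
#' @return `path`, invisibly.
#' @export
write_pg <- function(pg, path, format = c("graphml", "sif", "dot", "tsv")) {
  stopifnot(inherits(pg, "process_graph"))
  format <- match.arg(format)
  nt <- pg_nodes(pg)
  ed <- pg$edges
  con <- file(path, open = "wb")   # binary mode: LF line endings everywhere
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con, sep = "\n", useBytes = TRUE)

  if (format == "tsv") {
    hdr <- paste(names(nt), collapse = "\t")
    cols <- lapply(nt, function(col) {
      if (is.double(col)) ifelse(is.na(col), "NA", sprintf("%.4f", col))
      else as.character(col)
    })
    wl(hdr)
    if (nrow(nt)) wl(do.call(paste, c(cols, sep = "\t")))
  } else if (format == "sif") {
    linked <- unique(c(ed$from, ed$to))
    for (i in seq_len(nrow(ed))) wl(paste(ed$from[i], "pp", ed$to[i]))
    for (id in setdiff(nt$id, linked)) wl(id)
  } else if (format == "dot") {
    wl("graph PG {")
    for (id in nt$id) wl(sprintf("  \"%s\";", id))
    for (i in seq_len(nrow(ed)))
      wl(sprintf("  \"%s\" -- \"%s\" [shared=%d, crossing_binary=%d, crossing_total=%d];",
                 ed$from[i], ed$to[i], ed$shared_proteins[i],
                 ed$crossing_binary[i], ed$crossing_total[i]))
    wl("}")
  } else {
    num <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
    wl("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
       "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
       "  <key id=\"d0\" for=\"node\" attr.name=\"terms\" attr.type=\"string\"/>",
       "  <key id=\"d1\" for=\"node\" attr.name=\"proteins\" attr.type=\"string\"/>",
       "  <key id=\"d2\" for=\"node\" attr.name=\"nts\" attr.type=\"string\"/>",
       "  <key id=\"d3\" for=\"node\" attr.name=\"core_fraction\" attr.type=\"string\"/>",
       "  <key id=\"e0\" for=\"edge\" attr.name=\"shared_proteins\" attr.type=\"int\"/>",
       "  <key id=\"e1\" for=\"edge\" attr.name=\"crossing_binary\" attr.type=\"int\"/>",
       "  <key id=\"e2\" for=\"edge\" attr.name=\"crossing_total\" attr.type=\"int\"/>",
       "  <key id=\"e3\" for=\"edge\" attr.name=\"direction\" attr.type=\"string\"/>",
       "  <key id=\"e4\" for=\"edge\" attr.name=\"rule_tag\" attr.type=\"string\"/>",
       "  <key id=\"e5\" for=\"edge\" attr.name=\"note\" attr.type=\"string\"/>",
       "  <key id=\"g0\" for=\"graph\" attr.name=\"core_proteins\" attr.type=\"string\"/>",
       "  <graph id=\"PG\" edgedefault=\"undirected\">",
       sprintf("    <data key=\"g0\">%s</data>",
               .xml_escape(paste(sort(pg$core), collapse = ";"))))
    for (i in seq_len(nrow(nt))) {
      wl(sprintf("    <node id=\"%s\">", .xml_escape(nt$id[i])),
         sprintf("      <data key=\"d0\">%s</data>", .xml_escape(nt$terms[i])),
         sprintf("      <data key=\"d1\">%s</data>", .xml_escape(nt$proteins[i])),
         sprintf("      <data key=\"d2\">%s</data>", num(nt$nts[i])),
         sprintf("      <data key=\"d3\">%s</data>", num(nt$core_fraction[i])),
         "    </node>")
    }
    for (i in seq_len(nrow(ed))) {
      dir <- if (is.na(ed$dir_from[i])) "" else paste0(ed$dir_from[i], "->", ed$dir_to[i])
      wl(sprintf("    <edge source=\"%s\" target=\"%s\">",
                 .xml_escape(ed$from[i]), .xml_escape(ed$to[i])),
         sprintf("      <data key=\"e0\">%d</data>", ed$shared_proteins[i]),
         sprintf("      <data key=\"e1\">%d</data>", ed$crossing_binary[i]),
         sprintf("      <data key=\"e2\">%d</data>", ed$crossing_total[i]),
         sprintf("      <data key=\"e3\">%s</data>", .xml_escape(dir)),
         sprintf("      <data key=\"e4\">%s</data>",
                 ifelse(is.na(ed$rule_tag[i]), "", as.character(ed$rule_tag[i]))),
         sprintf("      <data key=\"e5\">%s</data>",
                 ifelse(is.na(ed$note[i]), "", .xml_escape(ed$note[i]))),
         "    </edge>")
    }
    wl("  </graph>", "</graphml>")
  }
  invisible(path)
}

#' Read a process graph from GraphML
#'
#' Inverse of [write_pg()]'s GraphML writer; restores nodes (terms,
#' proteins, NTS), edges with their evidence counters and direction
#' annotations, and the core protein set.
#'
#' @param path a GraphML file produced by [write_pg()].
#' @return A `process_graph`.
#' @export
read_pg <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) "" else xml2::xml_text(d)
  }
  graph <- xml2::xml_find_first(doc, "./g:graph", ns)
  core_txt <- get_data(graph, "g0")
  core <- if (nzchar(core_txt)) strsplit(core_txt, ";", fixed = TRUE)[[1L]] else character(0)

  num_or_na <- function(x) if (x == "NA" || !nzchar(x)) NA_real_ else as.numeric(x)
  nodes <- lapply(xml2::xml_find_all(graph, "./g:node", ns), function(nd) {
    prot_txt <- get_data(nd, "d1")
    list(id = xml2::xml_attr(nd, "id"),
         terms = strsplit(get_data(nd, "d0"), ";", fixed = TRUE)[[1L]],
         proteins = if (nzchar(prot_txt)) strsplit(prot_txt, ";", fixed = TRUE)[[1L]]
                    else character(0),
         nts = num_or_na(get_data(nd, "d2")),
         history = "imported")
  })
  erows <- lapply(xml2::xml_find_all(graph, "./g:edge", ns), function(eg) {
    dir <- get_data(eg, "e3")
    dd <- if (nzchar(dir)) strsplit(dir, "->", fixed = TRUE)[[1L]] else c(NA, NA)
    rt <- get_data(eg, "e4")
    note <- get_data(eg, "e5")
    data.frame(from = xml2::xml_attr(eg, "source"),
               to = xml2::xml_attr(eg, "target"),
               shared_proteins = as.integer(get_data(eg, "e0")),
               crossing_binary = as.integer(get_data(eg, "e1")),
               crossing_total = as.integer(get_data(eg, "e2")),
               dir_from = dd[1L], dir_to = dd[2L],
               rule_tag = if (nzchar(rt)) as.integer(rt) else NA_integer_,
               note = if (nzchar(note)) note else NA_character_,
               stringsAsFactors = FALSE)
  })
  edges <- if (length(erows)) do.call(rbind, erows) else .empty_edges()
  process_graph(nodes, edges, core = core)
}
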