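#' Ontology DAG container
#'
#' Holds a set of ontology terms with names and namespaces plus the child ->
#' parent `is_a` edges, backed by an igraph directed acyclic graph.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`
#'   (namespace in MF/BP/CC).
#' @param edges data.frame with columns `child`, `parent` (term ids).
#' @param include_part_of marker recorded for provenance (see [read_obo()]).
#' @return an `ontology_dag` object with a cached inclusive-ancestor list.
#' @export
ontology_dag <- function(terms, edges, include_part_of = FALSE) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop("duplicate term id")
  if (nrow(edges) > 0) {
    stopifnot(all(c("child", "parent") %in% names(edges)))
    unknown <- setdiff(c(edges$child, edges$parent), terms$id)
    if (length(unknown) > 0)
      stop("edge references unknown term(s): ",
           paste(unknown, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0) edges[, c("child", "parent")] else
      data.frame(child = character(), parent = character()),
    directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE))
  if (!igraph::is_dag(g))
    stop("cyclic is_a structure: ontology is not a DAG")
  # inclusive ancestor sets (term + everything reachable child -> parent)
  anc <- igraph::ego(g, order = igraph::vcount(g), nodes = igraph::V(g),
                     mode = "out")
  anc <- lapply(anc, function(v) igraph::as_ids(v))
  names(anc) <- terms$id
  structure(list(terms = terms, edges = edges, graph = g, ancestors = anc,
                 include_part_of = include_part_of),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d is_a edges (%s)\n",
              nrow(x$terms), nrow(x$edges),
              paste(sort(unique(x$terms$namespace)), collapse = "/")))
  invisible(x)
}

term_namespace <- function(dag, ids) {
  dag$terms$namespace[match(ids, dag$terms$id)]
}

#' Read an OBO 1.2-style ontology file
#'
#' Interprets only `[Term]` stanzas and the `id`, `name`, `namespace`,
#' `is_a`, `relationship: part_of` and `is_obsolete` tags.  Obsolete terms
#' are dropped together with any edges touching them.  The result must be a
#' DAG.
#'
#' @param path OBO file path.
#' @param include_part_of also treat `relationship: part_of` as an ancestry
#'   edge (off by default; only `is_a` ancestry is standard here).
#' @return an [ontology_dag()] object.
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ns_map <- c(molecular_function = "MF", biological_process = "BP",
              cellular_component = "CC", MF = "MF", BP = "BP", CC = "CC")

  stanzas <- list(); cur <- NULL; in_term <- FALSE
  flush <- function() if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)        # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(is_a = character(),
                                               obsolete = FALSE)
                          in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[2L]; val <- trimws(kv[3L])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, strsplit(val, "\\s")[[1L]][1L])
    else if (key == "relationship" && include_part_of &&
             grepl("^part_of\\s", val))
      cur$is_a <- c(cur$is_a, strsplit(val, "\\s+")[[1L]][2L])
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
  }
  flush()
  if (length(stanzas) == 0) stop("no [Term] stanzas found in ", path)
  for (s in stanzas) if (is.null(s$id)) stop("[Term] stanza missing id")

  keep <- !vapply(stanzas, `[[`, logical(1), "obsolete")
  stanzas <- stanzas[keep]
  if (length(stanzas) == 0) stop("all terms are obsolete")
  ids <- vapply(stanzas, `[[`, character(1), "id")
  terms <- data.frame(
    id = ids,
    name = vapply(stanzas, function(s) s$name %||% s$id, character(1)),
    namespace = unname(vapply(stanzas, function(s) {
      ns <- ns_map[s$namespace %||% "biological_process"]
      if (is.na(ns)) "BP" else ns
    }, character(1))),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(stanzas, function(s)
    if (length(s$is_a) > 0)
      data.frame(child = s$id, parent = s$is_a, stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character())
  edges <- edges[edges$parent %in% ids, , drop = FALSE]  # drop edges to dropped terms
  edges <- unique(edges)
  ontology_dag(terms, edges, include_part_of = include_part_of)
}

#' Write an ontology as OBO text
#'
#' Inverse of [read_obo()] for the interpreted fields; used by the synthetic
#' generator and round-trip tests.
#'
#' @param dag an [ontology_dag()].
#' @param path output file.
#' @export
write_obo <- function(dag, path) {
  ns_long <- c(MF = "molecular_function", BP = "biological_process",
               CC = "cellular_component")
  con <- file(path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", dag$terms$id[i]), con)
    writeLines(paste0("name: ", dag$terms$name[i]), con)
    writeLines(paste0("namespace: ", ns_long[dag$terms$namespace[i]]), con)
    par <- dag$edges$parent[dag$edges$child == dag$terms$id[i]]
    for (p in par) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read gene-to-term annotations
#'
#' Accepts either a two-column delimited table (gene id, term id) or
#' GAF-style rows (column 3 = object symbol, column 5 = term id; `!` comment
#' lines skipped).  Annotations citing terms absent from the DAG are skipped
#' with a warning reporting the count.  Duplicate rows collapse (set
#' semantics), so parsing is independent of row order.
#'
#' @param path annotation file.
#' @param dag an [ontology_dag()] used to validate term ids.
#' @param format `"tsv"` (two columns) or `"gaf"`.
#' @param sep field separator for `"tsv"`.
#' @return a named list mapping gene id -> character vector of term ids,
#'   with attribute `n_skipped` (annotations to unknown terms).
#' @export
read_annotations <- function(path, dag, format = c("tsv", "gaf"),
                             sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^!", lines) & nzchar(lines)]
    if (length(lines) == 0) stop("empty annotation map")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) < 5L))
      stop("GAF rows need at least 5 columns")
    tab <- data.frame(gene = vapply(parts, `[[`, character(1), 3L),
                      term = vapply(parts, `[[`, character(1), 5L),
                      stringsAsFactors = FALSE)
  } else {
    tab <- tryCatch(
      read.delim(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#"),
      error = function(e) stop("unreadable annotation file: ",
                               conditionMessage(e)))
    if (ncol(tab) < 2L) stop("annotation table needs 2 columns")
    tab <- data.frame(gene = as.character(tab[[1L]]),
                      term = as.character(tab[[2L]]),
                      stringsAsFactors = FALSE)
  }
  tab$gene <- trimws(tab$gene); tab$term <- trimws(tab$term)
  known <- tab$term %in% dag$terms$id
  n_skipped <- sum(!known)
  if (n_skipped > 0)
    warning(n_skipped, " annotation(s) to unknown terms skipped")
  tab <- unique(tab[known, , drop = FALSE])
  if (nrow(tab) == 0) stop("empty annotation map")
  ann <- split(tab$term, tab$gene)
  ann <- lapply(ann, unique)
  attr(ann, "n_skipped") <- n_skipped
  ann
}
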