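#' Read and write labeled graphs
#'
#' Two plain-text formats are supported. The canonical TSV dialect has
#' comment lines starting with `#`, vertex lines `V<TAB>id<TAB>label` and
#' edge lines `E<TAB>id1<TAB>id2`; ids must be declared before use and files
#' are UTF-8. GraphML stores the vertex label under the attribute key
#' `"label"`. A write/read round trip preserves vertex ids, labels, the edge
#' multiset (including parallel edges and self-loops) and row order.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @param g A [labeled_graph].
#' @return `read_graph()` returns a [labeled_graph]; `write_graph()` returns
#'   `path` invisibly.
#' @examples
#' g <- compressible_matching(2)
#' f <- tempfile(fileext = ".tsv")
#' write_graph(g, f)
#' identical(read_graph(f)$edges, g$edges)
#' @export
read_graph <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  switch(format, tsv = read_graph_tsv(path), graphml = read_graphml(path))
}

#' @rdname read_graph
#' @export
write_graph <- function(g, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(g, "labeled_graph"))
  format <- match.arg(format)
  switch(format, tsv = write_graph_tsv(g, path), graphml = write_graphml(g, path))
  invisible(path)
}

read_graph_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- character(); labs <- character()
  from <- character(); to <- character()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[[1]] == "V") {
      if (length(f) != 3) stop(sprintf("line %d: vertex line needs 'V<TAB>id<TAB>label'", i))
      if (!is.null(seen[[f[[2]]]])) stop(sprintf("line %d: duplicate vertex id '%s'", i, f[[2]]))
      seen[[f[[2]]]] <- TRUE
      ids <- c(ids, f[[2]]); labs <- c(labs, f[[3]])
    } else if (f[[1]] == "E") {
      if (length(f) != 3) stop(sprintf("line %d: edge line needs 'E<TAB>id1<TAB>id2'", i))
      for (v in f[2:3]) {
        if (is.null(seen[[v]])) {
          stop(sprintf("line %d: edge references undeclared vertex id '%s'", i, v))
        }
      }
      from <- c(from, f[[2]]); to <- c(to, f[[3]])
    } else {
      stop(sprintf("line %d: expected 'V' or 'E' record, got '%s'", i, f[[1]]))
    }
  }
  labeled_graph(
    data.frame(id = ids, label = labs, stringsAsFactors = FALSE),
    data.frame(from = from, to = to, stringsAsFactors = FALSE)
  )
}

write_graph_tsv <- function(g, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# netzip labeled graph (V id label / E id1 id2)", con)
  if (nrow(g$vertices)) {
    writeLines(paste("V", g$vertices$id, g$vertices$label, sep = "\t"), con)
  }
  if (nrow(g$edges)) {
    writeLines(paste("E", g$edges$from, g$edges$to, sep = "\t"), con)
  }
}

read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  # namespace-agnostic lookup so files from other tools parse too
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  ids <- xml2::xml_attr(nodes, "id")
  labs <- vapply(nodes, function(nd) {
    d <- xml2::xml_find_first(nd, ".//*[local-name()='data'][@key='label']")
    if (inherits(d, "xml_missing")) xml2::xml_attr(nd, "id") else xml2::xml_text(d)
  }, character(1))
  edges <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  labeled_graph(
    data.frame(id = ids, label = labs, stringsAsFactors = FALSE),
    data.frame(
      from = xml2::xml_attr(edges, "source"),
      to = xml2::xml_attr(edges, "target"),
      stringsAsFactors = FALSE
    )
  )
}

write_graphml <- function(g, path) {
  doc <- xml2::xml_new_root("graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key",
    id = "label", "for" = "node", "attr.name" = "label", "attr.type" = "string"
  )
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(g$vertices))) {
    nd <- xml2::xml_add_child(gr, "node", id = g$vertices$id[[i]])
    xml2::xml_add_child(nd, "data", g$vertices$label[[i]], key = "label")
  }
  for (i in seq_len(nrow(g$edges))) {
    xml2::xml_add_child(gr, "edge", source = g$edges$from[[i]], target = g$edges$to[[i]])
  }
  xml2::write_xml(doc, path)
}
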