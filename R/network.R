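#' Pairwise conditional-dependence network
#'
#' A `pairwise_network` is a weighted undirected graph over disease codes:
#' each edge carries a signed aggregated conditional-association strength
#' (`weight`) and a `sign_consistent` flag recording whether the two nodewise
#' coefficients behind it agreed in sign. Zero-weight pairs are absent by
#' construction (sparsity contract); self-loops are forbidden.
#'
#' @param nodes Character vector of node (disease) codes.
#' @param edges A data frame with columns `from`, `to`, `weight` and
#'   optionally `sign_consistent` (defaults to `TRUE`).
#' @return An object of class `pairwise_network` with elements `nodes`
#'   (character) and `edges` (tibble with `from`, `to`, `weight`,
#'   `sign_consistent`; `from` precedes `to` in node order).
#' @export
pairwise_network <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric(), sign_consistent = logical())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"sign_consistent" %in% names(edges)) edges$sign_consistent <- TRUE
    edges <- edges[c("from", "to", "weight", "sign_consistent")]
    if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes)) {
      stop("edge endpoints must be catalog nodes", call. = FALSE)
    }
    if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
    if (any(edges$weight == 0)) stop("zero-weight edges must be absent", call. = FALSE)
    # canonical orientation: 'from' before 'to' in node order, sorted
    i <- match(edges$from, nodes)
    j <- match(edges$to, nodes)
    flip <- i > j
    tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
    key <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
    edges <- edges[order(pmin(i, j), pmax(i, j)), ]
  }
  structure(list(nodes = nodes, edges = edges), class = "pairwise_network")
}

#' @export
print.pairwise_network <- function(x, ...) {
  cat(sprintf("<pairwise_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 10))
  invisible(x)
}

#' @export
#' @method tidy pairwise_network
tidy.pairwise_network <- function(x, ...) x$edges

#' Convert a pairwise network to an igraph graph
#'
#' Vertices keep catalog order; edge attributes `weight` (signed),
#' `absweight` and `sign_consistent` are attached.
#'
#' @param net A [pairwise_network()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "pairwise_network"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes)),
      weight = net$edges$weight,
      absweight = abs(net$edges$weight),
      sign_consistent = net$edges$sign_consistent
    )
  }
  g
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialize a pairwise network
#'
#' `write_network()` writes GraphML (with `weight` and `sign_consistent` edge
#' attributes, weights at 17 significant digits so the round-trip is lossless)
#' or a TSV edge list with columns `source`, `target`, `weight`,
#' `sign_consistent`. `read_network()` reads either format back; the
#' write/read round-trip reproduces the network exactly.
#'
#' @param net A [pairwise_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `pairwise_network`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist_tsv")) {
  stopifnot(inherits(net, "pairwise_network"))
  format <- match.arg(format)
  if (format == "edgelist_tsv") {
    lines <- c("source\ttarget\tweight\tsign_consistent",
               sprintf("%s\t%s\t%.17g\t%s",
                       net$edges$from, net$edges$to, net$edges$weight,
                       ifelse(net$edges$sign_consistent, "true", "false")))
    # header records the node set so isolates survive the round trip
    lines <- c(paste0("# nodes: ", paste(net$nodes, collapse = ",")), lines)
    con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
      stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    nodes <- sprintf('    <node id="%s"/>', xml_escape(net$nodes))
    edges <- sprintf(paste0(
      '    <edge source="%s" target="%s">',
      '<data key="w">%.17g</data><data key="sc">%s</data></edge>'),
      xml_escape(net$edges$from), xml_escape(net$edges$to),
      net$edges$weight, ifelse(net$edges$sign_consistent, "true", "false"))
    doc <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
      '  <key id="sc" for="edge" attr.name="sign_consistent" attr.type="boolean"/>',
      '  <graph id="G" edgedefault="undirected">',
      nodes, edges,
      '  </graph>',
      '</graphml>'
    )
    con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
      stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
    on.exit(close(con))
    writeLines(doc, con)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "edgelist_tsv") {
    lines <- readLines(path)
    stopifnot(startsWith(lines[1], "# nodes: "))
    nodes <- strsplit(sub("^# nodes: ", "", lines[1]), ",")[[1]]
    body <- lines[-(1:2)]
    if (length(body) == 0) return(pairwise_network(nodes))
    parts <- strsplit(body, "\t", fixed = TRUE)
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      weight = as.numeric(vapply(parts, `[[`, "", 3)),
      sign_consistent = vapply(parts, `[[`, "", 4) == "true"
    )
    return(pairwise_network(nodes, edges))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//g:node", ns), "id")
  enodes <- xml2::xml_find_all(doc, ".//g:edge", ns)
  if (length(enodes) == 0) return(pairwise_network(nodes))
  w <- vapply(enodes, function(e) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(e, './g:data[@key="w"]', ns)))
  }, numeric(1))
  sc <- vapply(enodes, function(e) {
    xml2::xml_text(xml2::xml_find_first(e, './g:data[@key="sc"]', ns)) == "true"
  }, logical(1))
  edges <- tibble::tibble(
    from = xml2::xml_attr(enodes, "source"),
    to = xml2::xml_attr(enodes, "target"),
    weight = w, sign_consistent = sc
  )
  pairwise_network(nodes, edges)
}
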