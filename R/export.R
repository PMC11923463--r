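#' Export a co-occurrence network for Gephi
#'
#' Writes GEXF 1.2, GraphML or a plain edge CSV. Node attributes exported:
#' concept class, degree, community id (if present on the nodes) and ATC
#' class (if present); edge attribute: cosine weight (full double
#' precision, so an export/import round trip restores weights to 1e-9 and
#' better).
#'
#' @param network A `cooc_network`.
#' @param path Output path.
#' @param format `"gexf"`, `"graphml"` or `"edge-csv"` (default from the
#'   file extension).
#' @param membership Optional named community vector to attach as the
#'   `community` node attribute.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("auto", "gexf", "graphml", "edge-csv"),
                           membership = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gexf = "gexf", graphml = "graphml", csv = "edge-csv",
                     stop("cannot guess format from extension: ", path, call. = FALSE))
  }
  nodes <- network$nodes
  if (!is.null(membership)) nodes$community <- unname(membership[nodes$name])
  num <- function(x) sprintf("%.17g", x)
  if (format == "edge-csv") {
    utils::write.csv(data.frame(source = network$edges$from,
                                target = network$edges$to,
                                weight = num(network$edges$weight)),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }

  attrs <- c("class", "community", "atc")
  attrs <- attrs[attrs %in% names(nodes)]
  if (format == "gexf") {
    doc <- xml2::xml_new_root("gexf",
                              xmlns = "http://www.gexf.net/1.2draft",
                              version = "1.2")
    graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
    attdecl <- xml2::xml_add_child(graph, "attributes", class = "node")
    for (i in seq_along(attrs)) {
      xml2::xml_add_child(attdecl, "attribute", id = as.character(i - 1L),
                          title = attrs[i], type = "string")
    }
    xml2::xml_add_child(attdecl, "attribute", id = as.character(length(attrs)),
                        title = "degree", type = "integer")
    nodes_el <- xml2::xml_add_child(graph, "nodes")
    for (i in seq_len(nrow(nodes))) {
      nd <- xml2::xml_add_child(nodes_el, "node", id = nodes$name[i],
                                label = nodes$name[i])
      av <- xml2::xml_add_child(nd, "attvalues")
      for (j in seq_along(attrs)) {
        v <- nodes[[attrs[j]]][i]
        xml2::xml_add_child(av, "attvalue", `for` = as.character(j - 1L),
                            value = ifelse(is.na(v), "", as.character(v)))
      }
      xml2::xml_add_child(av, "attvalue", `for` = as.character(length(attrs)),
                          value = as.character(nodes$degree[i]))
    }
    edges_el <- xml2::xml_add_child(graph, "edges")
    for (i in seq_len(nrow(network$edges))) {
      xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1L),
                          source = network$edges$from[i],
                          target = network$edges$to[i],
                          weight = num(network$edges$weight[i]))
    }
    xml2::write_xml(doc, path)
    return(invisible(path))
  }

  # graphml
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- c(attrs, "degree")
  for (i in seq_along(keydefs)) {
    xml2::xml_add_child(doc, "key", id = paste0("d", i - 1L), `for` = "node",
                        attr.name = keydefs[i],
                        attr.type = ifelse(keydefs[i] == "degree", "int", "string"))
  }
  xml2::xml_add_child(doc, "key", id = "w", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$name[i])
    for (j in seq_along(attrs)) {
      d <- xml2::xml_add_child(nd, "data", key = paste0("d", j - 1L))
      v <- nodes[[attrs[j]]][i]
      xml2::xml_set_text(d, ifelse(is.na(v), "", as.character(v)))
    }
    d <- xml2::xml_add_child(nd, "data", key = paste0("d", length(attrs)))
    xml2::xml_set_text(d, as.character(nodes$degree[i]))
  }
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(graph, "edge", source = network$edges$from[i],
                              target = network$edges$to[i])
    d <- xml2::xml_add_child(ed, "data", key = "w")
    xml2::xml_set_text(d, num(network$edges$weight[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' Round-trip reader for GEXF and GraphML exports; restores node names,
#' classes and edge weights.
#'
#' @param path File path.
#' @param format `"gexf"` or `"graphml"` (default from extension).
#' @return A `cooc_network` (tau recorded as `NA`).
#' @export
import_network <- function(path, format = c("auto", "gexf", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), gexf = "gexf",
                     graphml = "graphml",
                     stop("cannot guess format: ", path, call. = FALSE))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (format == "gexf") {
    nodes_xml <- xml2::xml_find_all(doc, ".//nodes/node")
    name <- xml2::xml_attr(nodes_xml, "id")
    cls <- vapply(nodes_xml, function(n) {
      v <- xml2::xml_find_first(n, ".//attvalue[@for='0']")
      if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_attr(v, "value")
    }, "")
    edges_xml <- xml2::xml_find_all(doc, ".//edges/edge")
    edges <- data.frame(from = xml2::xml_attr(edges_xml, "source"),
                        to = xml2::xml_attr(edges_xml, "target"),
                        weight = as.numeric(xml2::xml_attr(edges_xml, "weight")),
                        stringsAsFactors = FALSE)
  } else {
    keys <- xml2::xml_find_all(doc, ".//key[@for='node']")
    key_names <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                                 xml2::xml_attr(keys, "id"))
    class_key <- names(key_names)[key_names == "class"]
    nodes_xml <- xml2::xml_find_all(doc, ".//graph/node")
    name <- xml2::xml_attr(nodes_xml, "id")
    cls <- vapply(nodes_xml, function(n) {
      if (!length(class_key)) return(NA_character_)
      v <- xml2::xml_find_first(n, sprintf(".//data[@key='%s']", class_key[1]))
      if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
    }, "")
    edges_xml <- xml2::xml_find_all(doc, ".//graph/edge")
    edges <- data.frame(from = xml2::xml_attr(edges_xml, "source"),
                        to = xml2::xml_attr(edges_xml, "target"),
                        weight = vapply(edges_xml, function(e) {
                          as.numeric(xml2::xml_text(xml2::xml_find_first(e, ".//data[@key='w']")))
                        }, 0),
                        stringsAsFactors = FALSE)
  }
  cls[!is.na(cls) & cls == ""] <- NA_character_
  nodes <- data.frame(name = name, class = cls, stringsAsFactors = FALSE)
  new_cooc_network(nodes, edges, NA_real_)
}

#' Persist an incidence matrix as MatrixMarket with label sidecars
#'
#' Writes `<path>` (sparse coordinate MTX), `<path>.rows` and
#' `<path>.cols` (one label per line).
#'
#' @param m Incidence matrix.
#' @param path Output MTX path.
#' @return `path`, invisibly.
#' @export
write_incidence_mtx <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), path)
  writeLines(rownames(m), paste0(path, ".rows"))
  writeLines(colnames(m), paste0(path, ".cols"))
  invisible(path)
}

#' Read an incidence matrix written by [write_incidence_mtx()]
#' @param path MTX path (with `.rows`/`.cols` sidecars next to it).
#' @return Sparse binary incidence matrix with dimnames.
#' @export
read_incidence_mtx <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix") * 1
  dimnames(m) <- list(readLines(paste0(path, ".rows")),
                      readLines(paste0(path, ".cols")))
  m
}
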