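#' Construct a table of signed regulatory edges
#'
#' Edges carry a direction (`source` regulates `destination`), one of the four
#' regulatory relation labels, the sign that label implies (+1 for
#' activation/expression, -1 for inhibition/repression), and a free-text
#' provenance tag (typically the pathway the relation was seen in).
#'
#' @param source,destination Character vectors of target identifiers.
#'   Identifiers are opaque, case-preserving strings matched exactly.
#' @param relation Character vector of relation labels; one of `"activation"`,
#'   `"expression"`, `"inhibition"`, `"repression"`.
#' @param pathway_id Optional character vector of provenance tags (recycled).
#' @return A data frame with columns `source`, `destination`, `sign`,
#'   `relation`, `pathway_id`.
#' @examples
#' reg_edges(c("A", "B"), c("B", "C"), c("activation", "inhibition"))
#' @export
reg_edges <- function(source, destination, relation, pathway_id = "") {
  stopifnot(length(source) == length(destination),
            length(relation) %in% c(1L, length(source)) || length(source) == 0)
  relation <- rep_len(as.character(relation), length(source))
  bad <- which(!relation %in% names(RELATION_SIGNS))
  if (length(bad)) {
    stop("unknown relation label ", sQuote(relation[bad[1]]),
         " in edge record ", bad[1], " (",
         source[bad[1]], " -> ", destination[bad[1]], ")")
  }
  data.frame(
    source = as.character(source),
    destination = as.character(destination),
    sign = unname(RELATION_SIGNS[relation]),
    relation = relation,
    pathway_id = rep_len(as.character(pathway_id), length(source)),
    stringsAsFactors = FALSE
  )
}

#' Build a signed directed regulatory network from edge records
#'
#' Duplicate edges sharing (source, destination, sign) are merged into one,
#' concatenating their provenance tags, so the network holds at most two edges
#' per ordered node pair (one per sign). Opposite-sign edges between the same
#' pair are both kept: a pair of targets can activate under one pathway context
#' and inhibit under another.
#'
#' @param edges A data frame as returned by [reg_edges()] (columns `source`,
#'   `destination`, `relation`; optional `sign` and `pathway_id`). May have
#'   zero rows.
#' @param nodes Optional character vector of node identifiers to include even
#'   when isolated; the final node set is the union of `nodes` and all edge
#'   endpoints.
#' @param quiet Suppress the merge-count message.
#' @return An object of class `regnet`: a list with elements `nodes`
#'   (character vector) and `edges` (merged edge data frame).
#' @examples
#' net <- build_network(reg_edges("A", "B", "activation"))
#' net$nodes
#' @export
build_network <- function(edges = NULL, nodes = NULL, quiet = TRUE) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- reg_edges(character(0), character(0), character(0))
  } else {
    if (!all(c("source", "destination", "relation") %in% names(edges))) {
      stop("edge table must have columns source, destination, relation")
    }
    pid <- if ("pathway_id" %in% names(edges)) edges$pathway_id else ""
    given_sign <- if ("sign" %in% names(edges)) as.integer(edges$sign) else NULL
    edges <- reg_edges(edges$source, edges$destination, edges$relation, pid)
    if (!is.null(given_sign) && !all(given_sign == edges$sign)) {
      bad <- which(given_sign != edges$sign)[1]
      stop("edge record ", bad, " declares sign ", given_sign[bad],
           " inconsistent with relation ", sQuote(edges$relation[bad]))
    }
  }

  n_in <- nrow(edges)
  if (n_in > 0) {
    key <- paste(edges$source, edges$destination, edges$sign, sep = "\r")
    first <- !duplicated(key)
    prov <- vapply(split(edges$pathway_id, factor(key, levels = key[first])),
                   function(p) paste(unique(p[nzchar(p)]), collapse = ";"),
                   character(1))
    merged <- edges[first, , drop = FALSE]
    merged$pathway_id <- unname(prov[paste(merged$source, merged$destination,
                                           merged$sign, sep = "\r")])
    rownames(merged) <- NULL
    edges <- merged
  }
  if (!quiet) {
    message("build_network: kept ", nrow(edges), " edges (merged ",
            n_in - nrow(edges), " duplicates)")
  }

  all_nodes <- sort(unique(c(as.character(nodes),
                             edges$source, edges$destination)))
  structure(list(nodes = all_nodes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat("Signed directed regulatory network:",
      length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  positive edges:", sum(x$edges$sign > 0),
      " negative edges:", sum(x$edges$sign < 0), "\n")
  invisible(x)
}

#' Convert a regulatory network to an igraph graph
#'
#' @param network A `regnet` object.
#' @param directed Build a directed graph (default) or collapse to an
#'   undirected simple graph (used by the centrality screen).
#' @return An `igraph` graph whose vertices are the network's nodes.
#' @export
as_igraph <- function(network, directed = TRUE) {
  stopifnot(inherits(network, "regnet"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "destination", "sign")],
    directed = TRUE, vertices = network$nodes
  )
  if (!directed) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  g
}

#' Screen key targets by above-average centrality
#'
#' Keeps the nodes whose degree, betweenness, and closeness are each strictly
#' greater than the corresponding mean over all nodes of an undirected,
#' unweighted interaction graph. On disconnected graphs closeness is computed
#' within each node's connected component; isolated vertices have undefined
#' closeness, are excluded from the closeness mean, and never pass the screen.
#'
#' @param graph An undirected `igraph` graph, or a `regnet` object (collapsed
#'   to an undirected simple graph first).
#' @return Character vector of key target identifiers (possibly empty; on
#'   vertex-transitive graphs such as complete graphs it is always empty since
#'   every centrality equals its mean).
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' screen_key_targets(g)
#' @export
screen_key_targets <- function(graph) {
  if (inherits(graph, "regnet")) graph <- as_igraph(graph, directed = FALSE)
  stopifnot(inherits(graph, "igraph"))
  if (igraph::vcount(graph) == 0) {
    warning("empty graph: no targets to screen")
    return(character(0))
  }
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(graph))
  above <- function(x) !is.na(x) & x > mean(x, na.rm = TRUE)
  keep <- above(deg) & above(btw) & above(cls)
  nm <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  sort(nm[keep])
}

#' Write a network's edge list as TSV
#'
#' Columns `source`, `destination`, `relation`, `sign`, `pathway_id`; the sign
#' is serialized as `+1` / `-1`. UTF-8, header row, tab-separated.
#'
#' @param network A `regnet` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "regnet"))
  out <- network$edges[, c("source", "destination", "relation", "sign",
                           "pathway_id")]
  out$sign <- sprintf("%+d", out$sign)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an edge-list TSV back into a regulatory network
#'
#' @param path Path to a TSV written by [write_edge_list()] (or any TSV with
#'   columns `source`, `destination`, `relation`; `#` comment lines ignored).
#' @param nodes Optional isolated nodes to include.
#' @return A `regnet` object.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  need <- c("source", "destination", "relation")
  if (!all(need %in% names(tab))) {
    stop("edge list ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  if ("sign" %in% names(tab)) tab$sign <- as.integer(sub("^\\+", "", tab$sign))
  build_network(tab, nodes = nodes)
}
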