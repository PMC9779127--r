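#' Export a ceRNA network for Cytoscape
#'
#' SIF rows are \code{source<TAB>interaction<TAB>target} with interaction
#' labels \code{"lncRNA-miRNA"} / \code{"mRNA-miRNA"}; GraphML carries a
#' \code{type} node attribute (lncRNA/miRNA/mRNA) and an \code{interaction}
#' edge attribute. Re-reading either export reconstructs an identical
#' edge set.
#'
#' @param network a [CeRNANetwork-class].
#' @param path output file path.
#' @param format \code{"SIF"} or \code{"GraphML"}.
#' @return \code{path}, invisibly.
#' @seealso [importNetworkSIF()], [importNetworkGraphML()]
#' @export
exportNetwork <- function(network, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  ed <- networkEdges(network)
  nd <- networkNodes(network)
  if (!nrow(ed)) {
    warning("exporting an empty network")
    if (format == "SIF") {
      writeLines(character(), path)
    } else {
      g <- igraph::make_empty_graph(directed = FALSE)
      igraph::write_graph(g, path, format = "graphml")
    }
    return(invisible(path))
  }
  if (format == "SIF") {
    writeLines(paste(ed$source, ed$interaction, ed$target, sep = "\t"), path)
  } else {
    vert <- data.frame(name = nd$id, type = nd$type, stringsAsFactors = FALSE)
    el <- data.frame(from = ed$source, to = ed$target,
                     interaction = ed$interaction, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = vert)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# rebuild the typed node table from edge endpoints + interaction labels
.networkFromEdges <- function(ed) {
  if (!nrow(ed)) return(CeRNANetwork())
  srcType <- ifelse(ed$interaction == "lncRNA-miRNA", "lncRNA", "mRNA")
  nd <- unique(rbind(
    data.frame(id = ed$source, type = srcType, stringsAsFactors = FALSE),
    data.frame(id = ed$target, type = "miRNA", stringsAsFactors = FALSE)))
  CeRNANetwork(nodes = nd, edges = ed)
}

#' Import a ceRNA network from a SIF file
#' @param path path to a SIF file written by [exportNetwork()].
#' @return A [CeRNANetwork-class].
#' @export
importNetworkSIF <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(CeRNANetwork())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3))
    stop("malformed SIF row at line ", which(nf != 3)[1])
  ed <- data.frame(source = vapply(parts, `[`, "", 1),
                   interaction = vapply(parts, `[`, "", 2),
                   target = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  .networkFromEdges(unique(ed))
}

#' Import a ceRNA network from a GraphML file
#' @param path path to a GraphML file written by [exportNetwork()].
#' @return A [CeRNANetwork-class].
#' @export
importNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::gorder(g) == 0) return(CeRNANetwork())
  el <- igraph::as_data_frame(g, what = "edges")
  vt <- igraph::as_data_frame(g, what = "vertices")
  nd <- data.frame(id = vt$name, type = vt$type, stringsAsFactors = FALSE)
  # orient every edge RNA -> miRNA regardless of storage order
  tp <- stats::setNames(nd$type, nd$id)
  swap <- tp[el$from] == "miRNA"
  src <- ifelse(swap, el$to, el$from)
  tgt <- ifelse(swap, el$from, el$to)
  ed <- data.frame(source = src, interaction = el$interaction, target = tgt,
                   stringsAsFactors = FALSE)
  CeRNANetwork(nodes = nd[order(nd$id), , drop = FALSE],
               edges = unique(ed))
}
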