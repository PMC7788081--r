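#' Population trees
#'
#' A reference atlas is optionally organized as a rooted tree of populations
#' (e.g. the hematopoietic hierarchy with HSC at the root). The tree is held
#' as a parent/child edge table plus a declared root and backs the tie-break
#' rule of [assign_counterparts()] and the heterogeneity/stemness readouts
#' of [mapping_report()].
#'
#' @param edges data.frame with columns `parent`, `child`.
#' @param root name of the root population.
#' @return object of class `pop_tree`.
#' @export
pop_tree <- function(edges, root) {
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  nodes <- unique(c(edges$parent, edges$child, root))
  if (anyDuplicated(edges$child)) stop("a node has two parents")
  if (root %in% edges$child) stop("declared root has a parent")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_connected(g) || igraph::ecount(g) != length(nodes) - 1)
    stop("edges do not form a single rooted tree")
  structure(list(edges = edges, root = root, nodes = nodes, graph = g),
            class = "pop_tree")
}

#' @rdname pop_tree
#' @param path two-column TSV (`parent`, `child`; header optional).
#' @export
read_tree <- function(path, root) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  if (identical(tolower(tab[1, 1]), "parent")) tab <- tab[-1, , drop = FALSE]
  pop_tree(data.frame(parent = tab[[1]], child = tab[[2]]), root = root)
}

#' @rdname pop_tree
#' @param tree a `pop_tree`.
#' @return `tree_depths()`: named integer vector of edge distances from the
#'   root; `tree_distances()`: symmetric matrix of pairwise path lengths.
#' @export
tree_depths <- function(tree) {
  stopifnot(inherits(tree, "pop_tree"))
  d <- igraph::distances(tree$graph, v = tree$root)
  stats::setNames(as.integer(d[1, tree$nodes]), tree$nodes)
}

#' @rdname pop_tree
#' @export
tree_distances <- function(tree) {
  stopifnot(inherits(tree, "pop_tree"))
  d <- igraph::distances(tree$graph)
  d[tree$nodes, tree$nodes]
}

#' @export
print.pop_tree <- function(x, ...) {
  cat(sprintf("pop_tree: %d populations rooted at %s\n",
              length(x$nodes), x$root))
  invisible(x)
}
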