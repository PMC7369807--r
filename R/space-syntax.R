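#' Street networks as axial graphs
#'
#' Space-syntax measures operate on the axial graph of a street network:
#' nodes are axial lines (street segments), edges join lines that
#' intersect. Graphs are undirected and simple; self-loops and duplicate
#' edges are dropped on construction. Deriving the axial map from street
#' geometry is out of scope — graphs are supplied as edge lists or GraphML.
#'
#' @param edges Two-column data frame/matrix of node-id pairs, or a path to
#'   an edge-list text file (two whitespace/comma-separated columns) or a
#'   `.graphml` file.
#' @param nodes Optional character vector of node ids (to keep isolated
#'   nodes); ids appearing in `edges` are added automatically.
#' @return A `street_graph` (an igraph object with class prepended).
#' @examples
#' g <- street_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' connectivity(g)
#' @export
street_graph <- function(edges, nodes = NULL) {
  if (is.character(edges) && length(edges) == 1) {
    g <- if (grepl("\\.graphml$", edges, ignore.case = TRUE)) {
      igraph::read_graph(edges, format = "graphml")
    } else {
      df <- utils::read.table(edges, header = FALSE, sep = "",
                              colClasses = "character",
                              col.names = c("from", "to"))
      igraph::graph_from_data_frame(df, directed = FALSE)
    }
    g <- igraph::as_undirected(g, mode = "collapse")
  } else {
    df <- as.data.frame(edges)[, 1:2]
    df[] <- lapply(df, as.character)
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = nodes)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  class(g) <- c("street_graph", class(g))
  g
}

#' Write a street graph to GraphML
#'
#' @param g A `street_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_street_graph <- function(g, path) {
  igraph::write_graph(strip_sg(g), path, format = "graphml")
  invisible(path)
}

strip_sg <- function(g) {
  class(g) <- setdiff(class(g), "street_graph")
  g
}

node_ids <- function(g) igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))

#' Connectivity (degree) of each axial line
#'
#' Connectivity is the number of other axial lines a line intersects — the
#' node degree. High-connectivity streets are easier to enter and leave.
#'
#' @param g A `street_graph`.
#' @return Tibble with `node` and integer `connectivity`.
#' @export
connectivity <- function(g) {
  d <- igraph::degree(strip_sg(g))
  tibble::tibble(node = node_ids(g), connectivity = as.integer(d))
}

#' Depth of a graph from a root node
#'
#' Total and mean topological (shortest-path) depth of all other nodes from
#' `root`, by breadth-first search. The graph must reach every node from
#' the root; unreachable nodes are an error (depth is undefined), with the
#' unreachable set listed.
#'
#' @param g A `street_graph`.
#' @param root Node id.
#' @return A list with `total_depth` (integer) and `mean_depth`.
#' @export
depth_metrics <- function(g, root) {
  gg <- strip_sg(g)
  d <- as.numeric(igraph::distances(gg, v = root))
  ids <- node_ids(g)
  d <- d[ids != root]
  if (any(!is.finite(d))) {
    stop_input("nodes unreachable from `", root, "`: ",
               paste(ids[ids != root][!is.finite(d)], collapse = ", "))
  }
  list(total_depth = as.integer(sum(d)), mean_depth = mean(d))
}

# Diamond value D(n): mean RA of the "diamond" benchmark graph, the
# standard normalization making relative asymmetry comparable across
# system sizes.
diamond_value <- function(n) {
  2 * (n * (log2((n + 2) / 3) - 1) + 1) / ((n - 1) * (n - 2))
}

#' Integration of each axial line
#'
#' Integration measures how aggregated a space is with all others: from the
#' mean depth d of a node, relative asymmetry RA = 2(d - 1)/(n - 2) is
#' normalized by the diamond value D(n) to RRA = RA/D(n), and integration
#' is 1/RRA (higher = more integrated). A node at mean depth 1 (e.g. a star
#' center) has RA = 0 and its integration is reported as `Inf`.
#'
#' @param g A connected `street_graph` with at least 3 nodes.
#' @return Tibble with `node`, `total_depth`, `mean_depth`, `ra`, `rra`,
#'   `integration`.
#' @export
integration <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3) stop_input("integration needs at least 3 nodes")
  if (!igraph::is_connected(strip_sg(g))) {
    stop_input("integration is undefined on a disconnected graph")
  }
  dmat <- igraph::distances(strip_sg(g))
  ids <- node_ids(g)
  purrr::map_dfr(seq_len(n), function(i) {
    d <- dmat[i, -i]
    md <- mean(d)
    ra <- 2 * (md - 1) / (n - 2)
    rra <- ra / diamond_value(n)
    tibble::tibble(node = ids[i], total_depth = as.integer(sum(d)),
                   mean_depth = md, ra = ra, rra = rra,
                   integration = if (rra > 0) 1 / rra else Inf)
  })
}

#' Choice (betweenness) of each axial line
#'
#' Choice captures through-movement potential: the fraction of shortest
#' paths between all other node pairs that pass through a node, with equal
#' split over tied shortest paths, normalized by the number of pairs
#' (n - 1)(n - 2)/2.
#'
#' @param g A connected `street_graph`.
#' @return Tibble with `node` and normalized `choice` in \[0, 1\].
#' @export
choice <- function(g) {
  if (!igraph::is_connected(strip_sg(g))) {
    stop_input("choice is undefined on a disconnected graph")
  }
  b <- igraph::betweenness(strip_sg(g), directed = FALSE)
  n <- igraph::vcount(g)
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  tibble::tibble(node = node_ids(g), choice = as.numeric(b) / denom)
}

#' All space-syntax measures in one table
#'
#' @param g A connected `street_graph` with at least 3 nodes.
#' @return Tibble joining [connectivity()], [integration()] and [choice()]
#'   by node.
#' @examples
#' space_syntax(simulate_street_graph("cycle", 6))
#' @export
space_syntax <- function(g) {
  connectivity(g) |>
    dplyr::left_join(integration(g), by = "node") |>
    dplyr::left_join(choice(g), by = "node")
}
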