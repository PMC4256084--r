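#' Construct a labeled binary directed network
#'
#' The substrate for all simulation and analysis in queuenet: an unweighted
#' directed graph stored as a binary adjacency matrix with an ordered set of
#' unique node labels. Entry `(i, j) = 1` means a projection from node `i` to
#' node `j`. Self-loops are rejected because the traffic model's routing and
#' content accounting never reference self-projections; `drop_self_loops =
#' TRUE` removes them with a warning instead.
#'
#' @param adjacency Square numeric/integer matrix with entries in `{0, 1}`.
#'   Any other nonzero value is an error, not a weight: the model is
#'   unweighted and assumes no variation across nodes or edges.
#' @param labels Character vector of unique node labels, one per row of
#'   `adjacency`, in matrix order. Defaults to `rownames(adjacency)`, or
#'   `"n1" ... "nN"` when the matrix is unnamed.
#' @param drop_self_loops If `TRUE`, nonzero diagonal entries are zeroed with
#'   a warning rather than raising an error.
#'
#' @return An object of class `directed_network`: a list with elements
#'   `adjacency` (integer matrix with dimnames) and `labels`.
#' @examples
#' chain <- directed_network(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
#'                           labels = c("1", "2", "3"))
#' chain
#' @export
directed_network <- function(adjacency, labels = NULL, drop_self_loops = FALSE) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    abort("`adjacency` must be a square matrix.")
  }
  if (anyNA(adjacency)) abort("`adjacency` contains missing values.")
  if (!all(adjacency %in% c(0, 1))) {
    abort(paste0(
      "`adjacency` must be binary (0/1). Found entries: ",
      paste(utils::head(setdiff(unique(as.vector(adjacency)), c(0, 1)), 3),
            collapse = ", "),
      ". Weighted networks are not supported."))
  }
  n <- nrow(adjacency)
  if (is.null(labels)) labels <- rownames(adjacency)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    abort(sprintf("%d labels supplied for a %d-node adjacency matrix.",
                  length(labels), n))
  }
  if (anyDuplicated(labels)) abort("Node labels must be unique.")
  diag_hits <- which(diag(adjacency) != 0)
  if (length(diag_hits) > 0) {
    if (drop_self_loops) {
      warn(sprintf("Dropped %d self-loop(s) at: %s", length(diag_hits),
                   paste(head(labels[diag_hits], 5), collapse = ", ")))
      diag(adjacency) <- 0
    } else {
      abort(paste0(
        "Self-loops found at: ",
        paste(head(labels[diag_hits], 5), collapse = ", "),
        ". The traffic model has no self-projections; pass ",
        "`drop_self_loops = TRUE` to remove them."))
    }
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, labels = labels),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d edges\n",
              n_nodes(x), n_edges(x)))
  cat(sprintf("  density %.4f | strongly connected: %s\n",
              n_edges(x) / (n_nodes(x) * (n_nodes(x) - 1L)),
              if (is_strongly_connected(x)) "yes" else "no"))
  invisible(x)
}

#' Node and edge counts of a directed network
#' @param net A `directed_network`.
#' @return An integer scalar.
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  length(net$labels)
}

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  sum(net$adjacency)
}

#' Convert to and from igraph
#'
#' @param net A `directed_network`.
#' @param graph A directed `igraph` graph with a `name` vertex attribute.
#' @return `as_igraph()` returns an igraph graph; `from_igraph()` a
#'   `directed_network` whose node order follows the graph's vertex order.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
}

#' @rdname as_igraph
#' @export
from_igraph <- function(graph) {
  if (!igraph::is_directed(graph)) abort("Graph must be directed.")
  adj <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  labels <- igraph::vertex_attr(graph, "name")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(adj)))
  directed_network(adj, labels = labels)
}

#' Is the network strongly connected?
#'
#' Reported as a diagnostic: simulation only requires out-degree >= 1
#' everywhere, so strong connectivity is never enforced.
#' @param net A `directed_network`.
#' @return Logical scalar.
#' @export
is_strongly_connected <- function(net) {
  igraph::is_connected(as_igraph(net), mode = "strong")
}

#' Read a directed network from disk
#'
#' Three formats are supported:
#' \describe{
#'   \item{`edgelist`}{CSV with header `source,target`, one directed edge per
#'     row. An optional companion `labels` file (one label per line) fixes
#'     the node order and declares isolated nodes; without it, node order is
#'     first appearance in the file.}
#'   \item{`graphml`}{Standard directed GraphML (read via igraph).}
#'   \item{`mat`}{A MATLAB-style MAT container holding the adjacency under
#'     array `CoCoMac_adjacency` (or `adjacency`) and labels under cell
#'     `Labels` (or `labels`), the layout used for published macaque
#'     connectome matrices. Parsed with scipy.io through the `python` on
#'     `PATH`; errors if no python with scipy is available.}
#' }
#'
#' @param path Path to the network file.
#' @param format One of `"edgelist"`, `"graphml"`, `"mat"`.
#' @param labels Optional path to a companion label file (edgelist only).
#' @param drop_self_loops Passed to [directed_network()].
#' @return A validated `directed_network`; node order follows the file.
#' @export
read_network <- function(path, format = c("edgelist", "graphml", "mat"),
                         labels = NULL, drop_self_loops = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  switch(format,
    edgelist = read_network_edgelist(path, labels, drop_self_loops),
    graphml  = read_network_graphml(path, drop_self_loops),
    mat      = read_network_mat(path, drop_self_loops))
}

read_network_edgelist <- function(path, labels_path, drop_self_loops) {
  edges <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c("source", "target") %in% names(edges))) {
    abort("Edge list must have a header with columns `source,target`.")
  }
  if (!is.null(labels_path)) {
    labels <- readr::read_lines(labels_path)
    labels <- labels[nzchar(labels)]
    missing <- setdiff(unique(c(edges$source, edges$target)), labels)
    if (length(missing) > 0) {
      abort(paste0("Edges reference labels absent from the label file: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  } else {
    labels <- unique(c(rbind(edges$source, edges$target)))
  }
  n <- length(labels)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    adj[cbind(match(edges$source, labels), match(edges$target, labels))] <- 1L
  }
  directed_network(adj, labels = labels, drop_self_loops = drop_self_loops)
}

read_network_graphml <- function(path, drop_self_loops) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!igraph::is_directed(g)) abort("GraphML graph must be directed.")
  if (drop_self_loops) {
    nloop <- sum(igraph::which_loop(g))
    if (nloop > 0) {
      warn(sprintf("Dropped %d self-loop(s).", nloop))
      g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
    }
  }
  from_igraph(g)
}

read_network_mat <- function(path, drop_self_loops) {
  python <- Sys.which("python")
  if (!nzchar(python)) {
    abort("Reading MAT containers requires a `python` with scipy on PATH.")
  }
  out_json <- tempfile(fileext = ".json")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "import scipy.io",
    "m = scipy.io.loadmat(sys.argv[1])",
    "akey = next((k for k in ('CoCoMac_adjacency', 'adjacency') if k in m), None)",
    "lkey = next((k for k in ('Labels', 'labels') if k in m), None)",
    "if akey is None:",
    "    sys.exit('no adjacency array (CoCoMac_adjacency/adjacency) in MAT file')",
    "A = np.asarray(m[akey])",
    "if lkey is not None:",
    "    labels = [str(np.ravel(x)[0]) for x in np.ravel(m[lkey])]",
    "else:",
    "    labels = [f'n{i+1}' for i in range(A.shape[0])]",
    "rows, cols = np.nonzero(A)",
    "vals = A[rows, cols]",
    "json.dump({'labels': labels,",
    "           'rows': rows.tolist(), 'cols': cols.tolist(),",
    "           'vals': [float(v) for v in vals]},",
    "          open(sys.argv[2], 'w'))"
  ), script)
  status <- system2(python, c(script, shQuote(path), shQuote(out_json)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_json) || !is.null(attr(status, "status"))) {
    abort(paste0("Failed to parse MAT container: ",
                 paste(status, collapse = "\n")))
  }
  parsed <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  labels <- as.character(parsed$labels)
  n <- length(labels)
  adj <- matrix(0, n, n)
  if (length(parsed$rows) > 0) {
    adj[cbind(parsed$rows + 1, parsed$cols + 1)] <- parsed$vals
  }
  directed_network(adj, labels = labels, drop_self_loops = drop_self_loops)
}

#' Write a directed network to disk
#'
#' `edgelist` writes a `source,target` CSV (and a companion label file when
#' `labels` is given, preserving node order and isolated nodes); `graphml`
#' writes directed GraphML with node names. Both round-trip exactly through
#' [read_network()].
#'
#' @param net A `directed_network`.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param labels Optional path for the companion label file (edgelist only).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml"),
                          labels = NULL) {
  stopifnot(inherits(net, "directed_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    idx <- which(net$adjacency == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    readr::write_csv(tibble::tibble(source = net$labels[idx[, 1]],
                                    target = net$labels[idx[, 2]]), path)
    if (!is.null(labels)) readr::write_lines(net$labels, labels)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Per-node in- and out-degrees
#'
#' Exact row/column sums of the adjacency matrix. The in-degree sum, the
#' out-degree sum, and the edge count always coincide.
#'
#' @param net A `directed_network`.
#' @return A tibble with columns `node`, `k_in`, `k_out`, one row per node
#'   in network order.
#' @examples
#' net <- directed_network(rbind(c(0, 1), c(1, 0)), c("a", "b"))
#' node_degrees(net)
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  tibble::tibble(
    node  = net$labels,
    k_in  = as.integer(colSums(net$adjacency)),
    k_out = as.integer(rowSums(net$adjacency)))
}

#' Unidirectional edges of a network
#'
#' The ordered pairs `(i, j)` with an edge `i -> j` but no reciprocal edge
#' `j -> i`. These are the only edges the direction-reversal null model acts
#' on. Together with the reciprocal pairs they partition the edge set.
#'
#' @param net A `directed_network`.
#' @return A tibble with columns `from`, `to`, in row-major matrix order.
#' @export
unidirectional_edges <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  a <- net$adjacency
  uni <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  uni <- uni[order(uni[, 1], uni[, 2]), , drop = FALSE]
  tibble::tibble(from = net$labels[uni[, 1]], to = net$labels[uni[, 2]])
}

#' Reciprocal (bidirectional) node pairs
#'
#' @param net A `directed_network`.
#' @return A tibble with columns `a`, `b` (`a` before `b` in node order),
#'   one row per pair connected in both directions.
#' @export
reciprocal_pairs <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  a <- net$adjacency
  rec <- which(a == 1L & t(a) == 1L, arr.ind = TRUE)
  rec <- rec[rec[, 1] < rec[, 2], , drop = FALSE]
  rec <- rec[order(rec[, 1], rec[, 2]), , drop = FALSE]
  tibble::tibble(a = net$labels[rec[, 1]], b = net$labels[rec[, 2]])
}

#' Degree profile of a node's in-neighbourhood
#'
#' For each requested node, the set of in-neighbours (nodes projecting to
#' it) and the mean in- and out-degree of that set. Nodes with no
#' in-neighbours get `NA` means: the profile is undefined there, and the
#' row is flagged rather than dropped.
#'
#' @param net A `directed_network`.
#' @param nodes Labels to profile; default all nodes.
#' @return A tibble with columns `node`, `n_in_neighbours`, `nbr_mean_k_in`,
#'   `nbr_mean_k_out` and a list-column `in_neighbours`.
#' @export
in_neighbour_profile <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "directed_network"))
  if (is.null(nodes)) nodes <- net$labels
  unknown <- setdiff(nodes, net$labels)
  if (length(unknown) > 0) {
    abort(paste0("Unknown node label(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  deg <- node_degrees(net)
  purrr::map_dfr(nodes, function(lbl) {
    j <- match(lbl, net$labels)
    nbrs <- net$labels[net$adjacency[, j] == 1L]
    tibble::tibble(
      node = lbl,
      n_in_neighbours = length(nbrs),
      nbr_mean_k_in  = if (length(nbrs)) mean(deg$k_in[match(nbrs, deg$node)]) else NA_real_,
      nbr_mean_k_out = if (length(nbrs)) mean(deg$k_out[match(nbrs, deg$node)]) else NA_real_,
      in_neighbours = list(nbrs))
  })
}

#' Assortativity profile: node degree vs in-neighbour mean degrees
#'
#' One row per node combining its own degrees with the mean in- and
#' out-degree of its in-neighbours, the table behind degree-assortativity
#' scatter plots. Nodes without in-neighbours carry `NA` neighbour means.
#'
#' @param net A `directed_network`.
#' @return A tibble with columns `node`, `k_in`, `k_out`, `nbr_mean_k_in`,
#'   `nbr_mean_k_out`, in network node order.
#' @export
assortativity_profile <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  dplyr::left_join(node_degrees(net),
                   dplyr::select(in_neighbour_profile(net), "node",
                                 "nbr_mean_k_in", "nbr_mean_k_out"),
                   by = "node")
}
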