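#' Directed graph view with recomputed node weights
#'
#' Builds the igraph object and recomputes each node's weight as the sum
#' of its incoming edge weights (never trusted from input).
#'
#' @param network an `effective_network`, an igraph graph, or an edge
#'   data frame with `src`, `dst` and optional `weight`.
#' @return list with `graph` (igraph) and `node_weights` (named numeric).
#' @keywords internal
.as_graph <- function(network) {
  if (inherits(network, "effective_network")) {
    g <- as_igraph(network)
  } else if (inherits(network, "igraph")) {
    g <- network
  } else {
    g <- igraph::graph_from_data_frame(network, directed = TRUE)
  }
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  w <- igraph::strength(g, mode = "in",
                        weights = if (is.null(igraph::E(g)$weight))
                          rep(1, igraph::ecount(g)) else igraph::E(g)$weight)
  list(graph = g, node_weights = w)
}

#' In- and out-degrees
#'
#' @param network see [.as_graph()] accepted forms.
#' @return data frame with `node`, `in_degree`, `out_degree`.
#' @export
degrees <- function(network) {
  g <- .as_graph(network)$graph
  data.frame(node = igraph::V(g)$name,
             in_degree = as.integer(igraph::degree(g, mode = "in")),
             out_degree = as.integer(igraph::degree(g, mode = "out")),
             stringsAsFactors = FALSE)
}

#' k-core decomposition
#'
#' Core numbers from the standard peeling procedure on the underlying
#' undirected simple graph using total degree: nodes of degree < k are
#' removed iteratively, and a node's core number is the largest k at which
#' it survives.
#'
#' @inheritParams degrees
#' @return named integer vector of core numbers.
#' @export
kcore <- function(network) {
  g <- .as_graph(network)$graph
  und <- igraph::as_undirected(g, mode = "collapse")
  setNames(as.integer(igraph::coreness(und)), igraph::V(und)$name)
}

# exact minimum FVS of one strongly connected component, by increasing
# subset cardinality; returns all optima when collect_all
.fvs_scc <- function(sub, collect_all = FALSE, limit = 20) {
  m <- igraph::vcount(sub)
  if (m > limit)
    stop(sprintf("strongly connected component of size %d exceeds the exact-solver limit (%d); raise `limit` for moderate sizes only -- the search is exponential",
                 m, limit))
  verts <- seq_len(m)
  for (k in 1:m) {
    sets <- combn(verts, k, simplify = FALSE)
    feas <- Filter(function(s) {
      igraph::is_dag(igraph::delete_vertices(sub, s))
    }, sets)
    if (length(feas)) {
      if (!collect_all) feas <- feas[1]
      return(lapply(feas, function(s) igraph::V(sub)$name[s]))
    }
  }
  list(igraph::V(sub)$name)  # unreachable: full set is always an FVS
}

.fvs_solve <- function(network, weighted, limit) {
  parts <- .as_graph(network)
  g <- parts$graph
  w <- parts$node_weights
  comp <- igraph::components(g, mode = "strong")
  chosen <- character()
  for (ci in which(tabulate(comp$membership, comp$no) >= 2)) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
    if (igraph::is_dag(sub)) next
    if (!weighted) {
      chosen <- c(chosen, .fvs_scc(sub, collect_all = FALSE, limit = limit)[[1]])
    } else {
      opts <- .fvs_scc(sub, collect_all = TRUE, limit = limit)
      tw <- vapply(opts, function(s) sum(w[s]), numeric(1))
      chosen <- c(chosen, opts[[which.max(tw)]])
    }
  }
  # verify: removing in-edges of the chosen set must leave the graph acyclic
  resid <- g
  if (length(chosen) && igraph::ecount(g) > 0) {
    heads <- igraph::head_of(g, igraph::E(g))$name
    resid <- igraph::delete_edges(g, which(heads %in% chosen))
  }
  if (!igraph::is_dag(resid)) stop("internal error: returned set is not an FVS")
  sort(chosen)
}

#' Minimum feedback vertex set
#'
#' A smallest node set whose removal of incoming edges eliminates every
#' directed cycle; such nodes act as driver nodes for wide classes of
#' dynamics. Solved exactly per strongly connected component by
#' lexicographic subset search, and verified post hoc by a topological
#' acyclicity check.
#'
#' @inheritParams degrees
#' @param limit largest strongly connected component the exact search will
#'   attempt (default 20).
#' @return character vector of node names (possibly empty).
#' @export
mfvs <- function(network, limit = 20) .fvs_solve(network, weighted = FALSE, limit = limit)

#' Weighted minimum feedback vertex set
#'
#' Among all minimum-cardinality feedback vertex sets, returns one with
#' maximum total node weight, where a node's weight is the recomputed sum
#' of its incoming edge weights. The objective is strictly lexicographic:
#' cardinality first, weight second.
#'
#' @inheritParams mfvs
#' @return character vector of node names.
#' @export
wmfvs <- function(network, limit = 20) .fvs_solve(network, weighted = TRUE, limit = limit)

#' Per-class summary of a node metric
#'
#' @param values named numeric vector of a per-node metric (names are node
#'   ids) or data frame from [degrees()].
#' @param labels named character vector of "excitatory"/"inhibitory".
#' @param probs quantiles to report alongside the mean.
#' @return data frame with one row per class: `ei_label`, `n`, `mean`, and
#'   one column per quantile. Classes with no nodes get `NA` with a
#'   warning.
#' @export
metric_by_class <- function(values, labels, probs = c(0.25, 0.5, 0.75)) {
  if (is.data.frame(values)) stop("pass a single named metric vector")
  out <- lapply(c("excitatory", "inhibitory"), function(cl) {
    v <- values[names(values) %in% names(labels)[labels == cl]]
    if (length(v) == 0) {
      warning(sprintf("no nodes in class %s", cl))
      qs <- rep(NA_real_, length(probs))
    } else qs <- quantile(v, probs, na.rm = TRUE)
    d <- data.frame(ei_label = cl, n = length(v),
                    mean = if (length(v)) mean(v, na.rm = TRUE) else NA_real_)
    d[paste0("q", probs * 100)] <- as.list(qs)
    d
  })
  do.call(rbind, out)
}
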