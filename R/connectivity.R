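#' Translate trained Auto-CM weights into strengths of association
#'
#' The learned `w` matrix is symmetrised by its arithmetic mean with its
#' transpose (it is near-symmetric at convergence and the map is
#' undirected) and normalised by the contraction constant `C`, giving the
#' strength of association `SA[i, j] = (w[i, j] + w[j, i]) / (2 C)` in
#' `[0, 1]`. SA near 1 means two variables are highly connected; near 0,
#' unconnected. The implied distance is `d = 1 - SA`: strongly associated
#' variables become near, weakly associated ones far.
#'
#' @param model A trained `"autocm"` model (see [autocm_train()]).
#' @return Symmetric `N x N` SA matrix with zero diagonal, entries clipped
#'   to `[0, 1]`, dimnames from the model's node labels.
#' @export
weights_to_sa <- function(model) {
  stopifnot(inherits(model, "autocm"))
  w <- model$w
  if (max(w) == 0) {
    warning("untrained model (all-zero weights): SA is zero everywhere",
            call. = FALSE)
  }
  sa <- (w + t(w)) / (2 * model$C)
  sa <- pmin(pmax(sa, 0), 1)
  diag(sa) <- 0
  sa
}

#' Filter an SA matrix to its spanning tree of main connections
#'
#' Computes the minimum spanning tree of the distances `d = 1 - SA`
#' (equivalently, the maximum-SA spanning tree) with Kruskal's algorithm.
#' Ties in distance are broken lexicographically on the (node_a, node_b)
#' labels so the result is bit-reproducible.
#'
#' @param sa Symmetric numeric SA matrix (`N >= 2`), entries in `[0, 1]`,
#'   with node labels as dimnames (defaults to `V1..VN`).
#' @return A data.frame of the `N - 1` tree edges with columns `node_a`,
#'   `node_b` and `sa`, ordered by decreasing SA (then lexicographically).
#' @examples
#' sa <- matrix(c(0, .9, .1, .9, 0, .8, .1, .8, 0), 3,
#'              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' mst_filter(sa)
#' @export
mst_filter <- function(sa) {
  sa <- as.matrix(sa)
  n <- nrow(sa)
  if (n < 2) stop("need at least 2 nodes to build a map", call. = FALSE)
  if (!isTRUE(all.equal(sa, t(sa)))) {
    stop("SA matrix must be symmetric", call. = FALSE)
  }
  nodes <- rownames(sa)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(n))

  idx <- which(upper.tri(sa), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  d <- 1 - sa[idx]
  ord <- order(d, nodes[a], nodes[b], method = "radix")
  a <- a[ord]; b <- b[ord]; d <- d[ord]

  # Kruskal with union-find; lexicographic order above fixes tie-breaking.
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- integer(0)
  for (k in seq_along(d)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep <- c(keep, k)
      if (length(keep) == n - 1) break
    }
  }
  data.frame(node_a = nodes[a[keep]], node_b = nodes[b[keep]],
             sa = sa[cbind(a[keep], b[keep])], stringsAsFactors = FALSE)
}

#' Identify the hubs of a connectivity map
#'
#' A hub is a variable connected with several other variables: every node
#' whose degree in the spanning tree equals the maximum degree (all ties
#' included).
#'
#' @param map A `"connectivity_map"` (see [connectivity_map()]) or a tree
#'   edge data.frame from [mst_filter()].
#' @return Character vector of hub node labels.
#' @export
find_hubs <- function(map) {
  edges <- if (inherits(map, "connectivity_map")) map$edges else map
  deg <- table(c(edges$node_a, edges$node_b))
  names(deg)[deg == max(deg)]
}

#' Build the semantic connectivity map from a trained Auto-CM
#'
#' Bundles the full pipeline tail: weights to SA ([weights_to_sa()]),
#' spanning-tree filtering ([mst_filter()]) and hub detection
#' ([find_hubs()]). The result is the map whose nodes are variables, whose
#' edges form a connected acyclic graph of main connections, and whose edge
#' labels are the SA values.
#'
#' @param model A trained `"autocm"`, or a precomputed symmetric SA matrix.
#' @return An object of class `"connectivity_map"`: list with `nodes`,
#'   `sa` (full symmetric matrix), `edges` (the `N - 1` tree edges) and
#'   `hubs`.
#' @examples
#' m <- matrix(runif(200), 50, 4,
#'             dimnames = list(NULL, c("a", "b", "c", "d")))
#' fit <- autocm_train(m, autocm_config(max_epochs = 200))
#' cmap <- connectivity_map(fit)
#' cmap$hubs
#' @export
connectivity_map <- function(model) {
  sa <- if (inherits(model, "autocm")) weights_to_sa(model) else {
    stopifnot(is.matrix(model))
    model
  }
  nodes <- rownames(sa)
  if (is.null(nodes)) {
    nodes <- paste0("V", seq_len(nrow(sa)))
    dimnames(sa) <- list(nodes, nodes)
  }
  edges <- mst_filter(sa)
  structure(list(nodes = nodes, sa = sa, edges = edges,
                 hubs = find_hubs(edges)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d nodes, %d tree edges, SA in [%.2f, %.2f]\n",
              length(x$nodes), nrow(x$edges), min(x$edges$sa),
              max(x$edges$sa)))
  cat("  hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Export a connectivity map
#'
#' Writes the map as an edge-list CSV (`node_a`, `node_b`, `sa_rounded` to
#' two decimals as printed on map figures, `sa_full` at full precision,
#' `is_tree_edge`), as GraphML, or as Graphviz DOT. Graph formats carry the
#' SA as an edge attribute and flag hub nodes with a node attribute.
#'
#' @param map A `"connectivity_map"`.
#' @param path Output file path.
#' @param format `"edge_csv"`, `"graphml"` or `"dot"`.
#' @param edges `"tree"` (default) writes only the spanning-tree edges;
#'   `"all"` writes every node pair (edge_csv only), with tree membership
#'   flagged.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path, format = c("edge_csv", "graphml", "dot"),
                       edges = c("tree", "all")) {
  stopifnot(inherits(map, "connectivity_map"))
  format <- match.arg(format)
  edges <- match.arg(edges)

  tree_key <- paste(pmin(map$edges$node_a, map$edges$node_b),
                    pmax(map$edges$node_a, map$edges$node_b), sep = "\r")
  if (format == "edge_csv") {
    if (edges == "all") {
      idx <- which(upper.tri(map$sa), arr.ind = TRUE)
      df <- data.frame(node_a = map$nodes[idx[, 1]],
                       node_b = map$nodes[idx[, 2]],
                       sa = map$sa[idx], stringsAsFactors = FALSE)
    } else {
      df <- map$edges
    }
    key <- paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b),
                 sep = "\r")
    out <- data.frame(node_a = df$node_a, node_b = df$node_b,
                      sa_rounded = sprintf("%.2f", df$sa),
                      sa_full = sprintf("%.17g", df$sa),
                      is_tree_edge = key %in% tree_key,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(path))
  }

  g <- igraph::graph_from_data_frame(map$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = map$nodes))
  igraph::E(g)$sa <- map$edges$sa
  igraph::E(g)$label <- sprintf("%.2f", map$edges$sa)
  is_hub <- map$nodes %in% map$hubs
  # DOT has no boolean attribute type; write 0/1 there
  igraph::V(g)$is_hub <- if (format == "dot") as.integer(is_hub) else is_hub
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
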