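#' Feature graphs for structured penalties
#'
#' A `feature_graph` is an undirected, unweighted graph over the features of
#' one side (X or Y) of a paired dataset. Its edge set determines which
#' feature pairs the graph-OSCAR penalty acts on. Edges are stored uniquely
#' with `i < j`; self-loops are rejected. With no prior network available the
#' complete graph is used ("group-pursuit mode"), in which case graph-OSCAR
#' coincides with the classical OSCAR penalty over all pairs.
#'
#' @param n_features number of vertices (features), a positive integer.
#' @param edges two-column integer matrix of 1-based vertex pairs, one edge
#'   per row, or `NULL` for an empty edge set. Duplicates (in either
#'   orientation) are collapsed.
#' @return An object of class `feature_graph` with elements `n_features` and
#'   `edges` (an m x 2 integer matrix with `edges[,1] < edges[,2]`).
#' @examples
#' g <- feature_graph(4, rbind(c(1, 2), c(2, 1), c(3, 4)))
#' n_edges(g) # 2
#' @export
feature_graph <- function(n_features, edges = NULL) {
  if (length(n_features) != 1L || !is.finite(n_features) || n_features < 1 ||
      n_features != round(n_features)) {
    stop("`n_features` must be a single positive integer")
  }
  n_features <- as.integer(n_features)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have two columns")
    storage.mode(edges) <- "integer"
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_features)) {
      stop("edge indices must lie in [1, n_features]")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  structure(list(n_features = n_features, edges = edges),
            class = "feature_graph")
}

#' Complete graph over p features
#'
#' @param p number of features.
#' @return A `feature_graph` with all p(p-1)/2 edges.
#' @export
complete_graph <- function(p) {
  p <- as.integer(p)
  if (p < 2L) return(feature_graph(max(p, 1L)))
  idx <- utils::combn(p, 2L)
  feature_graph(p, t(idx))
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("feature_graph: %d features, %d edges\n",
              x$n_features, nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a feature graph
#' @param graph a `feature_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

is_feature_graph <- function(x) inherits(x, "feature_graph")

stopifnot_graph <- function(graph) {
  if (!is_feature_graph(graph)) stop("expected a `feature_graph` object")
  invisible(graph)
}
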