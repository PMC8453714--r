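# Minimum spanning tree topology.
#
# Following the MEG-MST convention, the "minimum" spanning tree of a
# similarity (PLM) matrix is the tree retaining the strongest connections,
# i.e. the maximum-weight spanning tree (equivalently the MST of the
# reciprocal weights); the selected edge set is identical either way.
# Kruskal's algorithm with deterministic tie-breaking (descending weight,
# then lexicographic node-pair order) guarantees reproducible trees.

#' Spanning tree from a connectivity matrix
#'
#' Kruskal's algorithm on edges sorted by descending weight; ties broken by
#' lexicographic node-pair order. A node whose off-diagonal weights are all
#' zero makes the support disconnected and raises an error naming it.
#'
#' @param matrix a \code{connectivity_matrix} or a plain symmetric
#'   nonnegative numeric matrix.
#' @param weight_transform \code{"negate"} (default; edge weights reported
#'   as the original similarities) or \code{"reciprocal"} (edge weights
#'   reported as 1/similarity distances). The edge set is identical.
#' @return object of class \code{spanning_tree}: \code{n_nodes},
#'   \code{labels}, and an \code{edges} data.frame (\code{i}, \code{j},
#'   \code{weight}) with exactly n_nodes - 1 rows.
#' @export
max_spanning_tree <- function(matrix, weight_transform = c("negate", "reciprocal")) {
  weight_transform <- match.arg(weight_transform)
  labels <- NULL
  if (inherits(matrix, "connectivity_matrix")) {
    labels <- matrix$roi_labels
    matrix <- matrix$values
  }
  n <- nrow(matrix)
  if (is.null(labels)) labels <- rownames(matrix)
  if (n < 2 || ncol(matrix) != n) stop("need a square matrix with N >= 2")
  if (max(abs(matrix - t(matrix))) > 1e-9 * max(1, max(abs(matrix)))) {
    stop("connectivity matrix must be symmetric")
  }
  if (any(matrix < 0)) stop("connectivity weights must be nonnegative")
  off <- matrix
  diag(off) <- 0
  dead <- which(rowSums(off) == 0)
  if (length(dead)) {
    nm <- if (!is.null(labels)) labels[dead[1]] else dead[1]
    stop("node with all-zero weights disconnects the support: ", nm)
  }
  pairs <- which(upper.tri(matrix), arr.ind = TRUE)
  w <- matrix[pairs]
  keep <- w > 0
  pairs <- pairs[keep, , drop = FALSE]
  w <- w[keep]
  ord <- order(-w, pairs[, 1], pairs[, 2])

  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  ei <- ej <- integer(n - 1)
  ew <- numeric(n - 1)
  m <- 0L
  for (k in ord) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) {
      parent[a] <- b
      m <- m + 1L
      ei[m] <- pairs[k, 1]; ej[m] <- pairs[k, 2]; ew[m] <- w[k]
      if (m == n - 1L) break
    }
  }
  if (m < n - 1L) stop("connectivity support is disconnected")
  if (weight_transform == "reciprocal") ew <- 1 / ew
  structure(list(n_nodes = n, labels = labels,
                 edges = data.frame(i = ei, j = ej, weight = ew)),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("spanning_tree: %d nodes, %d edges, total weight %.4f\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  n <- tree$n_nodes
  e <- tree$edges
  if (nrow(e) != n - 1) stop("a spanning tree of N nodes has N-1 edges")
  if (any(e$i < 1 | e$i > n | e$j < 1 | e$j > n)) stop("edge index out of range")
  invisible(tree)
}

tree_adjacency <- function(tree) {
  adj <- vector("list", tree$n_nodes)
  for (k in seq_len(nrow(tree$edges))) {
    i <- tree$edges$i[k]; j <- tree$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Node degrees of a tree
#' @param tree a \code{spanning_tree}.
#' @return integer vector of node degrees (sums to 2(N-1)).
#' @export
tree_degrees <- function(tree) {
  validate_tree(tree)
  tabulate(c(tree$edges$i, tree$edges$j), nbins = tree$n_nodes)
}

#' Leaf fraction of a tree
#'
#' Fraction of nodes with degree 1; a higher value indicates a more
#' integrated, star-like tree.
#'
#' @param tree a \code{spanning_tree}.
#' @param denominator \code{"n"} (literal fraction of nodes, default) or
#'   \code{"m"} (per-link normalization, M = N-1).
#' @return scalar.
#' @export
leaf_fraction <- function(tree, denominator = c("n", "m")) {
  denominator <- match.arg(denominator)
  deg <- tree_degrees(tree)
  den <- if (denominator == "n") tree$n_nodes else tree$n_nodes - 1
  sum(deg == 1) / den
}

#' Degree divergence of a tree
#'
#' The ratio of the second to the first raw moment of the degree
#' distribution, K = <k^2>/<k>; an index of the broadness of the degree
#' distribution and of resilience against targeted attacks.
#'
#' @param tree a \code{spanning_tree}.
#' @return scalar >= mean degree.
#' @export
degree_divergence <- function(tree) {
  deg <- tree_degrees(tree)
  mean(deg^2) / mean(deg)
}

#' Betweenness centrality on a tree
#'
#' For each node, the fraction of unordered pairs of other nodes whose
#' unique tree path passes through it, normalized by (N-1)(N-2)/2. Exact:
#' removing node v splits the tree into components of sizes c_1..c_d, and
#' the number of paths through v is ((N-1)^2 - sum c_k^2)/2.
#'
#' @param tree a \code{spanning_tree}.
#' @return numeric vector in [0, 1]; leaves score 0.
#' @export
tree_betweenness <- function(tree) {
  validate_tree(tree)
  n <- tree$n_nodes
  if (n < 3) return(numeric(n))
  adj <- tree_adjacency(tree)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    # sizes of the components hanging off each neighbour of v
    comp_sq <- 0
    for (nb in adj[[v]]) {
      # BFS from nb avoiding v
      seen <- logical(n)
      seen[v] <- TRUE
      seen[nb] <- TRUE
      queue <- nb
      size <- 1L
      while (length(queue)) {
        u <- queue[[1]]
        queue <- queue[-1]
        for (w in adj[[u]]) {
          if (!seen[w]) {
            seen[w] <- TRUE
            queue <- c(queue, w)
            size <- size + 1L
          }
        }
      }
      comp_sq <- comp_sq + as.numeric(size)^2
    }
    bc[v] <- ((n - 1)^2 - comp_sq) / 2
  }
  bc / ((n - 1) * (n - 2) / 2)
}

#' Tree hierarchy
#'
#' Trade-off between network integration and hub overload. The default is
#' the normalized form Th = L / (2 M BCmax) with L the leaf count,
#' M = N - 1 links and BCmax the maximum normalized betweenness, which
#' guarantees Th <= 1; \code{formula = "literal"} gives the unnormalized
#' ratio L / BCmax.
#'
#' @param tree a \code{spanning_tree}.
#' @param formula \code{"boersma"} (default) or \code{"literal"}.
#' @return scalar.
#' @export
tree_hierarchy <- function(tree, formula = c("boersma", "literal")) {
  formula <- match.arg(formula)
  validate_tree(tree)
  if (tree$n_nodes < 3) stop("tree hierarchy undefined for N < 3")
  bc_max <- max(tree_betweenness(tree))
  if (bc_max == 0) stop("maximum betweenness is zero")
  leaves <- sum(tree_degrees(tree) == 1)
  if (formula == "boersma") {
    leaves / (2 * (tree$n_nodes - 1) * bc_max)
  } else {
    leaves / bc_max
  }
}

# single-source BFS hop distances on the tree
.bfs_depths <- function(adj, n, src) {
  d <- rep.int(NA_integer_, n)
  d[src] <- 0L
  queue <- src
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.na(d[w])) {
        d[w] <- d[u] + 1L
        queue <- c(queue, w)
      }
    }
  }
  d
}

#' Diameter of a tree
#'
#' Longest shortest path in hop counts, found with the classical two-sweep
#' BFS (exact on trees).
#'
#' @param tree a \code{spanning_tree}.
#' @param normalize if TRUE, divide by the number of links M = N - 1.
#' @return integer hop count (or fraction of M when normalized).
#' @export
tree_diameter <- function(tree, normalize = FALSE) {
  validate_tree(tree)
  n <- tree$n_nodes
  if (n == 2) return(if (normalize) 1 else 1L)
  adj <- tree_adjacency(tree)
  d1 <- .bfs_depths(adj, n, 1L)
  far <- which.max(d1)
  d2 <- .bfs_depths(adj, n, far)
  dia <- max(d2)
  if (normalize) dia / (n - 1) else as.integer(dia)
}

#' All topological metrics of one tree
#' @param tree a \code{spanning_tree}.
#' @param th_formula tree-hierarchy variant, see \code{\link{tree_hierarchy}}.
#' @param lf_denominator leaf-fraction denominator, see
#'   \code{\link{leaf_fraction}}.
#' @return list with \code{leaf_fraction}, \code{degree_divergence},
#'   \code{tree_hierarchy}, \code{diameter}, \code{degree} (vector),
#'   \code{betweenness} (vector).
#' @export
mst_metrics <- function(tree, th_formula = "boersma", lf_denominator = "n") {
  validate_tree(tree)
  list(leaf_fraction = leaf_fraction(tree, lf_denominator),
       degree_divergence = degree_divergence(tree),
       tree_hierarchy = tree_hierarchy(tree, th_formula),
       diameter = tree_diameter(tree),
       degree = tree_degrees(tree),
       betweenness = tree_betweenness(tree))
}

#' Epoch-averaged topology metrics for one subject/session/band
#'
#' Builds the spanning tree of each epoch's connectivity matrix, computes
#' all metrics per epoch, and returns the arithmetic mean across epochs —
#' one set of values per subject/session/band.
#'
#' @param matrices list of \code{connectivity_matrix} objects (or plain
#'   matrices), one per epoch.
#' @param th_formula,lf_denominator passed to \code{\link{mst_metrics}}.
#' @return list as \code{\link{mst_metrics}}, averaged across epochs, plus
#'   \code{n_epochs}.
#' @export
metrics_for_band <- function(matrices, th_formula = "boersma",
                             lf_denominator = "n") {
  if (!length(matrices)) stop("need at least one epoch matrix")
  per_epoch <- lapply(matrices, function(m) {
    mst_metrics(max_spanning_tree(m), th_formula, lf_denominator)
  })
  avg <- function(field) {
    vals <- lapply(per_epoch, `[[`, field)
    Reduce(`+`, vals) / length(vals)
  }
  list(leaf_fraction = avg("leaf_fraction"),
       degree_divergence = avg("degree_divergence"),
       tree_hierarchy = avg("tree_hierarchy"),
       diameter = avg("diameter"),
       degree = avg("degree"),
       betweenness = avg("betweenness"),
       n_epochs = length(matrices))
}
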