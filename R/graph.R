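## k-nearest-neighbour similarity graph over training individuals and the
## two penalties it carries: the embedding manifold loss and the
## output-smoothness constraint.

#' Build a k-nearest-neighbour similarity graph
#'
#' Biological similarity between individuals is measured on the normalized
#' genotype features: for each node its Euclidean k-nearest neighbours are
#' connected with Gaussian-kernel weights `w_ij = exp(-d_ij^2 / (2 h^2))`,
#' the graph is symmetrized with `max(w_ij, w_ji)`, and the diagonal is
#' zero.  `h = "median"` uses the median of all kNN distances; if that
#' median is zero (duplicate rows) the smallest positive distance is used
#' instead.
#'
#' @param Xg Numeric matrix (rows = individuals, columns = genotype
#'   features), no missing values.
#' @param k Neighbours per node, `0 <= k < n`.  `k = 0` yields an empty
#'   graph.
#' @param h Kernel bandwidth, or `"median"`.
#' @return A `similarity_graph`: list with `edges` (data.frame `i`, `j`,
#'   `w`, one row per unordered pair, `i < j`), `n`, `k`, `h`.
#' @export
build_similarity <- function(Xg, k = 10, h = "median") {
  Xg <- as.matrix(Xg)
  n <- nrow(Xg)
  stop_if(anyNA(Xg), "Xg must not contain missing values")
  stop_if(k >= n, "k must be smaller than the number of rows")
  if (k == 0) {
    return(structure(list(edges = data.frame(i = integer(0), j = integer(0),
                                             w = numeric(0)),
                          n = n, k = 0L, h = NA_real_),
                     class = "similarity_graph"))
  }
  D <- as.matrix(stats::dist(Xg))
  ## k nearest neighbours per node (excluding self), stable in index order
  nbr <- t(apply(D, 1, function(d) order(d)[2:(k + 1)]))
  knn_d <- D[cbind(rep(seq_len(n), k), as.vector(nbr))]
  if (identical(h, "median")) {
    h_val <- stats::median(knn_d)
    if (h_val == 0) {
      pos <- knn_d[knn_d > 0]
      if (!length(pos)) pos <- D[D > 0]
      h_val <- if (length(pos)) min(pos) else 1
    }
  } else {
    h_val <- as.numeric(h)
    stop_if(!is.finite(h_val) || h_val <= 0, "h must be a positive number")
  }
  ## undirected edge set: (i,j) kept if j is among i's neighbours or vice
  ## versa; max-symmetrization is automatic since w depends only on d_ij
  ii <- rep(seq_len(n), k); jj <- as.vector(nbr)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  w <- exp(-D[cbind(a, b)]^2 / (2 * h_val^2))
  o <- order(a, b)
  structure(list(edges = data.frame(i = a[o], j = b[o], w = w[o]),
                 n = n, k = as.integer(k), h = h_val),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", x$n, "nodes,", nrow(x$edges),
      "undirected edges (k =", x$k, ", h =", signif(x$h, 4), ")\n")
  invisible(x)
}

#' Dense weight matrix of a similarity graph
#' @param graph A `similarity_graph`.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
graph_matrix <- function(graph) {
  C <- matrix(0, graph$n, graph$n)
  e <- graph$edges
  C[cbind(e$i, e$j)] <- e$w
  C[cbind(e$j, e$i)] <- e$w
  C
}

## subgraph induced on a set of node indices, relabelled 1..length(nodes)
induce_subgraph <- function(graph, nodes) {
  e <- graph$edges
  keep <- e$i %in% nodes & e$j %in% nodes
  map <- match(seq_len(graph$n), nodes)
  structure(list(edges = data.frame(i = map[e$i[keep]], j = map[e$j[keep]],
                                    w = e$w[keep]),
                 n = length(nodes), k = graph$k, h = graph$h),
            class = "similarity_graph")
}

#' Manifold regularization loss
#'
#' `sum_{i,j} ||Z_i - Z_j||^2 C_ij` over ordered pairs (both `(i,j)` and
#' `(j,i)` contribute), divided by the number of ordered edges for scale
#' stability.  Zero when all embeddings coincide or the graph is empty.
#'
#' @param Z Numeric matrix of embeddings, rows aligned to graph nodes.
#' @param graph A `similarity_graph` with `graph$n == nrow(Z)`.
#' @param normalize Divide by the ordered-edge count (default `TRUE`).
#' @return Nonnegative scalar.
#' @export
manifold_loss <- function(Z, graph, normalize = TRUE) {
  Z <- as.matrix(Z)
  stop_if(nrow(Z) != graph$n, "Z rows must match graph nodes")
  e <- graph$edges
  if (!nrow(e)) return(0)
  d2 <- rowSums((Z[e$i, , drop = FALSE] - Z[e$j, , drop = FALSE])^2)
  s <- 2 * sum(e$w * d2)            # ordered pairs: each edge counted twice
  if (normalize) s / (2 * nrow(e)) else s
}

## gradient of the (normalized) manifold loss w.r.t. Z
manifold_loss_grad <- function(Z, graph, normalize = TRUE) {
  G <- matrix(0, nrow(Z), ncol(Z))
  e <- graph$edges
  if (!nrow(e)) return(G)
  scale <- if (normalize) 1 / (2 * nrow(e)) else 1
  diff <- Z[e$i, , drop = FALSE] - Z[e$j, , drop = FALSE]
  contrib <- 4 * scale * e$w * diff   # d/dZ_i of 2*w*||Zi-Zj||^2
  for (col in seq_len(ncol(Z))) {
    G[, col] <- G[, col] +
      as.vector(tapply(contrib[, col], factor(e$i, levels = seq_len(graph$n)),
                       sum, default = 0)) -
      as.vector(tapply(contrib[, col], factor(e$j, levels = seq_len(graph$n)),
                       sum, default = 0))
  }
  G
}

#' Output-smoothness constraint penalty
#'
#' Weighted normalized roughness of predictions on the similarity graph:
#' `sum_{i,j} w_ij (yhat_i - yhat_j)^2 / sum_{i,j} w_ij` over ordered
#' pairs.  Zero for constant predictions; invariant to rescaling all
#' weights.
#'
#' @param yhat Numeric vector aligned to graph nodes.
#' @param graph A `similarity_graph`.
#' @return Nonnegative scalar; `0` (with a warning) on an empty graph.
#' @export
output_smoothness <- function(yhat, graph) {
  stop_if(length(yhat) != graph$n, "yhat length must match graph nodes")
  e <- graph$edges
  if (!nrow(e) || sum(e$w) == 0) {
    warning("empty similarity graph: smoothness penalty is 0")
    return(0)
  }
  sum(e$w * (yhat[e$i] - yhat[e$j])^2) / sum(e$w)
}

## gradient of output_smoothness w.r.t. yhat
output_smoothness_grad <- function(yhat, graph) {
  g <- numeric(graph$n)
  e <- graph$edges
  if (!nrow(e) || sum(e$w) == 0) return(g)
  den <- sum(e$w)
  contrib <- 2 * e$w * (yhat[e$i] - yhat[e$j]) / den
  g <- g + as.vector(tapply(contrib, factor(e$i, levels = seq_len(graph$n)),
                            sum, default = 0))
  g - as.vector(tapply(contrib, factor(e$j, levels = seq_len(graph$n)),
                       sum, default = 0))
}

#' Write / read a similarity graph as text
#'
#' Edges as a 3-column TSV (`i`, `j`, `w`) plus a JSON sidecar holding
#' `k`, `h` and `n`.
#'
#' @param graph A `similarity_graph`.
#' @param path Path of the edge TSV; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(n = graph$n, k = graph$k, h = graph$h),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  e <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  structure(list(edges = e, n = meta$n, k = meta$k, h = meta$h),
            class = "similarity_graph")
}
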