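#' Proportional (density) thresholding of a connectivity matrix
#'
#' Retains exactly `round_half_up(T * N * (N - 1))` strongest off-diagonal
#' entries as directed edges, where `T` is the desired connection density
#' (ratio of retained to possible directed connections). Ties at the cut are
#' broken deterministically by ascending (row, column) index; self-loops are
#' never retained.
#'
#' Adjacency orientation matches PDC semantics: entry `(i, j) = 1` means an
#' edge from source `j` to target `i`.
#'
#' @param conn a `band_connectivity` or nonnegative numeric matrix (target x
#'   source) with zero diagonal.
#' @param T connection density in `(0, 1]`.
#' @return Object of class `directed_graph`: binary `adjacency`,
#'   `node_labels`, `threshold_T`, `n_edges`.
#' @export
threshold_proportional <- function(conn, T) {
  w <- if (inherits(conn, "band_connectivity")) conn$matrix else conn
  w <- as.matrix(w)
  if (!is.numeric(T) || length(T) != 1 || T <= 0 || T > 1)
    stop("threshold T must lie in (0, 1]")
  if (any(w < 0)) stop("connectivity must be nonnegative")
  n <- nrow(w)
  stopifnot(n == ncol(w))
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("N", seq_len(n))
  k <- floor(T * n * (n - 1) + 0.5)                       # round half up
  off <- which(row(w) != col(w))
  ord <- off[order(-w[off], row(w)[off], col(w)[off])]
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  adj[ord[seq_len(k)]] <- 1L
  structure(list(adjacency = adj, node_labels = labels,
                 threshold_T = T, n_edges = k),
            class = "directed_graph")
}

#' @export
print.directed_graph <- function(x, ...) {
  cat(sprintf("<directed_graph> %d nodes, %d edges (T = %g)\n",
              length(x$node_labels), x$n_edges, x$threshold_T))
  invisible(x)
}

#' Threshold sweep over a density grid
#'
#' @param conn as in [threshold_proportional()].
#' @param t_min,t_max,step density grid (defaults 0.1-0.9 in steps of 0.05,
#'   inclusive endpoints: 17 graphs).
#' @return Named list of `directed_graph`s, one per grid value.
#' @export
sweep_thresholds <- function(conn, t_min = 0.1, t_max = 0.9, step = 0.05) {
  stopifnot(t_min <= t_max, step > 0)
  grid <- round(seq(t_min, t_max + step / 4, by = step), 10)
  grid <- grid[grid <= t_max + 1e-9]
  out <- lapply(grid, function(T) threshold_proportional(conn, T))
  names(out) <- format(grid)
  out
}

#' In- and out-degrees of a directed graph
#'
#' Under the source-to-target orientation (entry `(i, j)` = edge `j -> i`),
#' the in-degree of node `i` is its row sum and the out-degree of node `j`
#' its column sum. A high in-degree marks a region influenced by many
#' others; a high out-degree marks a region with many functional targets.
#'
#' @param g a `directed_graph`.
#' @return List with integer vectors `in_degree` and `out_degree`.
#' @export
degrees <- function(g) {
  a <- g$adjacency
  list(in_degree = as.integer(rowSums(a)),
       out_degree = as.integer(colSums(a)))
}

#' Normalized degree histogram
#'
#' Integer bins `0..N-1`; bar `k` is the count of nodes with degree `k`
#' divided by the number of network nodes, so the bars sum to 1.
#'
#' @param degs integer degrees, one per node.
#' @param N number of nodes (>= 1).
#' @return Named numeric vector of length `N` (names `"0".."N-1"`).
#' @export
degree_distribution <- function(degs, N) {
  stopifnot(N >= 1, length(degs) == N)
  tab <- tabulate(degs + 1L, nbins = N)
  stats::setNames(tab / N, as.character(0:(N - 1L)))
}

#' Directed shortest-path lengths in hops
#'
#' Breadth-first distances respecting edge direction; `d[i, j]` is the
#' length of the shortest directed path from `i` to `j`, `Inf` when `j` is
#' unreachable from `i`, and 0 on the diagonal.
#'
#' @param g a `directed_graph` or binary adjacency matrix in the `(target,
#'   source)` orientation.
#' @return Numeric matrix of distances.
#' @export
shortest_path_lengths <- function(g) {
  a <- if (inherits(g, "directed_graph")) g$adjacency else g
  # igraph expects adjacency[i, j] = edge i -> j; ours is j -> i
  ig <- igraph::graph_from_adjacency_matrix(t(a != 0) * 1, mode = "directed")
  d <- igraph::distances(ig, mode = "out")
  dimnames(d) <- dimnames(a)
  d
}

#' Global efficiency of a directed binary graph
#'
#' \deqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{d_{ij}}}
#' where unreachable pairs (`d = Inf`) contribute 0. Always in `[0, 1]`;
#' equals 1 for the complete directed graph and 0 for the empty one.
#'
#' @param g a `directed_graph` or binary adjacency matrix.
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  a <- if (inherits(g, "directed_graph")) g$adjacency else g
  n <- nrow(a)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(a)
  e <- 1 / d
  e[!is.finite(e)] <- 0
  diag(e) <- 0
  sum(e) / (n * (n - 1))
}

#' Local efficiency of a directed binary graph
#'
#' For each node `i`, take the sub-graph induced on its neighborhood (every
#' node connected to `i` by an edge in either direction, excluding `i`),
#' compute that sub-graph's global efficiency (0 when the neighborhood has
#' fewer than 2 nodes), and average over nodes. A fault-tolerance index: how
#' well the neighbors of `i` communicate once `i` is removed.
#'
#' @param g a `directed_graph` or binary adjacency matrix.
#' @return A number in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  a <- if (inherits(g, "directed_graph")) g$adjacency else g
  n <- nrow(a)
  if (n < 2) stop("local efficiency needs at least 2 nodes")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which((a[i, ] != 0 | a[, i] != 0) & seq_len(n) != i)
    if (length(nb) < 2) return(0)
    global_efficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Degree and efficiency report for one graph
#'
#' @param g a `directed_graph`.
#' @param band,condition,subject_id metadata carried into the report.
#' @return Object of class `efficiency_report`: degrees, normalized degree
#'   histograms, `e_glob`, `e_loc` and the metadata.
#' @export
efficiency_report <- function(g, band = NA_character_,
                              condition = NA_character_,
                              subject_id = NA_character_) {
  dg <- degrees(g)
  n <- length(g$node_labels)
  structure(list(in_degree = dg$in_degree, out_degree = dg$out_degree,
                 degree_hist_in = degree_distribution(dg$in_degree, n),
                 degree_hist_out = degree_distribution(dg$out_degree, n),
                 e_glob = global_efficiency(g), e_loc = local_efficiency(g),
                 threshold_T = g$threshold_T, band = band,
                 condition = condition, subject_id = subject_id),
            class = "efficiency_report")
}

#' Write a graph as TSV adjacency and directed edge list
#'
#' @param g a `directed_graph`.
#' @param path output TSV path for the adjacency; the edge list goes to
#'   `<path base>_edges.tsv` with columns `source`, `target`.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  adj <- as.data.frame(g$adjacency)
  utils::write.table(cbind(node = g$node_labels, adj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  idx <- which(g$adjacency == 1L, arr.ind = TRUE)
  edges <- data.frame(source = g$node_labels[idx[, "col"]],
                      target = g$node_labels[idx[, "row"]])
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  utils::write.table(edges, sub("\\.tsv$", "_edges.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
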