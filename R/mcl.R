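#' Markov Clustering (MCL) of a filtered TF graph
#'
#' Native implementation of Van Dongen's Markov Clustering Algorithm.  Edge
#' weights are treated as flow capacities of a random walk; the column
#' stochastic transition matrix is alternately *expanded* (squared),
#' *inflated* (entrywise power `inflation`, then column renormalization) and
#' *pruned* (entries below `prune_below` zeroed, then renormalized) until the
#' matrix stops changing.  Clusters are read off the converged matrix as
#' connected components of its nonzero support; singleton components (and
#' nodes with no incident edges) are reported as unclustered, so every
#' returned cluster has at least 2 members.
#'
#' Self-loop edges surviving the FPR filter are kept as data-derived flow;
#' nodes whose self-loop was filtered out get a self-loop added at the
#' node's maximum incident edge weight (the weighted-graph analogue of the
#' standard unit-loop initialization, which would otherwise swamp small
#' data weights).  Isolated nodes get a unit loop and become absorbing
#' singleton states.
#'
#' @param graph a [filter_graph()] result, or a symmetric non-negative
#'   numeric matrix (dimnames used as node names).
#' @param inflation granularity parameter, > 1; effective range is roughly
#'   2-5 (default 2.5).  Larger values give finer clusters.
#' @param prune_below flow values below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter iteration cap (default 100); non-convergence returns the
#'   current partition with `converged = FALSE` and a warning.
#' @return Object of class `tf_clustering`: list with `clusters` (list of
#'   member-name character vectors, decreasing size), `unclustered`
#'   (character vector), `inflation`, `n_iterations`, `converged`,
#'   `tf_names`, and `flow` (the converged column-stochastic matrix).
#' @examples
#' W <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
#' W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
#' cl <- mcl_cluster(W, inflation = 2)
#' length(cl$clusters)  # 2
#' @export
mcl_cluster <- function(graph, inflation = 2.5, prune_below = 1e-5,
                        max_iter = 100L) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (inherits(graph, "filtered_graph")) {
    W <- .filtered_adjacency(graph)
  } else if (is.matrix(graph)) {
    W <- graph
    if (is.null(rownames(W)))
      dimnames(W) <- rep(list(paste0("V", seq_len(nrow(W)))), 2)
    if (!isSymmetric(unname(W))) stop("matrix input must be symmetric")
  } else stop("graph must be a filtered_graph or a matrix")
  if (any(W < 0))
    stop("negative edge weights present; apply FPR filtering (filter_graph) ",
         "with a non-negative threshold before clustering")
  tf_names <- rownames(W)
  n <- nrow(W)
  # Nodes whose self-loop did not survive get one added so the walk can
  # rest in place.  On a weighted graph a unit loop would swamp the data
  # weights, so the added loop matches the node's maximum incident weight
  # (isolated nodes get 1, making them absorbing singletons).
  d <- diag(W)
  mx <- apply(W, 2, max)
  diag(W) <- ifelse(d > 0, d, ifelse(mx > 0, mx, 1))
  M <- sweep(W, 2, colSums(W), "/")
  converged <- FALSE
  it <- 0L
  tol <- 1e-8
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < prune_below] <- 0           # pruning
    cs <- colSums(M2)
    if (any(cs == 0)) {                 # keep columns stochastic: restore max
      for (j in which(cs == 0)) M2[which.max(M[, j]), j] <- 1
      cs <- colSums(M2)
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  # components of the symmetrized nonzero support
  support <- (M > 0) | (t(M) > 0)
  diag(support) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(tf_names, comp)
  sizes <- lengths(groups)
  clusters <- groups[sizes >= 2]
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[[`, "", 1L))
  clusters <- unname(clusters[ord])
  unclustered <- sort(unlist(groups[sizes < 2], use.names = FALSE))
  if (is.null(unclustered)) unclustered <- character(0)
  structure(list(clusters = clusters, unclustered = unclustered,
                 inflation = inflation, n_iterations = it,
                 converged = converged, tf_names = tf_names, flow = M),
            class = "tf_clustering")
}

#' @export
print.tf_clustering <- function(x, ...) {
  cat(sprintf("MCL clustering: %d clusters over %d TFs (%d unclustered), inflation %g\n",
              length(x$clusters), length(x$tf_names),
              length(x$unclustered), x$inflation))
  if (length(x$clusters))
    cat(sprintf("  cluster sizes: %s\n",
                paste(lengths(x$clusters), collapse = ", ")))
  cat(sprintf("  %sconverged in %d iterations\n",
              if (x$converged) "" else "NOT ", x$n_iterations))
  invisible(x)
}

#' Cluster-level summary metrics
#'
#' The per-run metrics used to compare clusterings across FPR levels:
#' node/edge counts, filtering percentage, number of clusters, median and
#' maximum cluster size, and the percentage of unclustered TFs.
#'
#' @param clustering a [mcl_cluster()] result.
#' @param filtered the [filter_graph()] result it was computed from.
#' @return Object of class `cluster_metrics` (also a one-row data.frame)
#'   with columns `n_nodes`, `n_edges_filtered`, `pct_edges_filtered`,
#'   `n_clusters`, `median_nodes_per_cluster`, `max_nodes_per_cluster`,
#'   `unclustered_pct`.
#' @export
cluster_metrics <- function(clustering, filtered) {
  stopifnot(inherits(clustering, "tf_clustering"),
            inherits(filtered, "filtered_graph"))
  sizes <- lengths(clustering$clusters)
  n <- length(clustering$tf_names)
  out <- data.frame(
    n_nodes = n,
    n_edges_filtered = filtered$n_filtered,
    pct_edges_filtered = filtered$pct_filtered,
    n_clusters = length(sizes),
    median_nodes_per_cluster = if (length(sizes)) stats::median(sizes) else NA_real_,
    max_nodes_per_cluster = if (length(sizes)) max(sizes) else NA_integer_,
    unclustered_pct = 100 * length(clustering$unclustered) / n
  )
  class(out) <- c("cluster_metrics", "data.frame")
  out
}

#' Sweep the MCL inflation (granularity) parameter
#'
#' Runs [mcl_cluster()] at each inflation value and tabulates
#' [cluster_metrics()], to support choosing the granularity empirically from
#' the number and size of clusters produced.
#'
#' @param filtered a [filter_graph()] result.
#' @param grid numeric vector of inflation values (default `c(2, 3, 4, 5)`).
#' @param ... passed to [mcl_cluster()].
#' @return data.frame with one metrics row per inflation value.
#' @export
sweep_inflation <- function(filtered, grid = c(2, 3, 4, 5), ...) {
  stopifnot(length(grid) >= 1)
  rows <- lapply(grid, function(i) {
    cl <- mcl_cluster(filtered, inflation = i, ...)
    cbind(inflation = i, as.data.frame(cluster_metrics(cl, filtered)))
  })
  do.call(rbind, rows)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, ~0 for independent ones.  Used to score recovery of
#' planted clusters.
#'
#' @param a,b vectors of cluster labels (same length, any label type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

#' Cluster labels of a clustering, as a named vector
#'
#' Unclustered TFs each receive their own singleton label.
#'
#' @param clustering a [mcl_cluster()] result.
#' @return Named character vector mapping TF name to cluster label.
#' @export
cluster_labels <- function(clustering) {
  stopifnot(inherits(clustering, "tf_clustering"))
  lab <- character(0)
  for (k in seq_along(clustering$clusters)) {
    members <- clustering$clusters[[k]]
    lab[members] <- paste0("cluster", k)
  }
  for (u in clustering$unclustered) lab[u] <- paste0("singleton_", u)
  lab[clustering$tf_names]
}
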