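#' Per-TF binary co-occurrence matrix
#'
#' For a focal TF t with sites \eqn{B_t = (b_1, ..., b_m)}, the co-occurrence
#' matrix \eqn{M_t} is the n-by-m binary matrix (n = number of TFs, rows in
#' `tf_names` order) with entry (i, j) = 1 iff TF i has at least one site
#' intersecting site j extended by `window_bp` base pairs on each side.  The
#' focal site is excluded from its own neighborhood, so the diagonal row is
#' not trivially 1; other sites of the same TF do count, which is what gives
#' the graph informative self-loop weights.
#'
#' @param collection a [tfbs_collection()].
#' @param tf focal TF identifier.
#' @param window_bp proximity window radius in bp (default 1000).
#' @return Binary integer matrix, rownames = all TF names, one column per
#'   site of `tf` (in sorted site order).
#' @export
cooccurrence_matrix <- function(collection, tf, window_bp = 1000) {
  stopifnot(inherits(collection, "tfbs_collection"))
  if (!tf %in% collection$tf_names) stop("unknown TF: ", tf)
  rec <- collection$records
  focal_idx <- which(rec$tf == tf)
  hits <- .site_hits(rec, window_bp)
  hits <- hits[hits$focal %in% focal_idx, , drop = FALSE]
  n <- length(collection$tf_names)
  m <- length(focal_idx)
  M <- matrix(0L, n, m,
              dimnames = list(collection$tf_names, NULL))
  if (nrow(hits)) {
    col <- match(hits$focal, focal_idx)
    row <- match(rec$tf[hits$hit], collection$tf_names)
    M[cbind(row, col)] <- 1L
  }
  attr(M, "tf") <- tf
  M
}

#' Co-occurrence frequency vector
#'
#' Row means of a TF's binary co-occurrence matrix: entry i is the fraction
#' of the focal TF's sites at which TF i was found within the window.
#'
#' @param M matrix from [cooccurrence_matrix()].
#' @return Named numeric vector in `[0, 1]`, one entry per TF.
#' @export
frequency_vector <- function(M) {
  stopifnot(is.matrix(M))
  if (ncol(M) < 1) stop("frequency undefined for a TF with zero sites")
  rowMeans(M)
}

#' Background (overall) binding-frequency vector
#'
#' The row mean of all per-TF co-occurrence matrices concatenated
#' horizontally: entry i is the fraction of *all* sites in the dataset at
#' which TF i was found within the window, i.e. the genome-wide windowed
#' binding prevalence of TF i.  Equivalently, the site-count-weighted mean of
#' the per-TF frequency vectors.
#'
#' @param matrices list of matrices from [cooccurrence_matrix()], covering
#'   every TF.
#' @return Named numeric vector in `[0, 1]`.
#' @export
background_vector <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) > 0)
  w <- sum(vapply(matrices, ncol, integer(1)))
  if (w == 0) stop("background undefined: collection has no sites")
  tot <- Reduce(`+`, lapply(matrices, rowSums))
  tot / w
}

#' Normalize a frequency vector against the background
#'
#' Subtracts the background prevalence from the co-occurrence frequencies, so
#' that each entry reflects the magnitude of the pairwise association rather
#' than how often the partner TF binds anywhere.  Subtraction (rather than
#' division) penalizes all TFs evenly and permits negative values, which the
#' TFBS scoring stage exploits as evidence *against* a putative site.
#'
#' @param f frequency vector from [frequency_vector()].
#' @param f_all background vector from [background_vector()].
#' @return Numeric vector in `[-1, 1]`.
#' @export
normalize_frequencies <- function(f, f_all) {
  if (length(f) != length(f_all)) stop("length mismatch between f and f_all")
  f - f_all
}

#' Build the TF co-occurrence graph
#'
#' End-to-end construction: per-TF co-occurrence counts, frequency vectors
#' \eqn{f_t}, background vector \eqn{f_{all}}, normalized vectors
#' \eqn{f'_t = f_t - f_{all}} assembled column-wise into the directed
#' adjacency matrix A, and the symmetric edge-weight matrix
#' \eqn{W = (A + A^T)/2} of the undirected graph.  The graph is complete:
#' every unordered TF pair (self-loops included) carries a signed weight, so
#' a graph over n TFs has n(n+1)/2 undirected edges until filtering.
#'
#' @param collection a [tfbs_collection()] with at least 2 TFs.
#' @param window_bp proximity window radius in bp (default 1000).
#' @return Object of class `cooc_graph`: list with `tf_names`, `A` (directed,
#'   column t = \eqn{f'_t}), `W` (symmetric), `f_all`, `m`, `w`, `window_bp`.
#' @examples
#' x <- generate_null(n_tfs = 5, sites_per_tf = 20,
#'                    genome_length = 1e6, seed = 1)
#' g <- build_graph(x)
#' n_edges(g)  # 15 = 5*6/2
#' @export
build_graph <- function(collection, window_bp = 1000) {
  stopifnot(inherits(collection, "tfbs_collection"))
  tf_names <- collection$tf_names
  n <- length(tf_names)
  if (n < 2) stop("need at least 2 TFs to build a graph")
  rec <- collection$records
  hits <- .site_hits(rec, window_bp)
  # C[i, t] = number of sites of TF t having >= 1 site of TF i in-window
  C <- matrix(0, n, n, dimnames = list(tf_names, tf_names))
  if (nrow(hits)) {
    hit_tf <- match(rec$tf[hits$hit], tf_names)
    key <- paste(hits$focal, hit_tf)        # unique (site, neighbor-TF)
    dup <- duplicated(key)
    focal_tf <- match(rec$tf[hits$focal[!dup]], tf_names)
    tab <- table(factor(hit_tf[!dup], levels = seq_len(n)),
                 factor(focal_tf, levels = seq_len(n)))
    C <- C + as.matrix(tab)
  }
  m <- collection$m[tf_names]
  Fmat <- sweep(C, 2, m, "/")              # column t = f_t
  f_all <- rowSums(C) / collection$w
  A <- Fmat - f_all                        # recycles down columns: f_t - f_all
  W <- (A + t(A)) / 2
  structure(
    list(tf_names = tf_names, A = A, W = W, f_all = f_all, m = m,
         w = collection$w, window_bp = window_bp),
    class = "cooc_graph"
  )
}

#' Number of undirected edges (self-loops included)
#'
#' The unfiltered graph is complete over its n TF nodes, so it has
#' n(n+1)/2 undirected edges counting self-loops.
#'
#' @param graph a `cooc_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "cooc_graph"))
  n <- length(graph$tf_names)
  n * (n + 1L) / 2L
}

#' @export
print.cooc_graph <- function(x, ...) {
  n <- length(x$tf_names)
  cat(sprintf("TF co-occurrence graph: %d nodes, %d undirected edges (incl. self-loops)\n",
              n, n_edges(x)))
  cat(sprintf("  window: %g bp; built from %d sites\n", x$window_bp, x$w))
  cat(sprintf("  edge weights: [%.4f, %.4f]\n", min(x$W), max(x$W)))
  invisible(x)
}

#' @export
summary.cooc_graph <- function(object, ...) {
  w <- object$W[upper.tri(object$W, diag = TRUE)]
  out <- list(n_nodes = length(object$tf_names), n_edges = n_edges(object),
              window_bp = object$window_bp, n_sites = object$w,
              weight_quantiles = stats::quantile(w, c(0, .25, .5, .75, 1)),
              n_negative = sum(w < 0))
  class(out) <- "summary.cooc_graph"
  out
}

#' @export
print.summary.cooc_graph <- function(x, ...) {
  cat(sprintf("TF co-occurrence graph: %d nodes, %d edges, window %g bp\n",
              x$n_nodes, x$n_edges, x$window_bp))
  cat(sprintf("  %d negative-weight edges\n", x$n_negative))
  print(round(x$weight_quantiles, 4))
  invisible(x)
}

# Undirected edge table of a complete graph: upper triangle incl. diagonal,
# lexicographic in (tf1, tf2).
.edge_table <- function(graph) {
  n <- length(graph$tf_names)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(tf1 = graph$tf_names[ij[, 1]],
             tf2 = graph$tf_names[ij[, 2]],
             weight = graph$W[ij],
             stringsAsFactors = FALSE)
}
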