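#' Permutation null pool of dummy edge weights
#'
#' Generates the empirical null distribution used to calibrate the edge
#' weight threshold.  Per repeat, every TF's co-occurrence matrix is replaced
#' by a dummy n-by-m_t matrix whose row i is i.i.d. Bernoulli with success
#' probability `f_all[i]` — the TF's genome-wide windowed prevalence — so the
#' overall abundance of each TF is preserved while its placement relative to
#' other TFs is destroyed.  The full adjacency construction is then rerun on
#' the dummy matrices (including recomputing the background vector from
#' them), and all n^2 directed entries of the dummy A are pooled.  Only the
#' row sums of each dummy matrix enter the construction, so each row sum is
#' drawn directly as a Binomial(m_t, f_all\[i\]) count, which is
#' distributionally identical to summing the Bernoulli entries.
#'
#' @param graph a [build_graph()] result (carries `f_all`, per-TF site
#'   counts and the total site count of the collection it was built from).
#' @param n_reps number of permutation repeats (default 25).
#' @param seed RNG seed; recorded in the result.  The global RNG state is
#'   left untouched.
#' @return Object of class `dummy_pool`: list with `weights` (numeric,
#'   length `n_reps * n^2`), `n_reps`, `n`, `seed`.
#' @export
dummy_pool <- function(graph, n_reps = 25L, seed = NULL) {
  stopifnot(inherits(graph, "cooc_graph"), n_reps >= 1)
  n <- length(graph$tf_names)
  m <- graph$m
  w <- graph$w
  f_all <- graph$f_all
  draw <- function() {
    out <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      # C[i, t] ~ Binomial(m_t, f_all[i]): dummy row sums
      C <- matrix(stats::rbinom(n * n, size = rep(m, each = n),
                                prob = rep_len(f_all, n * n)),
                  n, n)
      Fmat <- sweep(C, 2, m, "/")
      f_all_dummy <- rowSums(C) / w
      out[[r]] <- as.numeric(Fmat - f_all_dummy)
    }
    unlist(out)
  }
  weights <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(weights = weights, n_reps = as.integer(n_reps), n = n,
                 seed = seed),
            class = "dummy_pool")
}

#' @export
print.dummy_pool <- function(x, ...) {
  cat(sprintf("Dummy edge-weight pool: %d weights (%d repeats x %d^2 TFs)\n",
              length(x$weights), x$n_reps, x$n))
  if (!is.null(x$seed)) cat(sprintf("  seed: %s\n", format(x$seed)))
  cat(sprintf("  range: [%.4f, %.4f]\n", min(x$weights), max(x$weights)))
  invisible(x)
}

#' @export
plot.dummy_pool <- function(x, ...) {
  graphics::hist(x$weights, breaks = 100,
                 main = "Permutation null edge weights",
                 xlab = "dummy edge weight", ...)
}

#' Edge-weight threshold for a target false-positive rate
#'
#' A dummy edge with weight strictly greater than the threshold counts as a
#' false positive; one with lower weight is a true negative.  The returned
#' threshold is the smallest pooled weight theta such that the fraction of
#' pooled weights exceeding theta is at most `fpr`; the achieved FPR is
#' reported alongside (ties in the pool can make it smaller than the target).
#'
#' @param pool a [dummy_pool()].
#' @param fpr target false-positive rate in (0, 1).
#' @return Object of class `fpr_threshold`: list with `threshold`,
#'   `achieved_fpr`, `fpr_target`, `pool_size`.
#' @export
threshold_for_fpr <- function(pool, fpr) {
  stopifnot(inherits(pool, "dummy_pool"))
  if (!is.numeric(fpr) || length(fpr) != 1 || fpr <= 0 || fpr >= 1)
    stop("fpr must be a single value in (0, 1)")
  w <- sort(pool$weights)
  N <- length(w)
  if (!N) stop("empty pool")
  u <- unique(w)
  above <- N - findInterval(u, w)   # strict ">" count for each unique value
  ok <- which(above / N <= fpr)
  theta <- u[ok[1]]
  structure(list(threshold = theta, achieved_fpr = above[ok[1]] / N,
                 fpr_target = fpr, pool_size = N),
            class = "fpr_threshold")
}

#' @export
print.fpr_threshold <- function(x, ...) {
  cat(sprintf("FPR threshold: %.6g (target FPR %g, achieved %.4g, pool %d)\n",
              x$threshold, x$fpr_target, x$achieved_fpr, x$pool_size))
  invisible(x)
}

#' Filter graph edges below a weight threshold
#'
#' Removes every undirected edge (self-loops included) whose symmetric
#' weight is strictly below the threshold; edges exactly at the threshold
#' survive.
#'
#' @param graph a `cooc_graph`.
#' @param threshold weight cutoff, or an `fpr_threshold` object.
#' @return Object of class `filtered_graph`: list with `tf_names`, `edges`
#'   (data.frame tf1/tf2/weight of surviving unordered edges), `threshold`,
#'   `fpr_target` (if a threshold object was given), `n_filtered`,
#'   `pct_filtered`, `n_edges_total`, and `parent` (the input graph).
#' @export
filter_graph <- function(graph, threshold) {
  stopifnot(inherits(graph, "cooc_graph"))
  fpr_target <- NULL
  if (inherits(threshold, "fpr_threshold")) {
    fpr_target <- threshold$fpr_target
    threshold <- threshold$threshold
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  edges <- .edge_table(graph)
  keep <- edges$weight >= threshold
  total <- nrow(edges)
  structure(
    list(tf_names = graph$tf_names,
         edges = edges[keep, , drop = FALSE],
         threshold = threshold, fpr_target = fpr_target,
         n_filtered = sum(!keep),
         pct_filtered = 100 * sum(!keep) / total,
         n_edges_total = total,
         parent = graph),
    class = "filtered_graph"
  )
}

#' @export
print.filtered_graph <- function(x, ...) {
  cat(sprintf("Filtered TF graph: %d nodes, %d/%d edges surviving (%.1f%% filtered)\n",
              length(x$tf_names), nrow(x$edges), x$n_edges_total,
              x$pct_filtered))
  cat(sprintf("  weight threshold: %.6g%s\n", x$threshold,
              if (!is.null(x$fpr_target))
                sprintf(" (target FPR %g)", x$fpr_target) else ""))
  invisible(x)
}

# Symmetric adjacency matrix of the surviving edges (self-loops on the
# diagonal); zero elsewhere.
.filtered_adjacency <- function(x) {
  stopifnot(inherits(x, "filtered_graph"))
  n <- length(x$tf_names)
  W <- matrix(0, n, n, dimnames = list(x$tf_names, x$tf_names))
  if (nrow(x$edges)) {
    i <- match(x$edges$tf1, x$tf_names)
    j <- match(x$edges$tf2, x$tf_names)
    W[cbind(i, j)] <- x$edges$weight
    W[cbind(j, i)] <- x$edges$weight
  }
  W
}
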