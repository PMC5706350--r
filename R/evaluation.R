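#' Compare a filtered graph to reference interactions
#'
#' Restricts both the graph and the reference to the TFs they share
#' (unmatched TFs are dropped), then classifies every unordered matched-TF
#' pair (self-loops excluded): true positive if a surviving graph edge
#' coincides with a reference pair, false positive if an edge has no
#' reference support, false negative if a reference pair has no surviving
#' edge, true negative otherwise.  Precision, recall and F-score follow.
#'
#' @param filtered a [filter_graph()] result.
#' @param ref a [read_reference()] result (or an object with the same
#'   shape).
#' @return Object of class `comparison_result`: list with `tp`, `fp`, `tn`,
#'   `fn`, `precision`, `recall`, `f_score`, `n_tfs_matched`,
#'   `n_tfs_dropped`.
#' @export
compare_to_reference <- function(filtered, ref) {
  stopifnot(inherits(filtered, "filtered_graph"))
  matched <- intersect(filtered$tf_names, ref$tf_names)
  if (length(matched) < 2)
    stop("fewer than 2 graph TFs match the reference")
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  e <- filtered$edges
  e <- e[e$tf1 != e$tf2 & e$tf1 %in% matched & e$tf2 %in% matched, ,
         drop = FALSE]
  edge_keys <- pair_key(e$tf1, e$tf2)
  rp <- ref$pairs
  rp <- rp[rp$tf1 %in% matched & rp$tf2 %in% matched, , drop = FALSE]
  ref_keys <- pair_key(rp$tf1, rp$tf2)
  n <- length(matched)
  total <- n * (n - 1) / 2
  tp <- sum(edge_keys %in% ref_keys)
  fp <- length(edge_keys) - tp
  fn <- length(ref_keys) - tp
  tn <- total - tp - fp - fn
  if (tp + fp == 0) {
    warning("no predicted edges among matched TFs; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall,
                 f_score = f_score(precision, recall),
                 n_tfs_matched = n,
                 n_tfs_dropped = length(filtered$tf_names) - n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Reference comparison over %d matched TFs (%d dropped):\n",
              x$n_tfs_matched, x$n_tfs_dropped))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision %.4f  recall %.4f  F %.4f\n",
              x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Per-channel enrichment of predicted interactions
#'
#' Splits the reference pairs (restricted to TFs present in the graph) into
#' those matched by a surviving graph edge and those not, and tests with a
#' one-sided Wilcoxon rank-sum whether the matched pairs carry
#' stochastically larger scores in the given evidence channel.  Channel
#' scores are bounded, zero-inflated and far from normal, hence the rank
#' test.  If every score is tied the test carries no evidence and p = 1 is
#' reported.
#'
#' @param filtered a [filter_graph()] result.
#' @param ref a [read_reference()] result.
#' @param channel channel name (one of `ref$channel_names`).
#' @return Object of class `enrichment_result`: list with `channel`,
#'   `p_value`, `direction` (+1 if matched median exceeds unmatched, -1 if
#'   lower, 0 if equal), `n_matched`, `n_unmatched`.
#' @export
channel_enrichment <- function(filtered, ref, channel) {
  stopifnot(inherits(filtered, "filtered_graph"))
  if (!channel %in% ref$channel_names)
    stop("unknown channel: ", channel, " (have: ",
         paste(ref$channel_names, collapse = ", "), ")")
  matched_tfs <- intersect(filtered$tf_names, ref$tf_names)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  e <- filtered$edges
  e <- e[e$tf1 != e$tf2, , drop = FALSE]
  edge_keys <- pair_key(e$tf1, e$tf2)
  sel <- ref$pairs$tf1 %in% matched_tfs & ref$pairs$tf2 %in% matched_tfs
  keys <- pair_key(ref$pairs$tf1[sel], ref$pairs$tf2[sel])
  scores <- ref$channels[[channel]][sel]
  is_matched <- keys %in% edge_keys
  x <- scores[is_matched]
  y <- scores[!is_matched]
  if (!length(x) || !length(y))
    stop("cannot test enrichment: matched or unmatched group is empty")
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else {
    p <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  }
  med_diff <- stats::median(x) - stats::median(y)
  structure(list(channel = channel, p_value = p,
                 direction = sign(med_diff),
                 n_matched = length(x), n_unmatched = length(y)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Channel enrichment [%s]: p = %.4g (%s; %d matched vs %d unmatched)\n",
              x$channel, x$p_value,
              if (x$direction > 0) "matched higher"
              else if (x$direction < 0) "matched lower" else "no shift",
              x$n_matched, x$n_unmatched))
  invisible(x)
}

#' Regress co-occurrence edge weight on motif similarity
#'
#' Ordinary least squares of the undirected, signed edge weight on the PWM
#' similarity score, over the unordered TF pairs present in both the graph
#' and the similarity table.  A low R-squared indicates that proximity
#' co-occurrence carries information beyond motif similarity.
#'
#' @param graph a `cooc_graph`.
#' @param sim a [read_similarity()] result.
#' @return Object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n_pairs` and the underlying `lm` fit.
#' @export
similarity_regression <- function(graph, sim) {
  stopifnot(inherits(graph, "cooc_graph"))
  keep <- sim$tf1 %in% graph$tf_names & sim$tf2 %in% graph$tf_names &
    sim$tf1 != sim$tf2
  sim <- sim[keep, , drop = FALSE]
  if (nrow(sim) < 3)
    stop("need at least 3 TF pairs shared between graph and similarity table")
  if (stats::var(sim$similarity) == 0)
    stop("similarity scores have zero variance")
  weight <- graph$W[cbind(match(sim$tf1, graph$tf_names),
                          match(sim$tf2, graph$tf_names))]
  fit <- stats::lm(weight ~ similarity, data =
                     data.frame(weight = weight, similarity = sim$similarity))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_pairs = nrow(sim), fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Edge weight ~ motif similarity (n = %d pairs):\n", x$n_pairs))
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
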