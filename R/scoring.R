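#' Merge overlapping intervals
#'
#' Standard per-chromosome interval union: overlapping or book-ended
#' half-open intervals are condensed into one larger interval.  The result
#' is sorted and disjoint.
#'
#' @param x a `tfbs_collection` or a data.frame with columns chrom, start,
#'   end (0-based half-open).
#' @return data.frame chrom/start/end, sorted, disjoint.
#' @export
merge_overlapping <- function(x) {
  df <- if (inherits(x, "tfbs_collection")) x$records else x
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (!nrow(df))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  out <- lapply(sort(unique(df$chrom)), function(chr) {
    sel <- df$chrom == chr
    ir <- IRanges::reduce(IRanges::IRanges(start = df$start[sel] + 1L,
                                           end = df$end[sel]))
    data.frame(chrom = chr, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# For each interval in `query` (df chrom/start/end), whether its window
# (extension by window_bp on each side) intersects >= 1 interval of
# `subject`.
.window_hit <- function(query, subject, window_bp) {
  hit <- logical(nrow(query))
  if (!nrow(query) || !nrow(subject)) return(hit)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (!length(si)) next
    win <- IRanges::IRanges(start = query$start[qi] + 1L - window_bp,
                            end = query$end[qi] + window_bp)
    ir <- IRanges::IRanges(start = subject$start[si] + 1L,
                           end = subject$end[si])
    hit[qi] <- IRanges::overlapsAny(win, ir)
  }
  hit
}

#' Sum-score putative sites of a target TF
#'
#' Assigns each putative site of the target TF the signed sum of graph edge
#' weights from the target to every neighboring putative TFBS within the
#' window.  Neighbors are counted per site instance (not per distinct TF),
#' include other putative sites of the target itself (through the self-loop
#' weight), and exclude the focal site.  A site surrounded by frequently
#' co-occurring TFs scores high; negatively-weighted neighbors pull the
#' score down.  The graph must be the *unfiltered*, signed graph built from
#' the same putative collection.
#'
#' @param target TF identifier to score.
#' @param putative a [tfbs_collection()] of putative sites (all TFs).
#' @param graph [build_graph()] result on `putative` (unfiltered).
#' @param window_bp window radius in bp; defaults to the graph's window.
#' @return data.frame of class `scored_sites` with the target's site
#'   coordinates plus `sum_score`, `n_neighbors` and `normalized_score`
#'   (= sum_score / max(n_neighbors, 1), so 0 for isolated sites).
#' @export
sum_scores <- function(target, putative, graph, window_bp = graph$window_bp) {
  stopifnot(inherits(putative, "tfbs_collection"),
            inherits(graph, "cooc_graph"))
  if (!target %in% graph$tf_names) stop("target TF not in graph: ", target)
  if (!target %in% putative$tf_names)
    stop("target TF not in putative collection: ", target)
  rec <- putative$records
  focal_idx <- which(rec$tf == target)
  hits <- .site_hits(rec, window_bp)
  hits <- hits[hits$focal %in% focal_idx, , drop = FALSE]
  wrow <- graph$W[target, ]
  sum_score <- numeric(length(focal_idx))
  n_neighbors <- integer(length(focal_idx))
  if (nrow(hits)) {
    col <- match(hits$focal, focal_idx)
    wt <- wrow[rec$tf[hits$hit]]
    sum_score <- as.numeric(tapply(wt, factor(col, levels = seq_along(focal_idx)),
                                   sum, default = 0))
    n_neighbors <- as.integer(tabulate(col, nbins = length(focal_idx)))
  }
  out <- data.frame(rec[focal_idx, c("chrom", "start", "end", "tf")],
                    sum_score = sum_score,
                    n_neighbors = n_neighbors,
                    normalized_score = sum_score / pmax(n_neighbors, 1L))
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "window_bp") <- window_bp
  class(out) <- c("scored_sites", "data.frame")
  out
}

#' Neighbor-count ("length") scores
#'
#' The rival score based purely on how many putative TFBSs fall in each
#' window, ignoring which TFs they belong to.
#'
#' @inheritParams sum_scores
#' @return Same shape as [sum_scores()]; use the `n_neighbors` column as the
#'   score.
#' @export
length_scores <- function(target, putative, graph,
                          window_bp = graph$window_bp) {
  sum_scores(target, putative, graph, window_bp)
}

#' Recall of retained putative sites against actual sites
#'
#' Fraction of actual (experimentally determined) sites of the target TF
#' whose surrounding window contains at least one retained putative
#' interval.
#'
#' @param actual a `tfbs_collection` (or chrom/start/end data.frame) of
#'   actual sites; must be non-empty.
#' @param retained data.frame chrom/start/end of retained putative
#'   intervals.
#' @param window_bp window radius in bp.
#' @return Fraction in `[0, 1]`.
#' @export
tfbs_recall <- function(actual, retained, window_bp = 1000) {
  adf <- if (inherits(actual, "tfbs_collection")) actual$records else actual
  if (!nrow(adf)) stop("recall undefined: no actual sites")
  mean(.window_hit(adf, retained, window_bp))
}

#' Precision of retained putative sites against actual sites
#'
#' Fraction of *merged* retained putative intervals whose surrounding window
#' contains at least one actual site.  Merging overlapping putative sites
#' first keeps the denominator well-defined and the metric within `[0, 1]`.
#'
#' @param retained data.frame chrom/start/end of retained putative
#'   intervals (merged with [merge_overlapping()]); must be non-empty.
#' @param actual a `tfbs_collection` (or chrom/start/end data.frame) of
#'   actual sites.
#' @param window_bp window radius in bp.
#' @return Fraction in `[0, 1]`.
#' @export
tfbs_precision <- function(retained, actual, window_bp = 1000) {
  adf <- if (inherits(actual, "tfbs_collection")) actual$records else actual
  if (!nrow(retained)) stop("precision undefined: no retained putative sites")
  mean(.window_hit(retained, adf, window_bp))
}

#' F-score (harmonic mean of precision and recall)
#'
#' @param p,r precision and recall, each in `[0, 1]`.
#' @return `2pr/(p+r)`; 0 when both are 0.
#' @export
f_score <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

.score_column <- function(method) {
  switch(method,
         sum = "sum_score",
         normalized_sum = "normalized_score",
         length = "n_neighbors",
         stop("unknown scoring method: ", method))
}

#' Precision-recall sweep over score cutoffs
#'
#' Sweeps the retention cutoff over the distinct score values (preceded by
#' -Inf, i.e. the unfiltered set) and records precision, recall and F-score
#' at each point.  Sites with score >= cutoff are retained (for
#' `direction = "ge"`, the default); `direction = "le"` flips the
#' thresholding (retain score <= cutoff, swept downward), which is how the
#' neighbor-count score is also evaluated since it is negatively correlated
#' with the sum-score.  Cutoffs that would empty the retained set are not
#' visited (precision is undefined there).
#'
#' @param scored a [sum_scores()] result.
#' @param actual actual-site `tfbs_collection` for the target TF.
#' @param method one of `"sum"`, `"normalized_sum"`, `"length"`.
#' @param window_bp window radius in bp (defaults to the scoring window).
#' @param direction `"ge"` (retain score >= cutoff) or `"le"`.
#' @return Object of class `pr_curve`: data.frame with columns `cutoff`,
#'   `n_retained`, `precision`, `recall`, `f`; attributes `method`,
#'   `direction`, and `max_f` (list with the argmax-F row).
#' @export
pr_sweep <- function(scored, actual, method = "sum",
                     window_bp = attr(scored, "window_bp"),
                     direction = c("ge", "le")) {
  stopifnot(inherits(scored, "scored_sites"), nrow(scored) > 0)
  direction <- match.arg(direction)
  score <- scored[[.score_column(method)]]
  cutoffs <- if (direction == "ge") c(-Inf, sort(unique(score)))
             else c(Inf, sort(unique(score), decreasing = TRUE))
  adf <- if (inherits(actual, "tfbs_collection")) actual$records else actual
  rows <- lapply(cutoffs, function(ct) {
    keep <- if (direction == "ge") score >= ct else score <= ct
    if (!any(keep)) return(NULL)
    merged <- merge_overlapping(scored[keep, c("chrom", "start", "end")])
    p <- tfbs_precision(merged, adf, window_bp)
    r <- tfbs_recall(adf, merged, window_bp)
    data.frame(cutoff = ct, n_retained = sum(keep), precision = p,
               recall = r, f = f_score(p, r))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- out[which.max(out$f), , drop = FALSE]
  attr(out, "method") <- method
  attr(out, "direction") <- direction
  attr(out, "max_f") <- as.list(best)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' @export
print.pr_curve <- function(x, ...) {
  b <- attr(x, "max_f")
  cat(sprintf("PR curve (%s score, %d cutoffs)\n", attr(x, "method"), nrow(x)))
  cat(sprintf("  unfiltered: P %.4g  R %.4g  F %.4g\n",
              x$precision[1], x$recall[1], x$f[1]))
  cat(sprintf("  max F %.4g at cutoff %.4g (P %.4g, R %.4g, %d sites retained)\n",
              b$f, b$cutoff, b$precision, b$recall, b$n_retained))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ..., add = FALSE, col = 1, lty = 1) {
  if (!add) {
    graphics::plot(x$recall, x$precision, type = "l", col = col, lty = lty,
                   xlab = "recall", ylab = "precision",
                   main = paste0("TFBS filtering PR curve (",
                                 attr(x, "method"), ")"), ...)
  } else {
    graphics::lines(x$recall, x$precision, col = col, lty = lty, ...)
  }
  invisible(x)
}

#' Random-removal baseline
#'
#' Removes `n_remove` putative sites uniformly at random (matching the
#' removal count of a score cutoff) and reports the resulting precision,
#' recall and F-score — the control for whether score-based filtering does
#' better than merely returning fewer sites.
#'
#' @param scored a [sum_scores()] result.
#' @param n_remove number of sites to remove, in `[0, nrow(scored) - 1]`.
#' @param seed RNG seed (required for reproducibility).
#' @param actual actual-site collection for the target TF.
#' @param window_bp window radius in bp.
#' @return list with `precision`, `recall`, `f`, `n_retained`.
#' @export
random_baseline <- function(scored, n_remove, seed, actual,
                            window_bp = attr(scored, "window_bp")) {
  stopifnot(inherits(scored, "scored_sites"))
  n <- nrow(scored)
  if (n_remove < 0 || n_remove > n) stop("n_remove out of range")
  if (n_remove == n) stop("cannot remove all sites: precision undefined")
  keep <- withr::with_seed(seed,
                           sort(sample.int(n, n - n_remove)))
  merged <- merge_overlapping(scored[keep, c("chrom", "start", "end")])
  adf <- if (inherits(actual, "tfbs_collection")) actual$records else actual
  p <- tfbs_precision(merged, adf, window_bp)
  r <- tfbs_recall(adf, merged, window_bp)
  list(precision = p, recall = r, f = f_score(p, r), n_retained = n - n_remove)
}
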