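#' Cluster-discovery workflow
#'
#' Runs the full pipeline: build the co-occurrence graph, generate the
#' permutation null pool, derive the weight threshold for the target FPR,
#' filter the graph, cluster with MCL and compute cluster metrics.  All
#' artifacts (edge list, cluster table, threshold/metrics JSON and a
#' manifest with the configuration, seed and achieved FPR) are written to
#' `out_dir` when one is given.
#'
#' @param collection a [tfbs_collection()] (or a path readable by
#'   [read_tfbs()]).
#' @param window_bp proximity window radius in bp (default 1000).
#' @param fpr target false-positive rate (default 0.01; the conventional
#'   grid is 0.1, 0.01, 0.001, 0.0001).
#' @param n_reps permutation repeats for the null pool (default 25).
#' @param seed RNG seed for the null pool (required).
#' @param inflation,prune_below,max_iter MCL parameters, see
#'   [mcl_cluster()].
#' @param out_dir optional output directory.
#' @return list with `graph`, `pool`, `threshold`, `filtered`, `clustering`,
#'   `metrics`, `manifest`.
#' @export
run_cluster_workflow <- function(collection, window_bp = 1000, fpr = 0.01,
                                 n_reps = 25L, seed, inflation = 2.5,
                                 prune_below = 1e-5, max_iter = 100L,
                                 out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("seed is required: the null pool is a random permutation")
  if (is.character(collection)) collection <- read_tfbs(collection)
  stopifnot(inherits(collection, "tfbs_collection"))
  message(sprintf("[graph] %d sites, %d TFs, window %g bp",
                  collection$w, length(collection$tf_names), window_bp))
  graph <- build_graph(collection, window_bp = window_bp)
  pool <- dummy_pool(graph, n_reps = n_reps, seed = seed)
  message(sprintf("[null] %d dummy weights (%d repeats)",
                  length(pool$weights), pool$n_reps))
  thr <- threshold_for_fpr(pool, fpr)
  filtered <- filter_graph(graph, thr)
  message(sprintf("[filter] threshold %.6g: %d/%d edges removed (%.1f%%)",
                  thr$threshold, filtered$n_filtered,
                  filtered$n_edges_total, filtered$pct_filtered))
  clustering <- mcl_cluster(filtered, inflation = inflation,
                            prune_below = prune_below, max_iter = max_iter)
  metrics <- cluster_metrics(clustering, filtered)
  message(sprintf("[mcl] %d clusters, %.1f%% unclustered (inflation %g)",
                  metrics$n_clusters, metrics$unclustered_pct, inflation))
  manifest <- list(
    stage = "cluster_workflow",
    window_bp = window_bp, fpr_target = fpr, n_reps = n_reps, seed = seed,
    inflation = inflation, prune_below = prune_below, max_iter = max_iter,
    n_tfs = length(collection$tf_names), n_sites = collection$w,
    threshold = thr$threshold, achieved_fpr = thr$achieved_fpr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_graph(graph, file.path(out_dir, "graph_edges.tsv"))
    write_graph(filtered, file.path(out_dir, "filtered_edges.tsv"))
    write_clusters(clustering, file.path(out_dir, "clusters.tsv"))
    jsonlite::write_json(as.list(as.data.frame(metrics)),
                         file.path(out_dir, "cluster_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, cfg_path, auto_unbox = TRUE, digits = NA)
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, cfg_path, auto_unbox = TRUE, digits = NA)
  }
  list(graph = graph, pool = pool, threshold = thr, filtered = filtered,
       clustering = clustering, metrics = metrics, manifest = manifest)
}

#' TFBS-filtering workflow
#'
#' Builds the unfiltered signed graph from the putative collection, scores
#' the target TF's putative sites, and sweeps precision/recall/F for all
#' four scoring methods: the signed sum-score, the normalized sum-score,
#' the neighbor-count ("length") score (swept in both directions, the
#' better one reported) and a random-removal baseline matched to the
#' sum-score's removal count at its maximum F.
#'
#' @param putative putative-site [tfbs_collection()] (or path).
#' @param actual actual-site [tfbs_collection()] (or path) for the target.
#' @param target target TF identifier.
#' @param window_bp window radius in bp (default 1000).
#' @param seed RNG seed for the random baseline (required).
#' @param n_random_draws random-baseline repeats to average (default 20).
#' @param out_dir optional output directory for PR TSVs and a summary JSON.
#' @return list with `graph`, `scored`, `curves` (named list of
#'   [pr_sweep()] results), `random` (averaged baseline), `summary`
#'   (data.frame of max-F rows per method).
#' @export
run_filter_workflow <- function(putative, actual, target, window_bp = 1000,
                                seed, n_random_draws = 20L, out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("seed is required: the random baseline is stochastic")
  if (is.character(putative)) putative <- read_tfbs(putative)
  if (is.character(actual)) actual <- read_tfbs(actual)
  stopifnot(inherits(putative, "tfbs_collection"),
            inherits(actual, "tfbs_collection"))
  if (!nrow(actual$records)) stop("[recall] actual collection is empty")
  message(sprintf("[graph] unfiltered signed graph from %d putative sites",
                  putative$w))
  graph <- build_graph(putative, window_bp = window_bp)
  scored <- sum_scores(target, putative, graph, window_bp = window_bp)
  message(sprintf("[score] %d putative %s sites scored", nrow(scored), target))
  curves <- list(
    sum = pr_sweep(scored, actual, method = "sum", window_bp = window_bp),
    normalized_sum = pr_sweep(scored, actual, method = "normalized_sum",
                              window_bp = window_bp),
    length = pr_sweep(scored, actual, method = "length",
                      window_bp = window_bp),
    length_flipped = pr_sweep(scored, actual, method = "length",
                              window_bp = window_bp, direction = "le"))
  best_sum <- attr(curves$sum, "max_f")
  n_remove <- nrow(scored) - best_sum$n_retained
  rnd <- lapply(seq_len(n_random_draws), function(i)
    random_baseline(scored, n_remove, seed = seed + i - 1L, actual,
                    window_bp = window_bp))
  random <- list(precision = mean(vapply(rnd, `[[`, 0, "precision")),
                 recall = mean(vapply(rnd, `[[`, 0, "recall")),
                 f = mean(vapply(rnd, `[[`, 0, "f")),
                 n_remove = n_remove, n_draws = n_random_draws)
  message(sprintf("[baseline] random removal of %d sites: mean F %.4g",
                  n_remove, random$f))
  summary_df <- do.call(rbind, lapply(names(curves), function(nm) {
    b <- attr(curves[[nm]], "max_f")
    data.frame(method = nm, cutoff = b$cutoff, n_retained = b$n_retained,
               precision = b$precision, recall = b$recall, f = b$f)
  }))
  summary_df <- rbind(summary_df,
                      data.frame(method = "unfiltered", cutoff = -Inf,
                                 n_retained = nrow(scored),
                                 precision = curves$sum$precision[1],
                                 recall = curves$sum$recall[1],
                                 f = curves$sum$f[1]),
                      data.frame(method = "random", cutoff = NA,
                                 n_retained = nrow(scored) - n_remove,
                                 precision = random$precision,
                                 recall = random$recall, f = random$f))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scored, file.path(out_dir, "scored_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(curves))
      utils::write.table(as.data.frame(curves[[nm]]),
                         file.path(out_dir, paste0("pr_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(target = target, window_bp = window_bp,
                              seed = seed, summary = summary_df),
                         file.path(out_dir, "filter_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(graph = graph, scored = scored, curves = curves, random = random,
       summary = summary_df)
}
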