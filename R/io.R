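#' Read a reference interaction table (STRING detailed format)
#'
#' Reads a whitespace/tab-separated table in the layout of STRING's
#' `protein.links.detailed` files: two protein columns, seven per-channel
#' evidence scores (neighborhood, fusion, cooccurence, coexpression,
#' experimental, database, textmining) and a combined score.  Rows with
#' combined score below `score_threshold` are dropped; the remainder is
#' deduplicated to unordered pairs (channel scores averaged across the two
#' directions, which in STRING are identical anyway); self-pairs are
#' dropped.
#'
#' @param path file path.
#' @param score_threshold minimum combined score (default 400, STRING's
#'   conventional "medium confidence" cutoff).
#' @return Object of class `reference_interactions`: list with `pairs`
#'   (data.frame `tf1`, `tf2` with `tf1 < tf2`), `channels` (data.frame of
#'   the seven channel scores plus `combined_score`, row-aligned with
#'   `pairs`), `channel_names`, `tf_names` (all TFs appearing in a pair) and
#'   `score_threshold`.
#' @export
read_reference <- function(path, score_threshold = 400) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  want <- c(protein1 = "protein1", protein2 = "protein2",
            Neighborhood = "neighborhood", Fusion = "fusion",
            `Co-occurrence` = "cooccurence", `Co-expression` = "coexpression",
            Experiments = "experimental", Database = "database",
            `Text-Mining` = "textmining", combined_score = "combinedscore")
  idx <- match(want, canon(names(df)))
  if (anyNA(idx))
    stop("reference table is missing column(s): ",
         paste(names(want)[is.na(idx)], collapse = ", "))
  df <- df[idx]
  names(df) <- names(want)
  score_cols <- setdiff(names(want), c("protein1", "protein2"))
  for (col in score_cols) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(df[[col]])) stop("non-numeric values in column ", col)
  }
  if (any(df[score_cols] < 0)) stop("negative channel scores")
  df <- df[df$combined_score >= score_threshold, , drop = FALSE]
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  tf1 <- pmin(df$protein1, df$protein2)
  tf2 <- pmax(df$protein1, df$protein2)
  key <- paste(tf1, tf2, sep = "\r")
  ukey <- sort(unique(key))
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  pairs <- data.frame(tf1 = vapply(parts, `[[`, "", 1L),
                      tf2 = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  channels <- as.data.frame(lapply(df[score_cols], function(x)
    as.numeric(tapply(x, key, mean)[ukey])), check.names = FALSE)
  structure(list(pairs = pairs, channels = channels,
                 channel_names = setdiff(score_cols, "combined_score"),
                 tf_names = sort(unique(c(pairs$tf1, pairs$tf2))),
                 score_threshold = score_threshold),
            class = "reference_interactions")
}

#' @export
print.reference_interactions <- function(x, ...) {
  cat(sprintf("Reference interactions: %d unordered pairs over %d proteins (combined score >= %g)\n",
              nrow(x$pairs), length(x$tf_names), x$score_threshold))
  invisible(x)
}

#' Read a TF-pair motif (PWM) similarity table
#'
#' Reads a tab-separated table with columns tf1, tf2, score.  Multiple rows
#' for the same unordered TF pair (a TF represented by several PWMs) are
#' averaged; the number of averaged values is kept as the pair's
#' multiplicity.
#'
#' @param path file path.
#' @return Object of class `similarity_table`: data.frame with columns
#'   `tf1`, `tf2` (`tf1 <= tf2`), `similarity`, `n_scores`.
#' @export
read_similarity <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("similarity table needs columns tf1, tf2, score")
  names(df)[1:3] <- c("tf1", "tf2", "score")
  df$score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(df$score)) stop("non-numeric similarity score")
  a <- pmin(df$tf1, df$tf2)
  b <- pmax(df$tf1, df$tf2)
  key <- paste(a, b, sep = "\r")
  ukey <- sort(unique(key))
  sim <- as.numeric(tapply(df$score, key, mean)[ukey])
  nsc <- as.integer(tapply(df$score, key, length)[ukey])
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  out <- data.frame(tf1 = vapply(parts, `[[`, "", 1L),
                    tf2 = vapply(parts, `[[`, "", 2L),
                    similarity = sim, n_scores = nsc,
                    stringsAsFactors = FALSE)
  class(out) <- c("similarity_table", "data.frame")
  out
}

#' Write a co-occurrence graph as a TSV edge list
#'
#' One line per unordered edge (self-loops included), columns
#' tf1/tf2/weight, in lexicographic (tf1, tf2) order.
#'
#' @param graph a `cooc_graph` or `filtered_graph`.
#' @param path output file path.
#' @param include_negative keep negative-weight edges (default TRUE)?
#' @return Invisibly, the data.frame written.
#' @export
write_graph <- function(graph, path, include_negative = TRUE) {
  edges <- if (inherits(graph, "filtered_graph")) graph$edges
           else .edge_table(graph)
  if (!include_negative) edges <- edges[edges$weight >= 0, , drop = FALSE]
  utils::write.table(format(edges, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' Read an edge list written by [write_graph()]
#'
#' @param path file path.
#' @return data.frame tf1/tf2/weight.
#' @export
read_graph_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("tf1", "tf2", "weight") %in% names(df)))
  df$weight <- as.numeric(df$weight)
  df
}

#' Write a clustering as a TSV table
#'
#' One line per TF: tf, cluster id (`cluster1`, `cluster2`, ... by
#' decreasing size) or `unclustered`; TFs in cluster order then
#' alphabetical.
#'
#' @param clustering a [mcl_cluster()] result.
#' @param path output file path.
#' @return Invisibly, the data.frame written.
#' @export
write_clusters <- function(clustering, path) {
  stopifnot(inherits(clustering, "tf_clustering"))
  rows <- list()
  for (k in seq_along(clustering$clusters))
    rows[[length(rows) + 1L]] <-
      data.frame(tf = clustering$clusters[[k]], cluster = paste0("cluster", k))
  if (length(clustering$unclustered))
    rows[[length(rows) + 1L]] <-
      data.frame(tf = clustering$unclustered, cluster = "unclustered")
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(tf = character(0), cluster = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a cluster table written by [write_clusters()]
#'
#' @param path file path.
#' @return data.frame tf/cluster.
#' @export
read_clusters <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "cluster") %in% names(df)))
  df
}
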