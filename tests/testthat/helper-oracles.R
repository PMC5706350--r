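# Independent brute-force oracles: straight all-pairs interval arithmetic,
# no IRanges, no shared code with the package internals.

# O(m^2) co-occurrence oracle: half-open intervals, focal site extended by
# window_bp on each side, self excluded.
brute_cooc_matrix <- function(collection, tf, window_bp) {
  rec <- collection$records
  tfn <- collection$tf_names
  focal <- which(rec$tf == tf)
  M <- matrix(0L, length(tfn), length(focal), dimnames = list(tfn, NULL))
  for (jj in seq_along(focal)) {
    j <- focal[jj]
    hit <- rec$chrom == rec$chrom[j] &
      rec$start < rec$end[j] + window_bp &
      rec$start[j] - window_bp < rec$end
    hit[j] <- FALSE
    rows <- unique(match(rec$tf[hit], tfn))
    if (length(rows)) M[rows, jj] <- 1L
  }
  M
}

# Pairwise-merge interval-union oracle (half-open; book-ended merge).
brute_merge <- function(df) {
  out <- NULL
  for (chr in sort(unique(df$chrom))) {
    x <- df[df$chrom == chr, , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
    cs <- x$start[1]; ce <- x$end[1]
    res <- list()
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= ce) {
        ce <- max(ce, x$end[i])
      } else {
        res[[length(res) + 1L]] <- c(cs, ce)
        cs <- x$start[i]; ce <- x$end[i]
      }
    }
    res[[length(res) + 1L]] <- c(cs, ce)
    m <- do.call(rbind, res)
    out <- rbind(out, data.frame(chrom = chr, start = m[, 1], end = m[, 2]))
  }
  out
}

# Nested-loop recall/precision oracles.
brute_window_hit <- function(query, subject, w) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] + w &
          query$start[i] - w < subject$end)
  }, logical(1))
}
brute_recall <- function(actual_df, retained_df, w) {
  mean(brute_window_hit(actual_df, retained_df, w))
}
brute_precision <- function(retained_df, actual_df, w) {
  mean(brute_window_hit(retained_df, actual_df, w))
}

# Random toy collection over 1-2 chromosomes.
random_toy <- function(n_sites, n_tfs, genome = 50000L, seed = 1,
                       max_len = 60L) {
  withr::with_seed(seed, {
    start <- sample.int(genome, n_sites, replace = TRUE) - 1L
    len <- sample.int(max_len, n_sites, replace = TRUE)
    tfbs_collection(data.frame(
      chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
      start = start, end = start + len,
      tf = sample(LETTERS[seq_len(n_tfs)], n_sites, replace = TRUE)))
  })
}

# Hand-built co-occurrence graph (for scoring/evaluation arithmetic tests).
fake_graph <- function(W, window_bp = 1000) {
  structure(list(tf_names = rownames(W), A = W, W = W,
                 f_all = rep(0, nrow(W)),
                 m = stats::setNames(rep(1L, nrow(W)), rownames(W)),
                 w = nrow(W), window_bp = window_bp),
            class = "cooc_graph")
}

# Hand-built reference interaction table.
fake_reference <- function(pairs, channels = NULL) {
  pairs <- data.frame(tf1 = pmin(pairs[[1]], pairs[[2]]),
                      tf2 = pmax(pairs[[1]], pairs[[2]]),
                      stringsAsFactors = FALSE)
  ch_names <- c("Neighborhood", "Fusion", "Co-occurrence", "Co-expression",
                "Experiments", "Database", "Text-Mining")
  if (is.null(channels)) {
    channels <- as.data.frame(stats::setNames(
      rep(list(rep(500, nrow(pairs))), length(ch_names)), ch_names),
      check.names = FALSE)
  }
  channels$combined_score <- rep(500, nrow(pairs))
  structure(list(pairs = pairs, channels = channels,
                 channel_names = ch_names,
                 tf_names = sort(unique(c(pairs$tf1, pairs$tf2))),
                 score_threshold = 400),
            class = "reference_interactions")
}

# Write a STRING-detailed-layout reference file.
write_reference_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
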