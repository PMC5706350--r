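#' Configuration for planted co-binding simulations
#'
#' Describes a synthetic genome in which groups of TFs bind together at
#' shared complex loci — the co-binding structure a proximity method is
#' meant to detect — on top of independent uniform background binding.
#' Sites are coordinate intervals on a single uniform chromosome: the
#' method consumes only pairwise proximity, so no sequence or chromatin
#' structure is modelled.
#'
#' @param n_tfs total number of TFs (default 24).
#' @param n_clusters number of planted clusters (default 3); the first
#'   `n_clusters * tfs_per_cluster` TFs are assigned to clusters in blocks,
#'   any remainder are background-only.
#' @param tfs_per_cluster TFs per planted cluster (default 8).
#' @param genome_length chromosome length in bp (default 1e8).
#' @param complexes_per_cluster complex loci per cluster (default 200).
#' @param participation_prob probability that a cluster member binds at a
#'   given complex locus (default 0.8).
#' @param placement_jitter uniform jitter, in bp, applied to each bound
#'   site around its complex locus (default 300; keep below the analysis
#'   window so planted partners register as co-occurring).
#' @param background_rate expected number of background (independent,
#'   uniform) sites per TF; Poisson-distributed counts (default 300).
#' @param site_length site width in bp (default 200, a typical peak width).
#' @param target_tf TF whose sites the filtering fixture treats as the
#'   search target (default the first TF).
#' @return Object of class `planted_config` (a validated list).
#' @export
planted_config <- function(n_tfs = 24L, n_clusters = 3L, tfs_per_cluster = 8L,
                           genome_length = 1e8, complexes_per_cluster = 200L,
                           participation_prob = 0.8, placement_jitter = 300L,
                           background_rate = 300, site_length = 200L,
                           target_tf = NULL) {
  stopifnot(n_tfs >= 2, n_clusters >= 1, tfs_per_cluster >= 2,
            n_clusters * tfs_per_cluster <= n_tfs,
            participation_prob >= 0, participation_prob <= 1,
            placement_jitter >= 0, background_rate >= 0, site_length >= 1,
            genome_length > 10 * (site_length + 2 * placement_jitter))
  expected_sites <- n_tfs * background_rate +
    n_clusters * tfs_per_cluster * complexes_per_cluster * participation_prob
  if (expected_sites * site_length > 0.5 * genome_length)
    stop("infeasible config: expected sites would tile over half the genome")
  tf_names <- sprintf("TF%03d", seq_len(n_tfs))
  assignment <- rep(NA_integer_, n_tfs)
  assignment[seq_len(n_clusters * tfs_per_cluster)] <-
    rep(seq_len(n_clusters), each = tfs_per_cluster)
  names(assignment) <- tf_names
  if (is.null(target_tf)) target_tf <- tf_names[1]
  stopifnot(target_tf %in% tf_names)
  structure(list(n_tfs = n_tfs, tf_names = tf_names,
                 cluster_assignment = assignment,
                 n_clusters = n_clusters,
                 genome_length = genome_length,
                 complexes_per_cluster = complexes_per_cluster,
                 participation_prob = participation_prob,
                 placement_jitter = placement_jitter,
                 background_rate = background_rate,
                 site_length = site_length,
                 target_tf = target_tf),
            class = "planted_config")
}

# Draw one TF's background sites uniformly over the genome.
.uniform_sites <- function(n, genome_length, site_length) {
  start <- floor(stats::runif(n, 0, genome_length - site_length))
  data.frame(start = as.integer(start),
             end = as.integer(start + site_length))
}

#' Generate a planted co-binding dataset
#'
#' Per cluster, complex loci are drawn uniformly over the genome; each
#' member TF binds each locus independently with `participation_prob`, its
#' site centred at the locus plus uniform jitter in
#' `[-placement_jitter, +placement_jitter]`.  Background sites are added
#' per TF with Poisson(`background_rate`) counts at uniform positions.
#'
#' @param config a [planted_config()].
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return list with `collection` (a [tfbs_collection()]) and `truth` (list
#'   with `clusters` — named cluster label per assigned TF — and `sites`, a
#'   data.frame aligned with the sorted records giving each site's `origin`
#'   (`"complex"` or `"background"`) and cluster id).
#' @export
generate_planted <- function(config, seed = NULL) {
  stopifnot(inherits(config, "planted_config"))
  gen <- function() {
    G <- config$genome_length
    L <- config$site_length
    J <- config$placement_jitter
    rows <- list()
    for (k in seq_len(config$n_clusters)) {
      members <- names(config$cluster_assignment)[
        !is.na(config$cluster_assignment) & config$cluster_assignment == k]
      loci <- floor(stats::runif(config$complexes_per_cluster, J, G - L - J))
      for (tf in members) {
        binds <- stats::runif(length(loci)) < config$participation_prob
        if (!any(binds)) next
        jitter <- round(stats::runif(sum(binds), -J, J))
        start <- pmax(0, pmin(G - L, loci[binds] + jitter))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chr1", start = as.integer(start),
          end = as.integer(start + L), tf = tf,
          origin = "complex", cluster = k)
      }
    }
    for (tf in config$tf_names) {
      n_bg <- stats::rpois(1, config$background_rate)
      if (!n_bg) next
      bg <- .uniform_sites(n_bg, G, L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1", start = bg$start, end = bg$end, tf = tf,
        origin = "background", cluster = NA_integer_)
    }
    do.call(rbind, rows)
  }
  df <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  ord <- order(df$chrom, df$start, df$end, df$tf, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  collection <- tfbs_collection(df[c("chrom", "start", "end", "tf")])
  assigned <- config$cluster_assignment[!is.na(config$cluster_assignment)]
  truth <- list(clusters = paste0("planted", assigned),
                sites = df[c("tf", "origin", "cluster")])
  names(truth$clusters) <- names(assigned)
  list(collection = collection, truth = truth)
}

#' Generate an independent-binding (null) dataset
#'
#' Every TF's sites are placed independently and uniformly over the genome,
#' so any co-occurrence is a background collision.  This realizes, in
#' genomic space, the shuffled-order null that the dummy-matrix FPR
#' calibration models, and is the fixture for calibration tests.
#'
#' @param n_tfs number of TFs.
#' @param sites_per_tf sites per TF (scalar or vector recycled over TFs).
#' @param genome_length chromosome length in bp (default 1e8).
#' @param site_length site width in bp (default 200).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return A [tfbs_collection()].
#' @export
generate_null <- function(n_tfs, sites_per_tf, genome_length = 1e8,
                          site_length = 200L, seed = NULL) {
  stopifnot(n_tfs >= 1, all(sites_per_tf >= 1),
            genome_length > 10 * site_length)
  counts <- rep_len(as.integer(sites_per_tf), n_tfs)
  tf_names <- sprintf("TF%03d", seq_len(n_tfs))
  gen <- function() {
    rows <- lapply(seq_len(n_tfs), function(i) {
      s <- .uniform_sites(counts[i], genome_length, site_length)
      data.frame(chrom = "chr1", start = s$start, end = s$end,
                 tf = tf_names[i])
    })
    do.call(rbind, rows)
  }
  df <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  tfbs_collection(df)
}

#' Generate a putative-vs-actual TFBS filtering fixture
#'
#' Stands in for a motif-scan (putative) versus ChIP-seq (actual) dataset
#' pair for one target TF.  The *actual* collection holds the target's
#' complex-derived sites from a planted simulation.  The *putative*
#' collection holds (a) re-jittered copies of those actual sites (true
#' putative sites), (b) `decoy_count` uniformly placed decoy sites labelled
#' with the target TF, and (c) all other TFs' sites, which provide the
#' co-occurrence context the scoring stage exploits.
#'
#' @param config a [planted_config()]; `config$target_tf` is the target.
#' @param decoy_count number of uniform decoy putative sites for the target
#'   (default 1000).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return list with `putative` and `actual` (both [tfbs_collection()]s)
#'   and `truth` (data.frame of the target's putative sites with a logical
#'   `is_true` label, coordinates sorted as in the putative collection).
#' @export
generate_filter_fixture <- function(config, decoy_count = 1000L, seed = NULL) {
  stopifnot(inherits(config, "planted_config"), decoy_count >= 0)
  target <- config$target_tf
  if (is.na(config$cluster_assignment[target]))
    stop("target TF must belong to a planted cluster")
  run <- function() {
    planted <- generate_planted(config, seed = NULL)
    rec <- planted$collection$records
    origin <- planted$truth$sites$origin
    actual_df <- rec[rec$tf == target & origin == "complex", , drop = FALSE]
    if (!nrow(actual_df)) stop("target TF has no complex-derived sites")
    G <- config$genome_length
    L <- config$site_length
    J <- config$placement_jitter
    jit <- round(stats::runif(nrow(actual_df), -J, J))
    true_put <- data.frame(
      chrom = actual_df$chrom,
      start = as.integer(pmax(0, pmin(G - L, actual_df$start + jit))),
      end = NA_integer_, tf = target)
    true_put$end <- true_put$start + L
    decoys <- if (decoy_count > 0) {
      d <- .uniform_sites(decoy_count, G, L)
      data.frame(chrom = "chr1", start = d$start, end = d$end, tf = target)
    } else NULL
    others <- rec[rec$tf != target, c("chrom", "start", "end", "tf")]
    put_df <- rbind(cbind(true_put, is_true = TRUE),
                    if (!is.null(decoys)) cbind(decoys, is_true = FALSE),
                    cbind(others, is_true = NA))
    list(actual_df = actual_df, put_df = put_df)
  }
  parts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  put_df <- parts$put_df
  ord <- order(put_df$chrom, put_df$start, put_df$end, put_df$tf,
               method = "radix")
  put_df <- put_df[ord, , drop = FALSE]
  rownames(put_df) <- NULL
  putative <- tfbs_collection(put_df[c("chrom", "start", "end", "tf")])
  actual <- tfbs_collection(parts$actual_df[c("chrom", "start", "end", "tf")])
  truth <- put_df[put_df$tf == target, , drop = FALSE]
  rownames(truth) <- NULL
  list(putative = putative, actual = actual, truth = truth)
}
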