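test_that("merge_overlapping is the interval union", {
  df <- data.frame(chrom = "chr1", start = c(10L, 15L), end = c(20L, 30L))
  expect_equal(merge_overlapping(df),
               data.frame(chrom = "chr1", start = 10L, end = 30L),
               ignore_attr = TRUE)
  # disjoint intervals unchanged (sorted)
  df2 <- data.frame(chrom = "chr1", start = c(100L, 0L), end = c(150L, 50L))
  expect_equal(merge_overlapping(df2)$start, c(0L, 100L))
  # book-ended half-open intervals form one covered run
  df3 <- data.frame(chrom = "chr1", start = c(10L, 20L), end = c(20L, 30L))
  expect_equal(nrow(merge_overlapping(df3)), 1L)
  # random toys equal the pairwise-merge oracle; idempotent
  for (s in 1:8) {
    df <- withr::with_seed(s, {
      start <- sample.int(2000, 50, replace = TRUE)
      data.frame(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                 start = start, end = start + sample.int(80, 50, TRUE))
    })
    m <- merge_overlapping(df)
    expect_equal(m, brute_merge(df), ignore_attr = TRUE)
    expect_equal(merge_overlapping(m), m, ignore_attr = TRUE)
  }
})

test_that("sum-score is the signed per-instance weight sum", {
  # target t site with neighbors {X, X, Y}; W[t,X] = 0.2, W[t,Y] = -0.1
  W <- matrix(0, 3, 3, dimnames = rep(list(c("t", "X", "Y")), 2))
  W["t", "X"] <- W["X", "t"] <- 0.2
  W["t", "Y"] <- W["Y", "t"] <- -0.1
  g <- fake_graph(W)
  put <- tfbs_collection(data.frame(
    chrom = "chr1",
    start = c(1000L, 1200L, 1500L, 1700L, 90000L),
    end = c(1100L, 1300L, 1600L, 1800L, 90100L),
    tf = c("t", "X", "X", "Y", "t")))
  sc <- sum_scores("t", put, g, window_bp = 1000)
  sc <- sc[order(sc$start), ]
  expect_equal(sc$sum_score, c(0.2 + 0.2 - 0.1, 0))
  expect_equal(sc$n_neighbors, c(3L, 0L))
  expect_equal(sc$normalized_score, c(0.3 / 3, 0))
  # only negatively-weighted neighbors: score goes negative
  put2 <- tfbs_collection(data.frame(
    chrom = "chr1", start = c(1000L, 1200L), end = c(1100L, 1300L),
    tf = c("t", "Y")))
  expect_lt(sum_scores("t", put2, g, window_bp = 1000)$sum_score, 0)
  expect_error(sum_scores("Z", put, g), "target")
})

test_that("other target sites count as neighbors via the self-loop weight", {
  W <- matrix(0, 2, 2, dimnames = rep(list(c("t", "X")), 2))
  W["t", "t"] <- 0.15
  g <- fake_graph(W)
  put <- tfbs_collection(data.frame(
    chrom = "chr1", start = c(1000L, 1400L), end = c(1100L, 1500L),
    tf = c("t", "t")))
  sc <- sum_scores("t", put, g, window_bp = 1000)
  expect_equal(sc$sum_score, c(0.15, 0.15))
  expect_equal(sc$n_neighbors, c(1L, 1L))
})

test_that("recall and precision match the nested-loop oracles", {
  actual <- tfbs_collection(data.frame(
    chrom = "chr1", start = c(1000L, 5000L, 9000L, 13000L),
    end = c(1200L, 5200L, 9200L, 13200L), tf = "t"))
  # putatives near 2 of the 4 actual sites
  retained <- data.frame(chrom = "chr1", start = c(1500L, 8500L, 40000L),
                         end = c(1600L, 8600L, 40100L))
  expect_equal(tfbs_recall(actual, retained, 1000), 0.5)
  expect_equal(tfbs_recall(actual, retained, 1000),
               brute_recall(actual$records, retained, 1000))
  expect_equal(tfbs_precision(retained, actual, 1000), 2 / 3)
  expect_equal(tfbs_precision(retained, actual, 1000),
               brute_precision(retained, actual$records, 1000))
  # boundary cases
  expect_equal(tfbs_recall(actual, retained[0, ], 1000), 0)
  expect_error(tfbs_recall(actual$records[0, ], retained, 1000), "undefined")
  expect_error(tfbs_precision(retained[0, ], actual, 1000), "undefined")
  # randomized toys against the oracle
  for (s in 1:6) {
    q <- withr::with_seed(s, {
      start <- sample.int(30000, 40, replace = TRUE)
      data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                 start = start, end = start + 100L)
    })
    r <- withr::with_seed(s + 10, {
      start <- sample.int(30000, 25, replace = TRUE)
      data.frame(chrom = sample(c("chr1", "chr2"), 25, TRUE),
                 start = start, end = start + 100L)
    })
    expect_equal(tfbs_recall(q, r, 500), brute_recall(q, r, 500))
    expect_equal(tfbs_precision(r, q, 500), brute_precision(r, q, 500))
  }
})

test_that("F-score identities", {
  expect_equal(f_score(0.5, 0.5), 0.5)
  expect_equal(f_score(0, 0.8), 0)
  expect_equal(f_score(0, 0), 0)
  grid <- expand.grid(p = seq(0, 1, 0.25), r = seq(0, 1, 0.25))
  f <- f_score(grid$p, grid$r)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(f <= pmax(grid$p, grid$r) + 1e-12))
  expect_true(all((f == 0) == (grid$p * grid$r == 0)))
})

test_that("PR sweep starts unfiltered and shrinks monotonically", {
  cfg <- planted_config(n_tfs = 12, n_clusters = 2, tfs_per_cluster = 6,
                        complexes_per_cluster = 80, background_rate = 100)
  fx <- generate_filter_fixture(cfg, decoy_count = 300, seed = 5)
  g <- build_graph(fx$putative)
  sc <- sum_scores(cfg$target_tf, fx$putative, g)
  cur <- pr_sweep(sc, fx$actual, method = "sum")
  expect_equal(cur$cutoff[1], -Inf)
  # unfiltered row equals direct metrics on everything
  merged <- merge_overlapping(sc[, c("chrom", "start", "end")])
  expect_equal(cur$precision[1], tfbs_precision(merged, fx$actual, 1000))
  expect_equal(cur$recall[1], tfbs_recall(fx$actual, merged, 1000))
  expect_true(all(diff(cur$n_retained) <= 0))
  expect_true(all(diff(cur$recall) <= 1e-12))
  expect_true(all(cur$n_retained >= 1))
  b <- attr(cur, "max_f")
  expect_equal(b$f, max(cur$f))
  # filtering beats no filtering on planted data
  expect_gt(b$f, cur$f[1])
  # flipped direction sweeps retain-below
  curl <- pr_sweep(sc, fx$actual, method = "length", direction = "le")
  expect_equal(curl$cutoff[1], Inf)
  expect_true(all(diff(curl$n_retained) <= 0))
})

test_that("random baseline brackets score-based filtering", {
  cfg <- planted_config(n_tfs = 12, n_clusters = 2, tfs_per_cluster = 6,
                        complexes_per_cluster = 80, background_rate = 100)
  fx <- generate_filter_fixture(cfg, decoy_count = 300, seed = 6)
  g <- build_graph(fx$putative)
  sc <- sum_scores(cfg$target_tf, fx$putative, g)
  # n_remove = 0 reproduces the unfiltered metrics
  r0 <- random_baseline(sc, 0, seed = 1, fx$actual)
  cur <- pr_sweep(sc, fx$actual, method = "sum")
  expect_equal(r0$f, cur$f[1])
  expect_error(random_baseline(sc, nrow(sc), seed = 1, fx$actual),
               "undefined|all sites")
  expect_error(random_baseline(sc, -1, seed = 1, fx$actual), "range")
  # matched-removal random does worse than the score at max F
  b <- attr(cur, "max_f")
  rf <- mean(vapply(1:8, function(i)
    random_baseline(sc, nrow(sc) - b$n_retained, seed = i, fx$actual)$f,
    numeric(1)))
  expect_gt(b$f, rf)
})

test_that("length score is the neighbor count and correlates with sum score", {
  cfg <- planted_config(n_tfs = 12, n_clusters = 2, tfs_per_cluster = 6,
                        complexes_per_cluster = 80, background_rate = 100)
  fx <- generate_filter_fixture(cfg, decoy_count = 300, seed = 7)
  g <- build_graph(fx$putative)
  sc <- length_scores(cfg$target_tf, fx$putative, g)
  expect_true(all(sc$n_neighbors >= 0))
  expect_true(is.finite(stats::cor(sc$sum_score, sc$n_neighbors)))
})
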