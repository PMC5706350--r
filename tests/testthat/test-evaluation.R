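fake_filtered <- function(edges, tf_names) {
  structure(list(tf_names = tf_names, edges = edges,
                 threshold = 0, fpr_target = NULL,
                 n_filtered = 0L, pct_filtered = 0,
                 n_edges_total = length(tf_names) * (length(tf_names) + 1) / 2),
            class = "filtered_graph")
}

test_that("reference comparison counts the confusion matrix exactly", {
  tfs <- c("A", "B", "C", "D")
  edges <- data.frame(tf1 = c("A", "A", "B", "A"),
                      tf2 = c("B", "C", "C", "A"),   # incl. a self-loop
                      weight = c(0.5, 0.4, 0.3, 0.2))
  ref <- fake_reference(data.frame(x = c("A", "B", "B"),
                                   y = c("B", "C", "D")))
  cmp <- compare_to_reference(fake_filtered(edges, tfs), ref)
  # matched TFs: A,B,C,D; pairs: AB(tp) AC(fp) AD(tn) BC(tp) BD(fn) CD(tn)
  expect_equal(cmp$tp, 2)
  expect_equal(cmp$fp, 1)
  expect_equal(cmp$fn, 1)
  expect_equal(cmp$tn, 2)
  expect_equal(cmp$tp + cmp$fp + cmp$tn + cmp$fn, choose(4, 2))
  expect_equal(cmp$precision, 2 / 3)
  expect_equal(cmp$recall, 2 / 3)
  expect_equal(cmp$f_score, 2 / 3)

  # exhaustive enumeration oracle on random graphs
  for (s in 1:5) {
    all_pairs <- t(combn(tfs, 2))
    sel <- withr::with_seed(s, runif(nrow(all_pairs)) < 0.5)
    inref <- withr::with_seed(s + 9, runif(nrow(all_pairs)) < 0.5)
    if (!any(inref)) inref[1] <- TRUE
    e <- data.frame(tf1 = all_pairs[sel, 1], tf2 = all_pairs[sel, 2],
                    weight = 1)
    r <- fake_reference(data.frame(x = all_pairs[inref, 1],
                                   y = all_pairs[inref, 2]))
    r$tf_names <- tfs   # reference knows all four proteins
    cmp <- compare_to_reference(fake_filtered(e, tfs), r)
    expect_equal(cmp$tp, sum(sel & inref))
    expect_equal(cmp$fp, sum(sel & !inref))
    expect_equal(cmp$fn, sum(!sel & inref))
    expect_equal(cmp$tn, sum(!sel & !inref))
  }
})

test_that("edges equal to reference give perfect scores; none give zero", {
  tfs <- c("A", "B", "C")
  e <- data.frame(tf1 = c("A", "B"), tf2 = c("B", "C"), weight = 1)
  ref <- fake_reference(data.frame(x = c("A", "B"), y = c("B", "C")))
  cmp <- compare_to_reference(fake_filtered(e, tfs), ref)
  expect_equal(c(cmp$precision, cmp$recall, cmp$f_score), c(1, 1, 1))

  none <- fake_filtered(data.frame(tf1 = character(0), tf2 = character(0),
                                   weight = numeric(0)), tfs)
  expect_warning(cmp0 <- compare_to_reference(none, ref), "precision")
  expect_equal(c(cmp0$precision, cmp0$recall), c(0, 0))
  # unmatched TFs dropped; < 2 matched is an error
  lone <- fake_reference(data.frame(x = "A", y = "Z"))
  expect_error(compare_to_reference(fake_filtered(e, tfs), lone),
               "fewer than 2")
})

test_that("channel enrichment is calibrated under the null and powered", {
  tfs <- sprintf("P%02d", 1:40)
  pairs <- t(combn(tfs, 2))[1:400, ]
  mk_ref <- function(scores) {
    r <- fake_reference(data.frame(x = pairs[, 1], y = pairs[, 2]))
    r$channels[["Co-expression"]] <- scores
    r
  }
  predicted <- fake_filtered(
    data.frame(tf1 = pairs[1:200, 1], tf2 = pairs[1:200, 2], weight = 1), tfs)
  # null: matched and unmatched scores identically distributed
  pvals <- withr::with_seed(101, vapply(1:200, function(i) {
    ref <- mk_ref(stats::rexp(400, 1 / 300))
    channel_enrichment(predicted, ref, "Co-expression")$p_value
  }, numeric(1)))
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  # power: matched scores stochastically larger
  pow <- withr::with_seed(102, vapply(1:100, function(i) {
    sc <- stats::rexp(400, 1 / 300)
    sc[1:200] <- sc[1:200] + stats::rexp(200, 1 / 150)
    channel_enrichment(predicted, mk_ref(sc), "Co-expression")$p_value
  }, numeric(1)))
  expect_gte(mean(pow < 0.05), 0.95)
  # all scores tied: no evidence, p = 1
  ref_tied <- mk_ref(rep(100, 400))
  res <- channel_enrichment(predicted, ref_tied, "Co-expression")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, 0)
  expect_error(channel_enrichment(predicted, ref_tied, "NotAChannel"),
               "unknown channel")
})

test_that("similarity regression recovers OLS exactly", {
  tfs <- c("A", "B", "C", "D")
  W <- matrix(0, 4, 4, dimnames = list(tfs, tfs))
  sim <- data.frame(tf1 = c("A", "A", "A", "B", "B"),
                    tf2 = c("B", "C", "D", "C", "D"),
                    similarity = c(0.1, 0.3, 0.5, 0.7, 0.9),
                    n_scores = 1L)
  class(sim) <- c("similarity_table", "data.frame")
  # perfectly linear weights -> R^2 = 1
  wts <- 2 * sim$similarity - 0.3
  W[cbind(sim$tf1, sim$tf2)] <- wts
  W[cbind(sim$tf2, sim$tf1)] <- wts
  fit <- suppressWarnings(similarity_regression(fake_graph(W), sim))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, -0.3)

  # 5-pair hand data vs closed-form OLS
  wts <- c(0.12, -0.05, 0.4, 0.2, 0.33)
  W[cbind(sim$tf1, sim$tf2)] <- wts
  W[cbind(sim$tf2, sim$tf1)] <- wts
  fit <- similarity_regression(fake_graph(W), sim)
  x <- sim$similarity
  beta <- sum((x - mean(x)) * (wts - mean(wts))) / sum((x - mean(x))^2)
  alpha <- mean(wts) - beta * mean(x)
  ssr <- sum((wts - alpha - beta * x)^2)
  sst <- sum((wts - mean(wts))^2)
  expect_equal(fit$slope, beta)
  expect_equal(fit$intercept, alpha)
  expect_equal(fit$r_squared, 1 - ssr / sst)
  expect_equal(fit$n_pairs, 5L)

  # independent weights: R^2 near zero at n = 1000
  tfs2 <- sprintf("T%03d", 1:46)
  prs <- t(combn(tfs2, 2))[1:1000, ]
  sim2 <- data.frame(tf1 = prs[, 1], tf2 = prs[, 2],
                     similarity = withr::with_seed(3, stats::runif(1000)),
                     n_scores = 1L)
  class(sim2) <- c("similarity_table", "data.frame")
  W2 <- matrix(0, 46, 46, dimnames = list(tfs2, tfs2))
  wt2 <- withr::with_seed(4, stats::rnorm(1000, 0, 0.05))
  W2[cbind(sim2$tf1, sim2$tf2)] <- wt2
  W2[cbind(sim2$tf2, sim2$tf1)] <- wt2
  expect_lt(similarity_regression(fake_graph(W2), sim2)$r_squared, 0.02)

  # zero-variance similarity is rejected
  sim3 <- sim
  sim3$similarity <- 0.5
  expect_error(similarity_regression(fake_graph(W), sim3), "zero variance")
})
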