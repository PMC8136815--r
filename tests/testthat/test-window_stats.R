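test_that("rank-sum p-values match exact enumeration in small tie-free samples", {
  # the canonical 3-vs-2 case: only the observed assignment reaches U = 6
  res <- wilcoxon_rank_sum(c(3, 4, 5), c(1, 2), "greater")
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  # degenerate all-tied pooled sample: statistic sits at its null mean
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2), "greater")$p_value,
               0.5)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3),
                                 "two_sided")$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty sample")
})

test_that("exact p-values agree with the independent reference across all small partitions", {
  set.seed(90)
  for (nx in 1:6) {
    for (ny in 1:(10 - nx)) {
      if (ny < 1) next
      z <- sample(seq_len(100), nx + ny)  # tie-free
      x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
      for (alt in c("greater", "two_sided")) {
        ours <- wilcoxon_rank_sum(x, y, alt)
        ref <- stats::wilcox.test(x, y,
                                  alternative = sub("two_sided", "two.sided",
                                                    alt),
                                  exact = TRUE)
        expect_equal(ours$method, "exact")
        expect_equal(ours$p_value, ref$p.value,
                     info = sprintf("nx=%d ny=%d alt=%s", nx, ny, alt))
      }
    }
  }
})

test_that("the normal approximation stays within 0.02 of exact at n = 20 per group", {
  set.seed(91)
  for (rep in 1:25) {
    z <- sample(seq_len(10000), 40)  # tie-free
    x <- z[1:20]; y <- z[21:40]
    approx <- wilcoxon_rank_sum(x, y, "greater", exact_max_n = 0)$p_value
    exact <- stats::wilcox.test(x, y, alternative = "greater",
                                exact = TRUE)$p.value
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("tied samples reproduce the tie-corrected continuity-corrected reference", {
  set.seed(92)
  for (rep in 1:20) {
    x <- rpois(15, 0.7); y <- rpois(25, 0.5)
    ours <- wilcoxon_rank_sum(x, y, "greater")$p_value
    ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                               exact = FALSE,
                                               correct = TRUE))$p.value
    expect_equal(ours, ref)
  }
})

make_wcm <- function(counts, motif = "M", region = "R2", offsets = NULL) {
  offsets <- offsets %||% (0:(ncol(counts) - 1))
  structure(list(motif = motif, region = region, window_width = 50L,
                 step = 1L, window_offsets = offsets,
                 event_ids = sprintf("E%d", seq_len(nrow(counts))),
                 counts = counts),
            class = "window_count_matrix")
}

test_that("per-window enrichment p-values cover the whole window family", {
  set.seed(93)
  creg <- matrix(rpois(30 * 250, 0.3), nrow = 30)
  cbg <- matrix(rpois(60 * 250, 0.3), nrow = 60)
  ser <- enrichment_pvalues(make_wcm(creg), make_wcm(cbg))
  expect_s3_class(ser, "window_pvalue_series")
  expect_length(ser$pvalues, 250)
  expect_equal(ser$min_p, min(ser$pvalues))
  expect_equal(ser$min_p_window,
               ser$window_offsets[which.min(ser$pvalues)])
  # column-wise values equal the reference test column by column
  ref <- vapply(1:250, function(w)
    suppressWarnings(stats::wilcox.test(creg[, w], cbg[, w],
                                        alternative = "greater",
                                        exact = FALSE,
                                        correct = TRUE))$p.value, numeric(1))
  expect_equal(ser$pvalues, ref)
})

test_that("identical count distributions never look enriched", {
  set.seed(94)
  m <- matrix(rpois(40 * 100, 0.4), nrow = 40)
  ser <- enrichment_pvalues(make_wcm(m), make_wcm(m[sample(40), ]))
  expect_true(all(ser$pvalues >= 0.5))
  expect_error(enrichment_pvalues(make_wcm(m), make_wcm(m, region = "R3")),
               "disagree")
})

test_that("signal-bearing windows carry the minimum p-value", {
  # counts planted so that exactly columns 51..100 (offsets 51..100, the
  # windows containing a match at offset 100) separate the groups
  set.seed(95)
  creg <- matrix(rpois(50 * 250, 0.05), nrow = 50)
  cbg <- matrix(rpois(200 * 250, 0.05), nrow = 200)
  block <- 52:101
  creg[sample(50, 40), block] <- creg[sample(50, 40), block] + 1L
  ser <- enrichment_pvalues(make_wcm(creg), make_wcm(cbg))
  expect_true(ser$min_p_window %in% 51:100)
  expect_lt(ser$min_p, 1e-10)
})

test_that("label permutation yields super-uniform or uniform window p-values", {
  set.seed(96)
  pool <- rpois(60, 0.5)
  nperm <- 600
  pv <- numeric(nperm)
  for (b in seq_len(nperm)) {
    idx <- sample(60, 20)
    pv[b] <- wilcoxon_rank_sum(pool[idx], pool[-idx], "greater",
                               exact_max_n = 0)$p_value
  }
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(t * (1 - t) / nperm)
    expect_lte(mean(pv <= t), t + 3 * se)
  }
})

test_that("p-values are invariant under monotone transforms of the counts", {
  set.seed(97)
  x <- rpois(12, 1); y <- rpois(18, 1)
  p0 <- wilcoxon_rank_sum(x, y, "greater")$p_value
  expect_equal(wilcoxon_rank_sum(2 * x + 3, 2 * y + 3, "greater")$p_value, p0)
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y), "greater")$p_value, p0)
})

test_that("min-p summaries rank motifs ascending with name tie-breaks", {
  mk <- function(motif, minp, region = "R2") {
    pv <- rep(0.9, 10); pv[4] <- minp
    structure(list(motif = motif, region = region,
                   comparison = "regulated vs background",
                   window_offsets = 0:9, pvalues = pv, min_p = minp,
                   min_p_window = 3L),
              class = "window_pvalue_series")
  }
  tab <- summarize_min_p(list(mk("B", 0.3), mk("A", 1e-6), mk("C", 0.3)))
  expect_equal(tab$motif, c("A", "B", "C"))
  expect_equal(tab$min_p[1], 1e-6)
  expect_equal(nrow(summarize_min_p(list())), 0)
})
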