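test_that("overlap percentage follows the set-intersection definition", {
  expect_equal(overlap_pct(c(2, 3, 4, 5), c(3, 4, 5, 6, 7)), 75)
  expect_equal(overlap_pct(c(2, 3), 1:10), 100)
  expect_equal(overlap_pct(c(1, 2), c(5, 6)), 0)
  expect_error(overlap_pct(integer(0), 1:3), "nonempty")
})

test_that("random baseline matches the hypergeometric expectation", {
  w <- matrix(0, 10, 10)
  w[1, 2] <- w[2, 1] <- 1
  all_case <- patient_case("a", icto_network(w), resected = 1:10,
                           outcome = "good")
  bl <- random_baseline(all_case, suggested_size = 3, seed = 1)
  expect_equal(bl$mean, 100)
  expect_equal(bl$se, 0)
  none_case <- patient_case("b", icto_network(w), resected = integer(0),
                            outcome = "poor")
  bl0 <- random_baseline(none_case, suggested_size = 3, seed = 1)
  expect_equal(bl0$mean, 0)
  expect_equal(bl0$se, 0)
  half <- patient_case("c", icto_network(w), resected = 1:5,
                       outcome = "good")
  bl5 <- random_baseline(half, suggested_size = 2, n_samples = 4000, seed = 2)
  expect_equal(bl5$mean, 50, tolerance = 0.04) # E = 100 |R| / N
  expect_error(random_baseline(half, suggested_size = 11), "exceeds")
})

test_that("exact rank-sum p-values match full enumeration", {
  expect_equal(rank_sum_test(c(5, 6, 7), c(1, 2, 3))$p_value, 1 / 20)
  set.seed(9)
  for (i in 1:12) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- round(rnorm(n1), if (i <= 6) 3 else 0) # second half has ties
    y <- round(rnorm(n2), if (i <= 6) 3 else 0)
    for (alt in c("greater", "less")) {
      got <- rank_sum_test(x, y, alternative = alt)
      expect_true(got$exact)
      expect_equal(got$p_value, oracle_rank_sum_p(x, y, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- rnorm(7)
    got <- rank_sum_test(x, y, alternative = "greater")$p_value
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("rank-sum handles the cohort group sizes exactly and degenerate ties", {
  set.seed(11)
  g <- runif(13)
  p <- runif(7)
  res <- rank_sum_test(g, p)
  expect_true(res$exact) # 13 + 7 = 20 <= exact limit
  pg <- rank_sum_test(g, p, alternative = "greater")$p_value
  pl <- rank_sum_test(g, p, alternative = "less")$p_value
  expect_gte(pg + pl, 1) # inclusive tails under midranks
  expect_warning(tied <- rank_sum_test(rep(1, 4), rep(1, 5)), "tied")
  expect_equal(tied$p_value, 1)
  # large samples fall back to the tie-corrected normal approximation
  big <- rank_sum_test(rnorm(20, 1), rnorm(20))
  expect_false(big$exact)
  expect_lt(big$p_value, 0.05)
})

test_that("AUC equals the concordance count and the Mann-Whitney statistic", {
  r <- roc_analysis(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 3 / 4) # 3 concordant pairs of 4
  perfect <- roc_analysis(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$operating_point$sensitivity, 1)
  expect_equal(perfect$operating_point$specificity, 1)
  same <- roc_analysis(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$auc, 0.5)
  set.seed(12)
  scores <- rnorm(30)
  labels <- runif(30) > 0.5
  u <- wilcox.test(scores[labels], scores[!labels])$statistic
  expect_equal(roc_analysis(scores, labels)$auc,
               unname(u) / (sum(labels) * sum(!labels)))
  expect_error(roc_analysis(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with the pROC cross-check", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- c(rnorm(12, 1), rnorm(9))
  labels <- rep(c(TRUE, FALSE), c(12, 9))
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(roc_analysis(scores, labels)$auc, ref)
})

test_that("cohort evaluation aggregates per-case overlaps into group statistics", {
  w <- matrix(0, 12, 12)
  w[1, 2] <- w[2, 1] <- 1
  net <- icto_network(w)
  mk <- function(id, res, out, sugg) {
    patient_case(id, net, resected = res, outcome = out,
                 suggested_sets = sugg)
  }
  cases <- list(
    mk("g1", 1:4, "good", list(c(1L, 2L), c(4L, 5L))),
    mk("g2", 2:6, "good", list(c(2L, 3L))),
    mk("g3", 1:6, "good", list(c(5L, 6L))),
    mk("p1", 9:12, "poor", list(c(1L, 2L))),
    mk("p2", 8:12, "poor", list(c(1L, 2L))))
  ev <- evaluate_cohort(cases, seed = 1)
  expect_equal(nrow(ev$per_case), 5)
  expect_equal(ev$per_case$max_overlap_pct[1], 100)
  expect_equal(ev$per_case$min_overlap_pct[1], 50)
  expect_equal(ev$per_case$max_overlap_pct[4], 0)
  expect_true(ev$rank_sum$exact)
  expect_equal(ev$roc$auc, 1)
  # model overlap beats the random baseline where the suggestion aligns
  aligned <- ev$per_case$max_overlap_pct > 0
  expect_true(all(ev$per_case$max_overlap_pct[aligned] >
                  ev$per_case$baseline_mean[aligned]))
})
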