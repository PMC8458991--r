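test_that("top-1 accuracy counts argmax matches with index tie-breaks", {
  s <- matrix(c(0.9, 0.1,
                0.2, 0.8,
                0.5, 0.5), nrow = 3, byrow = TRUE)
  expect_equal(top1Accuracy(s, c(1, 2, 1)), 1)     # tie -> lowest index
  expect_equal(top1Accuracy(s, c(2, 1, 2)), 0)
  expect_equal(top1Accuracy(s, c(1, 1, 1)), 2 / 3)
  expect_error(top1Accuracy(s, c(1, 2)), "labels")
})

test_that("uniform random scores sit at chance on the 10-way task", {
  set.seed(123)
  n <- 4000
  s <- matrix(runif(n * 10), n, 10)
  acc <- top1Accuracy(s, sample.int(10, n, replace = TRUE))
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(acc - 0.1), 3 * se)
})

test_that("restricted top-1 implements the subset readout rule", {
  # true class wins within the allowed set though a disallowed class wins
  # globally
  s <- matrix(c(0.5, 0.1, 0.9,
                0.1, 0.6, 0.8), nrow = 2, byrow = TRUE)
  expect_equal(restrictedTop1(s, c(1, 2), c(1, 2)), 1)
  expect_equal(top1Accuracy(s, c(1, 2)), 0)
  # allowed set of size 1 is trivially perfect
  expect_equal(restrictedTop1(s, 2, c(2, 2)), 1)
  expect_error(restrictedTop1(s, c(1, 2), c(1, 3)), "outside")
  # brute-force oracle on a random 3-class-of-5 toy
  set.seed(9)
  scores <- matrix(rnorm(40 * 5), 40, 5)
  allowed <- c(2, 3, 5)
  labels <- sample(allowed, 40, replace = TRUE)
  brute <- mean(vapply(1:40, function(i) {
    best <- allowed[which.max(scores[i, allowed])]
    best == labels[i]
  }, logical(1)))
  expect_equal(restrictedTop1(scores, allowed, labels), brute)
})

test_that("Wilson interval matches the score-test inversion", {
  expect_equal(binomialCI(0, 10)[["low"]], 0)
  expect_equal(binomialCI(10, 10)[["high"]], 1)
  for (case in list(c(5, 10), c(1, 7), c(19, 20), c(50, 300))) {
    ci <- binomialCI(case[1], case[2])
    oracle <- suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE))$conf.int
    expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-10)
    expect_lte(ci[["low"]], case[1] / case[2])
    expect_gte(ci[["high"]], case[1] / case[2])
  }
  expect_error(binomialCI(5, 4), "k <= n")
})

test_that("consistent-category selection applies the absolute band", {
  acc <- c(a = 0.60, b = 0.70, c = 0.80, d = 0.62, e = 0.65)
  acc2 <- c(acc, f = 0.95)  # mean 0.72; f deviates 0.23 -> excluded
  sel <- selectConsistentCategories(acc2, k = 5, tolerance = 0.15)
  expect_false("f" %in% sel)
  expect_identical(length(sel), 5L)
  # absolute reading: mean 0.60, class at 0.80 excluded, 0.70 included
  acc3 <- c(rep(0.6, 8), 0.7, 0.8)
  acc3 <- acc3 - (mean(acc3) - 0.60)  # recenter exactly at 0.60
  sel3 <- selectConsistentCategories(acc3, k = 9, tolerance = 0.15)
  expect_false(10 %in% sel3)
  expect_true(9 %in% sel3)
  # all identical accuracies all qualify
  expect_identical(selectConsistentCategories(rep(0.5, 10), k = 10), 1:10)
  expect_error(selectConsistentCategories(c(0, 1, 0.5), k = 3,
                                          tolerance = 0.1), "within")
  # brute-force equivalence on a synthetic 20-class vector
  set.seed(17)
  a20 <- runif(20, 0.3, 0.9)
  dev <- abs(a20 - mean(a20))
  qual <- which(dev <= 0.15)
  brute <- sort(qual[order(dev[qual], qual)][seq_len(8)])
  expect_identical(selectConsistentCategories(a20, 8, 0.15), brute)
})

test_that("per-level evaluation reports bracketed intervals per pool", {
  m <- smallCNN(16, 3, conv_widths = c(2, 3, 3), hidden = 5, seed = 7)
  set.seed(8)
  mkpool <- function(n) list(x = array(runif(16 * 16 * n), c(16, 16, n)),
                             y = rep_len(1:3, n))
  pools <- list(SFL1 = mkpool(9), UF = mkpool(12))
  rep_ <- evaluateAcrossLevels(m, pools, metadata = list(regime = "full"))
  expect_identical(nrow(rep_), 2L)
  expect_true(all(rep_$ci_low <= rep_$accuracy))
  expect_true(all(rep_$ci_high >= rep_$accuracy))
  expect_identical(attr(rep_, "regime"), "full")
  # nested splits and empty pools
  pools2 <- list(SFL1 = list(train = mkpool(6), val = mkpool(6)),
                 UF = mkpool(0))
  expect_warning(rep2 <- evaluateAcrossLevels(m, pools2), "empty pool")
  expect_identical(nrow(rep2), 3L)
  expect_true(is.na(rep2$accuracy[rep2$level == "UF"]))
})

test_that("label-shuffled models sit at chance across the report", {
  ds <- generateDataset(
    suppressWarnings(synthSpec(n_classes = 5, images_per_class = 40,
                               seed = 19)))
  m <- smallCNN(64, 5, conv_widths = c(2, 4, 4), hidden = 8, seed = 20)
  set.seed(21)
  y_shuf <- sample(as.integer(ds@labels))
  acc <- top1Accuracy(modelPredict(m, ds@images), y_shuf)
  n <- length(y_shuf)
  expect_lt(abs(acc - 1 / 5), 3 * sqrt(0.2 * 0.8 / n))
})
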