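test_that("regime tables reproduce all 15 regime-by-stage proportion cells", {
  # canonical table: proportions per stage over SFL1..SFL4, UF
  expected <- list(
    full = lapply(1:5, function(i) c(0, 0, 0, 0, 1)),
    gradual = lapply(1:5, function(i) as.numeric(seq_len(5) == i)),
    mixed = list(c(1, 0, 0, 0, 0),
                 c(1 / 2, 1 / 2, 0, 0, 0),
                 c(1 / 4, 1 / 4, 1 / 2, 0, 0),
                 c(1 / 6, 1 / 6, 1 / 6, 1 / 2, 0),
                 c(1 / 8, 1 / 8, 1 / 8, 1 / 8, 1 / 2)))
  for (rg in names(expected)) {
    sched <- regimeTable(rg)
    for (k in 1:5) {
      expect_equal(unname(sched@stages[[k]]), expected[[rg]][[k]],
                   tolerance = 1e-15,
                   label = paste(rg, "stage", k))
      expect_equal(sum(sched@stages[[k]]), 1, tolerance = 1e-15)
    }
  }
  expect_error(regimeTable("other"))
})

test_that("stage lookup maps epochs to the right proportions", {
  mx <- regimeTable("mixed")
  expect_equal(unname(proportionsAt(mx, 150)),
               c(1 / 2, 1 / 2, 0, 0, 0))
  gr <- regimeTable("gradual")
  expect_equal(unname(proportionsAt(gr, 450)), c(0, 0, 0, 0, 1))
  expect_equal(proportionsAt(mx, 1), mx@stages[[1]])
  expect_equal(proportionsAt(mx, 100), mx@stages[[1]])
  expect_equal(proportionsAt(mx, 101), mx@stages[[2]])
  expect_equal(proportionsAt(mx, 500), mx@stages[[5]])
  expect_error(proportionsAt(mx, 0))
  expect_error(proportionsAt(mx, 501))
})

test_that("learning-rate schedule steps at 80% and 90% of training", {
  sched <- regimeTable("full")  # 500 epochs
  expect_identical(lrAt(sched, 1), 0.5)
  expect_identical(lrAt(sched, 400), 0.5)
  expect_identical(lrAt(sched, 401), 0.1)
  expect_identical(lrAt(sched, 450), 0.1)
  expect_identical(lrAt(sched, 451), 0.01)
  expect_identical(lrAt(sched, 500), 0.01)
  # scaled run keeps the fractional breakpoints
  s20 <- regimeTable("full", stage_length = 4L)
  expect_identical(lrAt(s20, 16), 0.5)
  expect_identical(lrAt(s20, 17), 0.1)
  expect_identical(lrAt(s20, 19), 0.01)
  # non-increasing over the whole run
  lrs <- vapply(1:500, function(e) lrAt(sched, e), numeric(1))
  expect_true(all(diff(lrs) <= 0))
  expect_error(lrAt(sched, 501))
})

test_that("largest-remainder apportionment is exact and deterministic", {
  p5 <- stats::setNames(c(1 / 2, 1 / 2, 0, 0, 0),
                        c("SFL1", "SFL2", "SFL3", "SFL4", "UF"))
  expect_equal(unname(apportionBatch(p5, 192)), c(96, 96, 0, 0, 0))
  p8 <- stats::setNames(c(1 / 8, 1 / 8, 1 / 8, 1 / 8, 1 / 2),
                        names(p5))
  expect_equal(unname(apportionBatch(p8, 192)), c(24, 24, 24, 24, 96))
  # remainders go to the largest fractional parts, ties by level order
  p3 <- stats::setNames(c(1 / 3, 1 / 3, 1 / 3), c("a", "b", "c"))
  expect_equal(sum(apportionBatch(p3, 32)), 32)
  expect_equal(unname(apportionBatch(p3, 32)), c(11, 11, 10))
  expect_error(apportionBatch(c(0.5, 0.6), 10), "sum to 1")
})

toyPools <- function(n_per_level = 12, size = 8, seed = 5) {
  set.seed(seed)
  lv <- c("SFL1", "SFL2", "SFL3", "SFL4", "UF")
  stats::setNames(lapply(lv, function(l) {
    list(x = array(runif(size * size * n_per_level),
                   c(size, size, n_per_level)),
         y = rep_len(1:2, n_per_level))
  }), lv)
}

test_that("batch composition respects proportions and seeding", {
  pools <- toyPools()
  props <- stats::setNames(c(0.5, 0.5, 0, 0, 0),
                           c("SFL1", "SFL2", "SFL3", "SFL4", "UF"))
  set.seed(11)
  b1 <- composeBatch(pools, props, 8)
  expect_equal(unname(b1$counts[c("SFL1", "SFL2")]), c(4, 4))
  expect_identical(dim(b1$x)[3], 8L)
  set.seed(11)
  b2 <- composeBatch(pools, props, 8)
  expect_identical(b1$x, b2$x)
  expect_identical(b1$y, b2$y)
  # a required level with an empty pool is a configuration error
  broken <- pools
  broken$SFL2$x <- broken$SFL2$x[, , 0, drop = FALSE]
  expect_error(composeBatch(broken, props, 8), "SFL2")
})

test_that("without-replacement draws cover each pool before repeating", {
  pools <- toyPools(n_per_level = 10)
  props <- stats::setNames(c(1, 0, 0, 0, 0),
                           c("SFL1", "SFL2", "SFL3", "SFL4", "UF"))
  set.seed(2)
  st <- NULL
  seen <- integer()
  for (i in 1:2) {
    b <- composeBatch(pools, props, 5, st)
    st <- b$state
    # map drawn images back to pool indices via exact matching
    idx <- apply(b$x, 3, function(img)
      which(apply(pools$SFL1$x, 3, function(p) identical(p, img))))
    seen <- c(seen, idx)
  }
  expect_identical(sort(seen), 1:10)  # one full epoch pass, no repeats
})

test_that("curriculum training produces a well-formed, reproducible history", {
  ds <- generateDataset(
    suppressWarnings(synthSpec(n_classes = 3, images_per_class = 12,
                               seed = 8)))
  pools <- makeLevelPools(ds, 8, 4, 0)
  sched <- regimeTable("full", stage_length = 2L)  # 10 epochs
  cfg <- trainingConfig(batch_size = 8, steps_per_epoch = 4,
                        initial_lr = 0.02, seed = 31)
  model <- smallCNN(64, 3, conv_widths = c(4, 8, 8), hidden = 16, seed = 32)
  fit <- suppressMessages(trainCurriculum(model, sched, cfg,
    list(train = pools$train, val = pools$val)))
  h <- fit$history
  expect_identical(nrow(h), 10L)
  expect_true(all(c("train_acc", paste0("val_", sflBank()$label)) %in%
                    names(h)))
  expect_true(all(h$lr[1:8] == 0.02))
  expect_equal(h$lr[9], 0.004)
  # double run determinism
  fit2 <- suppressMessages(trainCurriculum(model, sched, cfg,
    list(train = pools$train, val = pools$val)))
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model@weights, fit2$model@weights)
  # a zero-epoch schedule is a no-op
  s0 <- regimeTable("full", stage_length = 2L, total_epochs = 0L)
  fit0 <- trainCurriculum(model, s0, cfg,
                          list(train = pools$train, val = pools$val))
  expect_identical(fit0$model@weights, model@weights)
  expect_identical(nrow(fit0$history), 0L)
})
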