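test_that("RDM entries equal one minus rank correlation", {
  acts <- rbind(c(1, 2, 3, 4, 5),
                c(2, 4, 6, 8, 10),   # same rank order as row 1
                c(5, 4, 3, 2, 1))    # exactly reversed ranks
  r <- rdmFromActivations(acts)
  v <- rdmValues(r)
  expect_equal(v[1, 2], 0, tolerance = 1e-12)
  expect_equal(v[1, 3], 2, tolerance = 1e-12)
  expect_true(isSymmetric(unname(v)))
  expect_true(all(diag(v) == 0))
  # brute-force rank-then-product-moment oracle on a random fixture
  set.seed(31)
  a <- matrix(rnorm(15), 3, 5)
  v2 <- rdmValues(rdmFromActivations(a))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(v2[i, j], 1 - spearmanOracle(a[i, ], a[j, ]),
                 tolerance = 1e-12)
  expect_error(rdmFromActivations(rbind(c(1, 1, 1), c(1, 2, 3))),
               "constant activation.*1")
  expect_error(rdmFromActivations(matrix(1:4, 4, 1)), "2 units")
})

test_that("RDMs are rank-invariant under monotone activation scalings", {
  set.seed(32)
  acts <- matrix(rnorm(8 * 10), 8, 10)
  base <- rdmValues(rdmFromActivations(acts))
  warped <- t(apply(acts, 1, function(r) exp(1.7 * r) + 3))
  expect_equal(rdmValues(rdmFromActivations(warped)), base,
               tolerance = 1e-12)
})

test_that("RDM comparison uses the strictly-upper triangle", {
  set.seed(33)
  acts <- matrix(rnorm(4 * 6), 4, 6)
  a <- rdmFromActivations(acts)
  expect_equal(rdmCompare(a, a), 1)
  va <- rdmValues(a)
  # oracle over the 6 upper-triangle pairs
  b <- matrix(runif(16), 4, 4); b <- (b + t(b)) / 2; diag(b) <- 0
  ut <- upper.tri(va)
  expect_equal(rdmCompare(a, b), spearmanOracle(va[ut], b[ut]),
               tolerance = 1e-12)
  # rank reversal of the triangle gives -1
  rev_ <- max(va) - va; diag(rev_) <- 0
  expect_equal(rdmCompare(a, rev_), -1, tolerance = 1e-12)
  expect_error(rdmCompare(a, matrix(0, 3, 3)), "mismatch")
  expect_error(rdmCompare(matrix(1, 4, 4) - diag(4),
                          matrix(1, 4, 4) - diag(4)), "variance")
})

test_that("permutation p matches exhaustive enumeration on 4 images", {
  set.seed(34)
  acts <- matrix(rnorm(4 * 7), 4, 7)
  model <- rdmValues(rdmFromActivations(acts))
  target <- matrix(runif(16), 4, 4); target <- (target + t(target)) / 2
  diag(target) <- 0
  rho_obs <- rdmCompare(model, target)
  perms <- allPermutations(4L)
  rhos <- vapply(perms, function(p) rdmCompare(model[p, p], target),
                 numeric(1))
  p_exact <- mean(rhos > rho_obs)
  set.seed(35)
  pt <- permutationTestRDM(model, target, n_perm = 4000)
  expect_equal(pt$rho, rho_obs, tolerance = 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(pt$p - p_exact), max(3 * se, 0.015))
  # self-comparison under the strict rule gives rho 1, p 0
  set.seed(36)
  ptself <- permutationTestRDM(model, model, n_perm = 300)
  expect_equal(ptself$rho, 1)
  expect_identical(ptself$p, 0)
  expect_gt(ptself$p_conventional, 0)
  # seeded determinism
  set.seed(37); p1 <- permutationTestRDM(model, target, n_perm = 500)$p
  set.seed(37); p2 <- permutationTestRDM(model, target, n_perm = 500)$p
  expect_identical(p1, p2)
})

test_that("bootstrap SD collapses to zero for identical RDMs", {
  set.seed(38)
  acts <- matrix(rnorm(6 * 8), 6, 8)
  r <- rdmFromActivations(acts)
  bs <- suppressMessages(bootstrapSdRDM(r, r, n_boot = 200))
  expect_equal(bs$sd, 0, tolerance = 1e-12)
  expect_equal(bs$mean_rho, 1, tolerance = 1e-12)
})

test_that("bootstrap SD agrees with an independent reimplementation", {
  set.seed(39)
  acts <- matrix(rnorm(6 * 9), 6, 9)
  model <- rdmValues(rdmFromActivations(acts))
  target <- matrix(runif(36), 6, 6); target <- (target + t(target)) / 2
  diag(target) <- 0
  # independent replicate loop written from scratch
  oracleBoot <- function(nb) {
    out <- numeric(nb); i <- 1
    while (i <= nb) {
      idx <- sample.int(6, 6, replace = TRUE)
      if (length(unique(idx)) < 3) next
      keep <- upper.tri(model) & outer(idx, idx, "!=")
      va <- model[idx, idx][keep]; vb <- target[idx, idx][keep]
      if (max(va) == min(va) || max(vb) == min(vb)) next
      out[i] <- spearmanOracle(va, vb)
      i <- i + 1
    }
    sd(out)
  }
  set.seed(40); sd_oracle <- oracleBoot(4000)
  set.seed(41)
  bs <- suppressMessages(bootstrapSdRDM(model, target, n_boot = 4000))
  expect_lt(abs(bs$sd - sd_oracle) / sd_oracle, 0.1)
  expect_gte(bs$sd, 0)
})

test_that("activation extraction maps RSA layer tags onto the model", {
  m <- smallCNN(16, 3, conv_widths = c(2, 4, 4), hidden = 8, seed = 42)
  x <- array(runif(16 * 16 * 5), c(16, 16, 5))
  fc <- extractActivations(m, x, "final_fc")
  expect_identical(dim(fc), c(5L, 8L))
  mid <- extractActivations(m, x, "mid_conv")
  expect_identical(dim(mid), c(5L, 4L * 4L * 4L))
  expect_identical(fc, modelActivations(m, x, "hidden"))
  expect_identical(mid, modelActivations(m, x, "conv2"))
})

test_that("pixel observers track their own conceptual model", {
  spec <- suppressWarnings(synthSpec(seed = 43, images_per_class = 1))
  src <- generateHybridSources(spec)
  hs <- buildHybridSet(src$lsf_sources, src$hsf_sources, src$shared_low,
                       src$shared_high)
  lsf_model <- conceptualRDM(hs$layout, "LSF")
  hsf_model <- conceptualRDM(hs$layout, "HSF")
  low_rdm <- rdmFromActivations(pixelObserver(hs$images, "low"))
  high_rdm <- rdmFromActivations(pixelObserver(hs$images, "high"))
  r_ll <- rdmCompare(low_rdm, lsf_model)
  r_lh <- rdmCompare(low_rdm, hsf_model)
  r_hh <- rdmCompare(high_rdm, hsf_model)
  r_hl <- rdmCompare(high_rdm, lsf_model)
  expect_gt(r_ll, 0.5)
  expect_gt(r_hh, 0.5)
  expect_lt(r_lh, r_ll)
  expect_lt(r_hl, r_hh)
})
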