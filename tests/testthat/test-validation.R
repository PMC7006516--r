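test_that("LOO validation on near-identical shapes is near-perfect", {
  tpl <- small_pipeline()$tpl$mesh
  copies <- list(tpl, tpl, tpl, tpl, tpl)
  corr <- build_correspondence(copies)
  rec <- suppressWarnings(loo_cross_validate(corr, "full", voxel_size = 0.8))
  expect_identical(nrow(rec), 5L)
  expect_true(all(rec$jaccard > 0.98))
  expect_true(all(rec$rmse < 1e-4))
  expect_true(all(rec$hausdorff < 1e-3))
})

test_that("LOO produces one record per subject with both fitting modes", {
  fx <- small_pipeline()
  full <- suppressWarnings(loo_cross_validate(fx$corr, "full"))
  sparse <- suppressWarnings(loo_cross_validate(fx$corr, "sparse"))
  expect_identical(nrow(full), 8L)
  expect_identical(nrow(sparse), 8L)
  expect_true(all(full$jaccard >= 0 & full$jaccard <= 1))
  expect_true(all(full$rmse <= full$hausdorff))
  expect_true(all(sparse$rmse <= sparse$hausdorff))
  expect_identical(unique(sparse$k), 3L)
  expect_setequal(full$subject, fx$corr$ids)
})

test_that("LOO accuracy improves with mode count up to the generating count", {
  fx <- small_pipeline()
  rmse_k <- vapply(1:4, function(k)
    mean(suppressWarnings(loo_cross_validate(fx$corr, "full", k = k))$rmse),
    numeric(1))
  expect_lt(rmse_k[2], rmse_k[1])
  expect_lt(rmse_k[3], rmse_k[2])
  # plateau after the generating count (3 modes): no comparable further gain
  expect_lt(abs(rmse_k[4] - rmse_k[3]), 0.5 * (rmse_k[2] - rmse_k[3]))
})

test_that("paired signed-rank test matches the exact enumeration oracle", {
  # n = 10, all differences positive
  set.seed(70)
  x <- runif(10, 1, 2)
  y <- x - runif(10, 0.05, 0.4)
  res <- paired_signed_rank(x, y)
  expect_true(res$exact)

  # enumeration oracle over all 2^10 sign assignments of the rank statistic
  r <- rank(abs(x - y))
  v_obs <- sum(r[(x - y) > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  v_all <- signs %*% r
  p_oracle <- min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 / 1024, tolerance = 1e-12)

  # identical pairs: degenerate case reported, not an error
  z <- paired_signed_rank(x, x)
  expect_identical(z$p_value, 1)
  expect_true(z$all_zero)
})

test_that("summaries reproduce spreadsheet-style means and SDs exactly", {
  fx <- small_pipeline()
  full <- suppressWarnings(loo_cross_validate(fx$corr, "full", k = 3))
  sparse <- suppressWarnings(loo_cross_validate(fx$corr, "sparse"))
  s <- summarize_and_compare(full, sparse)
  expect_identical(s$table$metric, c("jaccard", "rmse", "hausdorff"))
  expect_equal(s$table$full_mean[2], sum(full$rmse) / nrow(full), tolerance = 1e-12)
  expect_equal(s$table$sparse_sd[1],
               sqrt(sum((sparse$jaccard - mean(sparse$jaccard))^2) /
                      (nrow(sparse) - 1)),
               tolerance = 1e-12)
  expect_true(all(s$table$n == 8))
  expect_true(all(s$table$p_value >= 0 & s$table$p_value <= 1))
  expect_output(print(s), "mean \\(SD\\)")
})
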