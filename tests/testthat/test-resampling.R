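test_that("gene-set test: whole-universe target and constructed extremes", {
  cvs <- tibble::tibble(gene_id = sprintf("g%04d", 1:200),
                        mean_cv = rlnorm(200, -1, 0.3))
  all_genes <- geneset_variability_test(cvs, cvs$gene_id, n_boot = 500,
                                        seed = 1)
  expect_equal(all_genes$empirical_p, 1)
  expect_equal(all_genes$observed, mean(cvs$mean_cv))

  # 13 high-CV genes among 987 low-CV: observed exceeds every null draw
  cvs2 <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000),
                         mean_cv = c(rep(10, 13), rep(1, 987)))
  res <- geneset_variability_test(cvs2, cvs2$gene_id[1:13], n_boot = 2000,
                                  seed = 2)
  expect_equal(res$observed, 10)
  expect_equal(res$empirical_p, 1 / 2001)
  expect_true(res$significant)

  expect_error(geneset_variability_test(cvs, c("g0001", "nope"), 500, seed = 1),
               class = "telonoise_error_identifier")
})

test_that("resampling results expose quantiles, add-one p and tidy methods", {
  cvs <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                        mean_cv = runif(100))
  res <- geneset_variability_test(cvs, cvs$gene_id[1:5], n_boot = 1000,
                                  seed = 3)
  expect_s3_class(res, "telonoise_resample")
  expect_gte(res$empirical_p, 1 / 1001)
  expect_true(all(diff(res$null_quantiles) >= 0))
  td <- tidy(res)
  expect_equal(nrow(td), 1)
  expect_equal(td$observed, res$observed)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("gene-set test is invariant to the row order of the universe", {
  cvs <- tibble::tibble(gene_id = sprintf("g%03d", 1:80),
                        mean_cv = runif(80))
  a <- geneset_variability_test(cvs, cvs$gene_id[1:7], n_boot = 500, seed = 9)
  b <- geneset_variability_test(cvs[sample.int(80), ], cvs$gene_id[1:7],
                                n_boot = 500, seed = 9)
  expect_equal(a$empirical_p, b$empirical_p)
  expect_equal(a$null_quantiles, b$null_quantiles)
})

test_that("CV-ratio test: identity ratio, power on a constructed 3x contrast", {
  set.seed(4)
  a <- rnorm(150, 100, 10)
  same <- cv_ratio_test(a, a, n_boot = 200, seed = 5)
  expect_equal(same$observed, 1)
  b <- rnorm(150, 100, 30)  # CV 3x that of a
  res <- cv_ratio_test(a, b, n_boot = 2000, seed = 6)
  expect_gt(res$observed, 2.5)
  expect_lte(res$empirical_p, 0.001)
  expect_error(cv_ratio_test(rep(1, 10), a, n_boot = 200, seed = 1),
               class = "telonoise_error_degenerate")
})

test_that("pedigree test: identical populations give p = 1", {
  cells <- tidyr::expand_grid(pair = sprintf("p%02d", 1:5),
                              role = c("mother", "daughter"),
                              cell = 1:10) |>
    dplyr::mutate(pedigree_pair_id = pair, channel1_intensity = 50)
  res <- pedigree_permutation_test(cells, n_perm = 500, seed = 7)
  expect_equal(res$observed, 0)
  expect_equal(res$empirical_p, 1)
})

test_that("pedigree test: well-separated constant pairs are maximally similar", {
  levels <- 2^(1:10) * 10
  cells <- purrr::map(1:10, function(i) {
    tidyr::expand_grid(role = c("mother", "daughter"), cell = 1:10) |>
      dplyr::mutate(pedigree_pair_id = sprintf("p%02d", i),
                    channel1_intensity = levels[i])
  }) |> dplyr::bind_rows()
  res <- pedigree_permutation_test(cells, n_perm = 999, seed = 8)
  expect_equal(res$observed, 0)
  n_identity <- sum(res$null == 0)
  expect_equal(res$empirical_p, (1 + n_identity) / 1000)
  expect_lte(res$empirical_p, 0.01)
  expect_true(res$significant)
})

test_that("pedigree test excludes nonpositive intensities with a message", {
  cells <- tidyr::expand_grid(pair = sprintf("p%02d", 1:3),
                              role = c("mother", "daughter"), cell = 1:5) |>
    dplyr::mutate(pedigree_pair_id = pair,
                  channel1_intensity = ifelse(cell == 1, 0, 20))
  expect_message(pedigree_permutation_test(cells, n_perm = 100, seed = 9),
                 "non-positive")
})

test_that("subsampling is deterministic, order-preserving and unbiased for the CV", {
  p <- quiet_params()
  cells <- make_telegraph_population(p, 200, seed = 10)
  expect_identical(subsample_cells(cells, 200, seed = 1), cells)
  s1 <- subsample_cells(cells, 50, seed = 2)
  s2 <- subsample_cells(cells, 50, seed = 2)
  expect_identical(s1$cell_id, s2$cell_id)
  expect_identical(s1$cell_id, sort(s1$cell_id))  # original order kept
  # row-order invariance: shuffled input selects the same cells
  shuf <- cells[sample.int(200), ]
  s3 <- subsample_cells(shuf, 50, seed = 2)
  expect_setequal(s3$cell_id, s1$cell_id)
  expect_error(subsample_cells(cells, 300, seed = 1),
               class = "telonoise_error_insufficient_data")
  full_cv <- coefficient_of_variation(cells$channel1_intensity)
  set.seed(11)
  cv_est <- replicate(300, {
    s <- subsample_cells(cells, 50, seed = sample.int(1e8, 1))
    coefficient_of_variation(s$channel1_intensity)
  })
  expect_lt(abs(mean(cv_est) - full_cv) / full_cv, 0.1)
})

test_that("empirical p-values never reach zero and honour the add-one floor", {
  cvs <- tibble::tibble(gene_id = sprintf("g%03d", 1:50),
                        mean_cv = c(100, runif(49)))
  res <- geneset_variability_test(cvs, "g001", n_boot = 200, seed = 12)
  expect_gte(res$empirical_p, 1 / 201)
  expect_gt(res$empirical_p, 0)
})
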