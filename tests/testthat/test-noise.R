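test_that("perfectly correlated reporters have zero intrinsic noise", {
  x <- rlnorm(500, 0, 0.4)
  cells <- tibble::tibble(population_id = "p", channel1_intensity = x,
                          channel2_intensity = x)
  d <- decompose_noise(cells)
  expect_equal(d$eta_int2, 0, tolerance = 1e-14)
  g <- x / mean(x)
  expect_equal(d$eta_ext2, mean(g^2) - 1)  # variance of the common signal
  expect_equal(d$eta_tot2, d$eta_int2 + d$eta_ext2)
})

test_that("independent channels have near-zero extrinsic noise", {
  set.seed(3)
  cells <- tibble::tibble(
    population_id = "p",
    channel1_intensity = rlnorm(50000, 0, 0.3),
    channel2_intensity = rlnorm(50000, 0, 0.3)
  )
  d <- suppressWarnings(decompose_noise(cells))
  expect_lt(abs(d$eta_ext2), 0.01)
  expect_equal(d$eta_int2, d$eta_tot2, tolerance = 0.05)
})

test_that("decomposition equals the brute-force second-moment oracle to 1e-12", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    c1 <- rlnorm(n, 2, 0.5)
    c2 <- rlnorm(n, 1, 0.5) * (0.5 + runif(1)) + 0.3 * c1
    d <- suppressWarnings(decompose_noise(
      tibble::tibble(channel1_intensity = c1, channel2_intensity = c2)))
    o <- oracle_decompose(c1, c2)
    expect_equal(d$eta_int2, o$eta_int2, tolerance = 1e-12)
    expect_equal(d$eta_ext2, o$eta_ext2, tolerance = 1e-12)
    expect_equal(d$eta_tot2, o$eta_tot2, tolerance = 1e-12)
  }
})

test_that("decomposition is invariant to channel swap and per-channel scaling", {
  set.seed(5)
  c1 <- rlnorm(300, 0, 0.3)
  c2 <- 0.6 * c1 + rlnorm(300, -1, 0.3)
  base <- decompose_noise(tibble::tibble(channel1_intensity = c1,
                                         channel2_intensity = c2))
  swapped <- decompose_noise(tibble::tibble(channel1_intensity = c2,
                                            channel2_intensity = c1))
  expect_equal(swapped$eta_int2, base$eta_int2)
  expect_equal(swapped$eta_ext2, base$eta_ext2)
  scaled <- decompose_noise(tibble::tibble(channel1_intensity = 13 * c1,
                                           channel2_intensity = c2))
  expect_equal(scaled$eta_int2, base$eta_int2)
  expect_equal(scaled$eta_ext2, base$eta_ext2)
})

test_that("two-allele telegraph populations recover configured noise components", {
  p <- telegraph_params(k_on = 1, k_off = 1, mu_on = 140, mu_off = 60,
                        cv_intrinsic = 0.2, sigma_extrinsic = 0.25,
                        cv_measurement = 0)
  truth <- telegraph_noise_components(p)
  cells <- make_telegraph_population(p, 10000, seed = 101, n_alleles = 2)
  d <- decompose_noise(cells)
  expect_lt(abs(d$eta_int2 - truth$eta_int2) / truth$eta_int2, 0.15)
  expect_lt(abs(d$eta_ext2 - truth$eta_ext2) / truth$eta_ext2, 0.15)
})

test_that("channel correlation: exact limits and type-I control", {
  x <- rlnorm(100)
  expect_equal(channel_correlation(
    tibble::tibble(channel1_intensity = x, channel2_intensity = x))$estimate, 1)
  expect_equal(channel_correlation(
    tibble::tibble(channel1_intensity = x,
                   channel2_intensity = -2 * x + 10))$estimate, -1)
  expect_error(channel_correlation(
    tibble::tibble(channel1_intensity = rep(1, 10),
                   channel2_intensity = rlnorm(10))),
    class = "telonoise_error_degenerate")
  set.seed(21)
  rejections <- replicate(1000, {
    ct <- cor.test(rnorm(1000), rnorm(1000))
    ct$p.value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("paired component test handles exact and degenerate cases", {
  eq <- tibble::tibble(population_id = letters[1:5],
                       eta_int2 = c(1, 2, 3, 4, 5) / 10,
                       eta_ext2 = c(1, 2, 3, 4, 5) / 10)
  eq$eta_tot2 <- eq$eta_int2 + eq$eta_ext2
  r <- paired_component_test(eq)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  sep <- tibble::tibble(population_id = sprintf("p%02d", 1:12),
                        eta_int2 = 0.5, eta_ext2 = 0.2)
  sep$eta_tot2 <- sep$eta_int2 + sep$eta_ext2
  r2 <- paired_component_test(sep)
  expect_equal(r2$df, 11)
  expect_true(is.infinite(r2$statistic) && r2$statistic > 0)
  expect_lte(r2$p.value, .Machine$double.xmin)
  expect_error(paired_component_test(sep[1, ]),
               class = "telonoise_error_insufficient_data")
})

test_that("intrinsic-dominant regimes are detected by the paired test", {
  # true intrinsic fraction ~0.8 via strong per-allele noise, weak extrinsic
  p <- telegraph_params(mu_on = 100, mu_off = 5, cv_intrinsic = 0.45,
                        sigma_extrinsic = 0.22, cv_measurement = 0,
                        lock_mode = "locked_on")
  comp <- telegraph_noise_components(p)
  expect_gt(comp$eta_int2 / comp$eta_tot2, 0.75)
  set.seed(31)
  rejects <- replicate(200, {
    cells <- purrr::map(1:12, function(i) {
      make_telegraph_population(p, 50, seed = sample.int(1e8, 1),
                                n_alleles = 2,
                                population_id = sprintf("pop%02d", i))
    }) |> dplyr::bind_rows()
    d <- suppressWarnings(decompose_noise(cells))
    t <- paired_component_test(d)
    t$p.value < 0.05 & t$statistic > 0
  })
  expect_gte(mean(rejects), 0.95)
})
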