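# Expression-matrix, flow-event and nucleus-stack generators.

test_that("noiseless locked parameters give every gene a CV of zero", {
  p <- telegraph_params(mu_on = 100, mu_off = 5, cv_intrinsic = 0,
                        sigma_extrinsic = 0, cv_measurement = 0,
                        lock_mode = "locked_on")
  sim <- simulate_expression_matrix(list("1" = p), n_genes = 40, n_arms = 8,
                                    condition_sd = 0, seed = 1)
  cvs <- gene_condition_cv(sim$expression)
  expect_equal(cvs$mean_cv, rep(0, 40))
})

test_that("genome layout bookkeeping: arms, ranks and distances", {
  sim <- simulate_expression_matrix(list("1" = quiet_params()),
                                    n_genes = 160, n_arms = 8, seed = 2)
  pos <- sim$positions
  expect_equal(nrow(pos), 160)
  arm_key <- paste(pos$chromosome, pos$arm)
  expect_equal(dplyr::n_distinct(arm_key), 8)
  expect_true(all(table(arm_key) == 20))
  expect_true(all(sort(unique(pos$telomere_rank)) == 1:20))
  expect_equal(sum(pos$telomere_rank == 1), 8)
  # distance consistent with the assigned arm
  expect_equal(pos$distance_to_telomere,
               ifelse(pos$arm == "left", pos$start,
                      pos$chrom_length - pos$end))
  # expression table covers the full design
  expect_equal(nrow(sim$expression), 160 * 11 * 2)
})

test_that("slow-toggling telomeric ranks are more variable than fast internal ranks", {
  rp <- list("1" = telegraph_params(k_on = 0.02, k_off = 0.02),
             "4" = telegraph_params(k_on = 2, k_off = 2))
  ord <- replicate(5, {
    s <- sample.int(1e6, 1)
    sim <- simulate_expression_matrix(rp, n_genes = 160, n_arms = 8, seed = s)
    cvs <- dplyr::left_join(gene_condition_cv(sim$expression),
                            sim$positions, by = "gene_id")
    mean(cvs$mean_cv[cvs$telomere_rank == 1]) >
      mean(cvs$mean_cv[cvs$telomere_rank == 8])
  })
  expect_true(all(ord))
})

test_that("expression simulator validates its configuration", {
  expect_error(simulate_expression_matrix(list(), seed = 1),
               class = "telonoise_error_config")
  expect_error(simulate_expression_matrix(list("1" = quiet_params()),
                                          n_replicates = 1, seed = 1),
               class = "telonoise_error_config")
})

test_that("flow events: debris fraction, gating and locked constant FL1", {
  p <- quiet_params()
  ev <- simulate_flow_events(p, n_events = 50000, frac_debris = 0.1, seed = 3)
  gated <- gate_events(ev, quiet = TRUE)
  frac <- nrow(gated) / nrow(ev)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.1 * 0.9 / 50000))

  ev0 <- simulate_flow_events(p, n_events = 2000, frac_debris = 0, seed = 4)
  expect_equal(nrow(gate_events(ev0, quiet = TRUE)), 2000)

  pc <- telegraph_params(mu_on = 250, mu_off = 5, cv_intrinsic = 0,
                         sigma_extrinsic = 0, cv_measurement = 0,
                         lock_mode = "locked_on")
  evc <- simulate_flow_events(pc, n_events = 1000, frac_debris = 0, seed = 5)
  expect_equal(evc$fl1, rep(250, 1000))

  expect_error(simulate_flow_events(p, 100, frac_debris = 1.2, seed = 1),
               class = "telonoise_error_parameter")
})

test_that("rendered nuclei recover truth exactly without noise", {
  p <- telegraph_params(mu_on = 500, mu_off = 50)
  truth <- make_telegraph_population(p, 12, seed = 6)
  r <- render_nuclei_stack(truth, noise = list(background = 0))
  meas <- nuclear_intensity(project_zstack(r$stack), r$annotations)
  j <- dplyr::left_join(r$truth, meas, by = "cell_id")
  expect_equal(j$signal, j$expected_signal, tolerance = 1e-10)
})

test_that("uniform background is removed exactly by construction", {
  p <- telegraph_params(mu_on = 500, mu_off = 50)
  truth <- make_telegraph_population(p, 6, seed = 7)
  r0 <- render_nuclei_stack(truth, noise = list(background = 0))
  rb <- render_nuclei_stack(truth, noise = list(background = 300))
  m0 <- nuclear_intensity(project_zstack(r0$stack), r0$annotations)
  mb <- nuclear_intensity(project_zstack(rb$stack), rb$annotations)
  expect_equal(m0$signal, mb$signal, tolerance = 1e-9)
})

test_that("renderer rejects more nuclei than the frame can hold", {
  p <- telegraph_params(mu_on = 500, mu_off = 50)
  truth <- make_telegraph_population(p, 200, seed = 8)
  expect_error(render_nuclei_stack(truth,
                                   geometry = list(width = 64, height = 64)),
               class = "telonoise_error_config")
})
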