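test_that("telomere ranks follow the distance rule on a hand-worked chromosome", {
  genes <- tibble::tibble(
    chromosome = "chr1",
    start = c(100, 5000, 9800),
    end = c(600, 5500, 9900),
    gene_id = c("gA", "gB", "gC")
  )
  lens <- tibble::tibble(chromosome = "chr1", length = 10000)
  pos <- assign_telomere_ranks(genes, lens)
  pos <- pos[match(c("gA", "gB", "gC"), pos$gene_id), ]
  # gA: 100 bp from the left telomere -> left arm, rank 1.
  # gB: 5000 bp from the left but only 4500 from the right -> right arm.
  # gC: 100 bp from the right telomere via its end coordinate -> rank 1 right,
  # pushing gB to rank 2 on its (nearer) arm.
  expect_equal(pos$arm, c("left", "right", "right"))
  expect_equal(pos$distance_to_telomere, c(100, 4500, 100))
  expect_equal(pos$telomere_rank, c(1, 2, 1))
})

test_that("rank assignment is a within-arm bijection and translation-invariant", {
  genes <- tibble::tibble(
    chromosome = "chr1",
    start = c(0, 3000, 6200, 9000, 12000, 15500),
    end = c(500, 3500, 6700, 9500, 12500, 16000),
    gene_id = sprintf("g%d", 1:6)
  )
  lens <- tibble::tibble(chromosome = "chr1", length = 16000)
  pos <- assign_telomere_ranks(genes, lens)
  per_arm <- split(pos$telomere_rank, pos$arm)
  for (r in per_arm) expect_equal(sort(r), seq_along(r))
  shifted <- assign_telomere_ranks(
    dplyr::mutate(genes, start = start + 10, end = end + 10),
    dplyr::mutate(lens, length = length + 10))
  expect_equal(shifted$telomere_rank[match(pos$gene_id, shifted$gene_id)],
               pos$telomere_rank)
  expect_error(assign_telomere_ranks(
    dplyr::mutate(genes, end = end + 1e6), lens),
    class = "telonoise_error_coordinate")
})

test_that("a single gene per arm is rank 1 on each arm", {
  genes <- tibble::tibble(chromosome = c("chr1", "chr1"),
                          start = c(10, 9000), end = c(500, 9500),
                          gene_id = c("gL", "gR"))
  lens <- tibble::tibble(chromosome = "chr1", length = 10000)
  pos <- assign_telomere_ranks(genes, lens)
  expect_equal(sort(pos$telomere_rank), c(1, 1))
  expect_setequal(pos$arm, c("left", "right"))
})

test_that("centromere table splits arms at the centromere midpoint", {
  genes <- tibble::tibble(chromosome = "chr1",
                          start = c(100, 4000), end = c(600, 4500),
                          gene_id = c("gA", "gB"))
  lens <- tibble::tibble(chromosome = "chr1", length = 20000)
  cen <- tibble::tibble(chromosome = "chr1", start = 2900, end = 3100)
  pos <- assign_telomere_ranks(genes, lens, centromeres = cen)
  # with the centromere at 3000, gB (4000-4500) lies on the right arm even
  # though its nearest telomere by raw distance would still be the left one
  expect_equal(pos$arm[pos$gene_id == "gB"], "right")
  expect_equal(pos$distance_to_telomere[pos$gene_id == "gB"], 20000 - 4500)
})

test_that("positional scan flags only the noisy telomeric ranks", {
  rp <- list("1" = telegraph_params(k_on = 0.02, k_off = 0.02),
             "4" = telegraph_params(k_on = 2, k_off = 2))
  sim <- simulate_expression_matrix(rp, n_genes = 240, n_arms = 8, seed = 42)
  cvs <- gene_condition_cv(sim$expression)
  scan <- positional_group_scan(cvs, sim$positions, group_size = 16,
                                max_rank = 6, n_boot = 1000, seed = 43)
  expect_equal(scan$rank, 1:6)
  expect_true(all(scan$significant[1:3]))
  expect_false(any(scan$significant[5:6]))
  expect_s3_class(plot_rank_scan(scan), "ggplot")
})

test_that("a set spanning the whole universe is never significant", {
  cvs <- tibble::tibble(gene_id = sprintf("g%03d", 1:40),
                        mean_cv = runif(40))
  genes <- tibble::tibble(chromosome = "chr1",
                          start = seq(0, 3900, by = 100)[1:40],
                          end = seq(0, 3900, by = 100)[1:40] + 50,
                          gene_id = cvs$gene_id)
  pos <- assign_telomere_ranks(genes, tibble::tibble(chromosome = "chr1",
                                                     length = 4000))
  scan <- positional_group_scan(cvs, pos, group_size = 40, max_rank = 1,
                                n_boot = 500, seed = 44)
  expect_equal(scan$empirical_p, 1)
})

test_that("distance trend recovers an exactly linear relationship", {
  genes <- tibble::tibble(chromosome = "chr1",
                          start = seq(0, 4500, by = 500)[1:10],
                          end = seq(0, 4500, by = 500)[1:10] + 100,
                          gene_id = sprintf("g%02d", 1:10))
  pos <- assign_telomere_ranks(genes, tibble::tibble(chromosome = "chr1",
                                                     length = 100000))
  cvs <- tibble::tibble(gene_id = pos$gene_id,
                        mean_cv = 2 - 1e-4 * pos$distance_to_telomere)
  tr <- distance_trend(cvs, pos)
  expect_equal(tr$slope, -1e-4)
  expect_equal(tr$pearson_r, -1)
  flat <- tibble::tibble(gene_id = pos$gene_id, mean_cv = 0.5)
  expect_error(distance_trend(flat, pos),
               class = "telonoise_error_degenerate")
  # centromere orientation flips the sign of a telomere-graded trend
  tr_cen <- distance_trend(cvs, pos, orientation = "centromere")
  expect_equal(tr_cen$pearson_r, 1)
})
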