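#' Render a synthetic z-stack of fluorescent nuclei
#'
#' Renders each cell of `truth` as a 2-D Gaussian spot on a regular grid,
#' split across `n_z` focal planes, with an optional uniform or graded
#' background and per-frame noise. The summed projection of a spot has peak
#' amplitude equal to the cell's `true_signal` (so its integral is
#' `2 * pi * spot_sigma^2` times the signal, i.e. proportional to it).
#' Alongside the stack, the renderer emits the three 4x4-pixel nuclear boxes
#' and three adjacent 4x4 background boxes per cell that
#' [nuclear_intensity()] consumes, plus a truth table giving each cell's
#' expected background-subtracted box-mean intensity computed from the
#' noiseless rendering.
#'
#' @param truth A cell table; `true_signal` (or, if absent,
#'   `channel1_intensity`) is rendered.
#' @param geometry List: `width`, `height` (pixels), `n_z` focal planes,
#'   `spot_sigma` (pixels), `spacing` (grid pitch between nucleus centres).
#' @param noise List: `background` (uniform background on the summed scale),
#'   `gradient_x` (linear background slope per pixel across x, summed scale),
#'   `read_noise_sd` (Gaussian sd per pixel per frame), `poisson` (logical;
#'   apply counting noise to each frame).
#' @param seed Integer seed (only used when noise is stochastic).
#'
#' @return A list: `stack` (numeric array height x width x n_z),
#'   `annotations` (tibble: `cell_id`, `box_type`, `box_index`, `x0`, `y0`,
#'   `size`; corners are 0-based, boxes half-open), and `truth` (tibble:
#'   `cell_id`, `true_signal`, `expected_signal`).
#' @export
render_nuclei_stack <- function(truth,
                                geometry = list(width = 256, height = 256,
                                                n_z = 8, spot_sigma = 3,
                                                spacing = 28),
                                noise = list(background = 0, gradient_x = 0,
                                             read_noise_sd = 0, poisson = FALSE),
                                seed = 1) {
  g <- utils::modifyList(list(width = 256, height = 256, n_z = 8,
                              spot_sigma = 3, spacing = 28), geometry)
  nz <- utils::modifyList(list(background = 0, gradient_x = 0,
                               read_noise_sd = 0, poisson = FALSE), noise)
  signals <- if ("true_signal" %in% names(truth) && !all(is.na(truth$true_signal))) {
    truth$true_signal
  } else {
    truth$channel1_intensity
  }
  cell_ids <- truth$cell_id
  n_cells <- length(signals)

  # grid of nucleus centres; margin keeps boxes in-bounds
  margin <- ceiling(g$spacing / 2)
  cx_grid <- seq(margin, g$width - margin, by = g$spacing)
  cy_grid <- seq(margin, g$height - margin, by = g$spacing)
  if (length(cx_grid) * length(cy_grid) < n_cells) {
    abort(sprintf("Geometry fits %d nuclei but %d were requested.",
                  length(cx_grid) * length(cy_grid), n_cells),
          class = "telonoise_error_config")
  }
  centres <- tidyr::expand_grid(cy = cy_grid, cx = cx_grid)[seq_len(n_cells), ]

  # noiseless summed projection: Gaussian spots + background field
  xs <- matrix(rep(0:(g$width - 1), each = g$height), nrow = g$height)
  ys <- matrix(rep(0:(g$height - 1), times = g$width), nrow = g$height)
  summed <- nz$background + nz$gradient_x * (xs - (g$width - 1) / 2)
  two_s2 <- 2 * g$spot_sigma^2
  for (i in seq_len(n_cells)) {
    dx2 <- (xs - centres$cx[i])^2
    dy2 <- (ys - centres$cy[i])^2
    summed <- summed + signals[i] * exp(-(dx2 + dy2) / two_s2)
  }

  # box annotations: three nuclear boxes spanning the spot, three adjacent
  # background boxes (0-based top-left corners of 4x4 half-open boxes)
  nuc_off <- list(c(-2, -2), c(-6, -2), c(2, -2))
  bg_off <- list(c(-2, -12), c(-2, 8), c(-12, -2))
  ann <- purrr::map(seq_len(n_cells), function(i) {
    tibble(
      cell_id = cell_ids[i],
      box_type = rep(c("nuclear", "background"), each = 3),
      box_index = rep(1:3, times = 2),
      x0 = centres$cx[i] + vapply(c(nuc_off, bg_off), `[`, numeric(1), 1),
      y0 = centres$cy[i] + vapply(c(nuc_off, bg_off), `[`, numeric(1), 2),
      size = 4L
    )
  }) %>% bind_rows()
  if (any(ann$x0 < 0 | ann$y0 < 0 | ann$x0 + 4 > g$width | ann$y0 + 4 > g$height)) {
    abort("Annotation boxes fall outside the frame; increase spacing/margins.",
          class = "telonoise_error_config")
  }

  # expected measured value from the noiseless rendering
  expected <- vapply(cell_ids, function(id) {
    a <- ann[ann$cell_id == id, ]
    res <- quantify_boxes(summed, a)
    res$signal
  }, numeric(1))

  # split across z with Gaussian axial weights, add per-frame noise
  zc <- (g$n_z + 1) / 2
  w <- exp(-((seq_len(g$n_z) - zc)^2) / (2 * (g$n_z / 4)^2))
  w <- w / sum(w)
  if (nz$read_noise_sd > 0 || nz$poisson) withr::local_seed(seed)
  stack <- array(0, dim = c(g$height, g$width, g$n_z))
  for (z in seq_len(g$n_z)) {
    frame <- summed * w[z]
    if (nz$poisson) frame <- rpois(length(frame), lambda = pmax(frame, 0))
    if (nz$read_noise_sd > 0) {
      frame <- frame + rnorm(length(frame), sd = nz$read_noise_sd)
    }
    stack[, , z] <- frame
  }

  list(stack = stack,
       annotations = ann,
       truth = tibble(cell_id = cell_ids, true_signal = signals,
                      expected_signal = unname(expected)),
       geometry = g, noise = nz)
}
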