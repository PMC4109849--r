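#' Telegraph (two-state promoter) parameter set
#'
#' Parameters of the two-state chromatin model used by every generator in the
#' package. A locus toggles between an active state (mean expression `mu_on`)
#' and a silent state (mean expression `mu_off`) at rates `k_on` (silent to
#' active) and `k_off` (active to silent), in units of events per cell
#' generation. Expression measured in a cell is
#' `extrinsic * mu_state * intrinsic + measurement error`, where the extrinsic
#' factor is a unit-mean lognormal shared by all alleles of the cell, the
#' intrinsic factor is a unit-mean lognormal drawn independently per allele,
#' and measurement error is additive Gaussian truncated at zero.
#'
#' @param k_on,k_off Switching rates (events/generation), both `>= 0`.
#' @param mu_on,mu_off State mean expression (arbitrary fluorescence units);
#'   `mu_on > mu_off >= 0`.
#' @param cv_intrinsic Coefficient of variation of the per-allele lognormal
#'   intrinsic factor (dimensionless, `>= 0`).
#' @param sigma_extrinsic Standard deviation, on the log scale, of the shared
#'   per-cell lognormal extrinsic factor (dimensionless, `>= 0`). The factor
#'   has mean 1, so its variance is `exp(sigma_extrinsic^2) - 1`.
#' @param cv_measurement Additive measurement-noise CV: Gaussian noise with
#'   standard deviation `cv_measurement` times the pre-noise intensity,
#'   truncated at zero.
#' @param lock_mode `"toggling"` for the free two-state mixture, or
#'   `"locked_on"` / `"locked_off"` for populations held in one chromatin
#'   state (the selection regimes of a counter-selectable marker: growth
#'   without uracil locks an adjacent URA3 ON, 5-FOA locks it OFF).
#'
#' @return An object of class `telegraph_params`.
#' @examples
#' telegraph_params(k_on = 0.1, k_off = 0.1, mu_on = 100, mu_off = 5)
#' @export
telegraph_params <- function(k_on = 0.1, k_off = 0.1,
                             mu_on = 100, mu_off = 5,
                             cv_intrinsic = 0.1,
                             sigma_extrinsic = 0.1,
                             cv_measurement = 0.05,
                             lock_mode = c("toggling", "locked_on", "locked_off")) {
  lock_mode <- match.arg(lock_mode)
  num <- c(k_on = k_on, k_off = k_off, mu_on = mu_on, mu_off = mu_off,
           cv_intrinsic = cv_intrinsic, sigma_extrinsic = sigma_extrinsic,
           cv_measurement = cv_measurement)
  if (!all(is.finite(num))) {
    abort("All telegraph parameters must be finite numbers.",
          class = "telonoise_error_parameter")
  }
  if (any(num < 0)) {
    abort("Rates, means and noise CVs must all be >= 0.",
          class = "telonoise_error_parameter")
  }
  if (!(mu_on > mu_off)) {
    abort("`mu_on` must exceed `mu_off`.", class = "telonoise_error_parameter")
  }
  if (lock_mode == "toggling" && k_on == 0 && k_off == 0) {
    abort("k_on = k_off = 0 with lock_mode = 'toggling' leaves the stationary state undefined.",
          class = "telonoise_error_config")
  }
  structure(
    list(k_on = k_on, k_off = k_off, mu_on = mu_on, mu_off = mu_off,
         cv_intrinsic = cv_intrinsic, sigma_extrinsic = sigma_extrinsic,
         cv_measurement = cv_measurement, lock_mode = lock_mode),
    class = "telegraph_params"
  )
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("<telegraph_params>\n")
  cat(sprintf("  k_on = %g, k_off = %g (stationary P(active) = %.3f)\n",
              x$k_on, x$k_off, stationary_active_fraction(x)))
  cat(sprintf("  mu_on = %g AU, mu_off = %g AU, lock_mode = %s\n",
              x$mu_on, x$mu_off, x$lock_mode))
  cat(sprintf("  cv_intrinsic = %g, sigma_extrinsic = %g, cv_measurement = %g\n",
              x$cv_intrinsic, x$sigma_extrinsic, x$cv_measurement))
  invisible(x)
}

#' Stationary probability of the active chromatin state
#'
#' `k_on / (k_on + k_off)` for a toggling locus; 1 or 0 for locked modes.
#'
#' @param params A [telegraph_params()] object.
#' @return A probability.
#' @export
stationary_active_fraction <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  switch(params$lock_mode,
         toggling   = params$k_on / (params$k_on + params$k_off),
         locked_on  = 1,
         locked_off = 0)
}

# Unit-mean lognormal draws parameterised by CV (cv = 0 degenerates to 1).
rlnorm_unit_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Unit-mean lognormal draws parameterised by log-scale sd.
rlnorm_unit_sdlog <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Additive truncated-Gaussian measurement noise. Returns the noisy vector with
# an "n_clipped" attribute counting values truncated at zero.
apply_measurement_noise <- function(signal, cv_measurement) {
  if (cv_measurement == 0) {
    attr(signal, "n_clipped") <- 0L
    return(signal)
  }
  noisy <- signal + rnorm(length(signal), mean = 0, sd = cv_measurement * signal)
  clipped <- sum(noisy < 0)
  noisy <- pmax(noisy, 0)
  attr(noisy, "n_clipped") <- clipped
  noisy
}

# Draw per-allele intensities for cells with known states. `states` is logical
# (TRUE = active). Returns a list with per-allele intensity vectors, the shared
# latent signal, and the clip count.
draw_cell_expression <- function(states, params, n_alleles = 1L) {
  n <- length(states)
  extrinsic <- rlnorm_unit_sdlog(n, params$sigma_extrinsic)
  mu <- ifelse(states, params$mu_on, params$mu_off)
  latent <- extrinsic * mu
  clipped <- 0L
  channels <- vector("list", n_alleles)
  for (a in seq_len(n_alleles)) {
    intrinsic <- rlnorm_unit_cv(n, params$cv_intrinsic)
    obs <- apply_measurement_noise(latent * intrinsic, params$cv_measurement)
    clipped <- clipped + attr(obs, "n_clipped")
    channels[[a]] <- as.numeric(obs)
  }
  list(channels = channels, latent = latent, n_clipped = clipped)
}

# Standard empty CellTable columns shared by every generator.
cell_table <- function(cell_id, population_id, channel1, channel2 = NA_real_,
                       colony_id = NA_character_, region_id = NA_character_,
                       pedigree_pair_id = NA_character_, role = "none",
                       true_state = NA_character_, true_signal = NA_real_) {
  tibble(
    cell_id = cell_id,
    population_id = population_id,
    colony_id = colony_id,
    region_id = region_id,
    pedigree_pair_id = pedigree_pair_id,
    role = role,
    channel1_intensity = channel1,
    channel2_intensity = channel2,
    true_state = true_state,
    true_signal = true_signal
  )
}

#' Simulate a single-time-point telegraph population
#'
#' Draws `n_cells` cells whose chromatin state comes from the stationary
#' distribution of the two-state model (or the locked state), then draws
#' per-cell expression as extrinsic factor x state mean x per-allele intrinsic
#' factor, plus truncated additive measurement noise. In two-allele mode
#' (`n_alleles = 2`, the dual-reporter design) both alleles of a cell share
#' the extrinsic factor and the chromatin state but draw independent intrinsic
#' factors, so inter-channel covariance carries the extrinsic component only.
#'
#' @param params A [telegraph_params()] object.
#' @param n_cells Number of cells (`>= 1`).
#' @param seed Integer seed; output is deterministic given `seed`.
#' @param n_alleles 1 (single reporter) or 2 (dual reporter).
#' @param population_id Label stored in the `population_id` column.
#'
#' @return A cell-table tibble with columns `cell_id`, `population_id`,
#'   `colony_id`, `region_id`, `pedigree_pair_id`, `role`,
#'   `channel1_intensity`, `channel2_intensity`, `true_state`, `true_signal`.
#'   The number of measurement-noise values truncated at zero is attached as
#'   attribute `n_clipped`.
#' @examples
#' p <- telegraph_params(k_on = 0.1, k_off = 0.1, mu_on = 100, mu_off = 5)
#' cells <- make_telegraph_population(p, n_cells = 1000, seed = 1)
#' mean(cells$true_state == "active")
#' @export
make_telegraph_population <- function(params, n_cells, seed, n_alleles = 1L,
                                      population_id = "pop1") {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort("`n_cells` must be >= 1.", class = "telonoise_error_parameter")
  }
  n_cells <- as.integer(n_cells)
  n_alleles <- as.integer(n_alleles)
  stopifnot(n_alleles %in% c(1L, 2L))
  withr::local_seed(seed)

  p_on <- stationary_active_fraction(params)
  states <- runif(n_cells) < p_on
  expr <- draw_cell_expression(states, params, n_alleles)

  out <- cell_table(
    cell_id = sprintf("cell%06d", seq_len(n_cells)),
    population_id = population_id,
    channel1 = expr$channels[[1]],
    channel2 = if (n_alleles == 2L) expr$channels[[2]] else NA_real_,
    true_state = ifelse(states, "active", "silent"),
    true_signal = expr$latent
  )
  attr(out, "n_clipped") <- expr$n_clipped
  out
}
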