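#' Simulate a flow-cytometry event stream
#'
#' Draws FL1 (fluorescence) from the telegraph model for single cells, FSC and
#' SSC from lognormal size/granularity distributions, and marks a `frac_debris`
#' fraction of events as debris with non-measurable (zero) scatter on one or
#' both channels, so that gating has something to remove.
#'
#' @param params A [telegraph_params()] object for the FL1 channel.
#' @param n_events Number of events (default 100,000, a typical acquisition).
#' @param frac_debris Per-event probability of being debris, in `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `fsc`, `ssc`, `fl1` and attribute
#'   `gated = FALSE` (see [gate_events()]).
#' @examples
#' ev <- simulate_flow_events(telegraph_params(), n_events = 1000,
#'                            frac_debris = 0.1, seed = 2)
#' mean(ev$fsc == 0 | ev$ssc == 0)
#' @export
simulate_flow_events <- function(params, n_events = 100000, frac_debris = 0.05,
                                 seed) {
  stopifnot(inherits(params, "telegraph_params"))
  if (n_events < 1) {
    abort("`n_events` must be >= 1.", class = "telonoise_error_parameter")
  }
  if (!is.finite(frac_debris) || frac_debris < 0 || frac_debris > 1) {
    abort("`frac_debris` must lie in [0, 1].", class = "telonoise_error_parameter")
  }
  withr::local_seed(seed)
  n_events <- as.integer(n_events)

  p_on <- stationary_active_fraction(params)
  states <- runif(n_events) < p_on
  expr <- draw_cell_expression(states, params, n_alleles = 1L)

  fsc <- rlnorm(n_events, meanlog = log(500), sdlog = 0.25)
  ssc <- rlnorm(n_events, meanlog = log(300), sdlog = 0.30)
  debris <- runif(n_events) < frac_debris
  if (any(debris)) {
    which_ch <- sample(c("fsc", "ssc", "both"), sum(debris), replace = TRUE)
    fsc[debris][which_ch != "ssc"] <- 0
    ssc[debris][which_ch != "fsc"] <- 0
  }

  out <- tibble(fsc = fsc, ssc = ssc, fl1 = expr$channels[[1]])
  attr(out, "gated") <- FALSE
  out
}
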