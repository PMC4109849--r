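#' Colony growth model
#'
#' Describes colonies grown from single founder cells whose epigenetic
#' (chromatin) state is heritable: the founder state is drawn once per colony
#' and propagates through a synchronous binary tree of divisions, flipping
#' with probability `p_switch_per_division` at each division. Slow switching
#' produces founder effects (colonies dominated by the founder's state);
#' fast switching (the sir2-null analogue) drives every colony towards the
#' same stationary mixture.
#'
#' @param n_colonies Number of colonies (`>= 1`).
#' @param cells_per_colony Cells sampled per colony; must not exceed
#'   `2^generations`.
#' @param generations Synchronous divisions simulated within a colony.
#' @param p_founder_on Probability the founder starts in the active state.
#' @param p_switch_per_division Per-division probability a cell's state flips.
#' @param n_regions_per_colony Number of colony regions (contiguous sectors of
#'   the lineage leaf order, a proxy for spatial sectors of the colony).
#'
#' @return An object of class `colony_model`.
#' @export
colony_model <- function(n_colonies = 6, cells_per_colony = 256,
                         generations = 8, p_founder_on = 0.5,
                         p_switch_per_division = 0.01,
                         n_regions_per_colony = 2) {
  probs <- c(p_founder_on = p_founder_on,
             p_switch_per_division = p_switch_per_division)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "telonoise_error_parameter")
  }
  counts <- c(n_colonies, cells_per_colony, generations, n_regions_per_colony)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    abort("Counts must be >= 1.", class = "telonoise_error_parameter")
  }
  structure(list(n_colonies = as.integer(n_colonies),
                 cells_per_colony = as.integer(cells_per_colony),
                 generations = as.integer(generations),
                 p_founder_on = p_founder_on,
                 p_switch_per_division = p_switch_per_division,
                 n_regions_per_colony = as.integer(n_regions_per_colony)),
            class = "colony_model")
}

# Grow founder states through `generations` synchronous divisions.
# `founders` is a logical vector (one entry per lineage); returns a logical
# matrix lineages x 2^generations whose columns are leaves in subtree-
# contiguous order, each daughter flipping state per division. `p_switch` is
# either a single flip probability or a length-2 vector
# c(active = P(active -> silent), silent = P(silent -> active)).
grow_lineage_states <- function(founders, p_switch, generations) {
  if (length(p_switch) == 1) p_switch <- c(active = p_switch, silent = p_switch)
  s <- matrix(founders, ncol = 1)
  for (g in seq_len(generations)) {
    s <- s[, rep(seq_len(ncol(s)), each = 2), drop = FALSE]
    if (any(p_switch > 0)) {
      p_cell <- ifelse(s, p_switch[["active"]], p_switch[["silent"]])
      flip <- matrix(runif(length(s)) < p_cell, nrow = nrow(s))
      s <- xor(s, flip)
    }
  }
  s
}

#' Simulate colonies with heritable chromatin state
#'
#' Each colony draws a founder state, grows it through
#' `colony$generations` divisions with per-division flips, keeps the first
#' `cells_per_colony` leaves of the lineage order, partitions them into
#' `n_regions_per_colony` contiguous regions, and draws expression for every
#' cell conditioned on its state exactly as [make_telegraph_population()].
#' Each colony is one population.
#'
#' @param params A [telegraph_params()] object (its `lock_mode` is ignored in
#'   favour of the colony founder/switching process).
#' @param colony A [colony_model()] object.
#' @param seed Integer seed.
#'
#' @return A cell-table tibble with `colony_id` and `region_id` populated.
#' @examples
#' p <- telegraph_params()
#' cells <- simulate_colonies(p, colony_model(n_colonies = 3), seed = 7)
#' dplyr::count(cells, colony_id)
#' @export
simulate_colonies <- function(params, colony, seed) {
  stopifnot(inherits(params, "telegraph_params"), inherits(colony, "colony_model"))
  if (colony$cells_per_colony < colony$n_regions_per_colony) {
    abort("`cells_per_colony` must be >= `n_regions_per_colony`.",
          class = "telonoise_error_config")
  }
  n_leaves <- 2^colony$generations
  if (colony$cells_per_colony > n_leaves) {
    abort(sprintf("cells_per_colony (%d) exceeds 2^generations (%d) leaves.",
                  colony$cells_per_colony, n_leaves),
          class = "telonoise_error_config")
  }
  withr::local_seed(seed)

  founders <- runif(colony$n_colonies) < colony$p_founder_on
  leaves <- grow_lineage_states(founders, colony$p_switch_per_division,
                                colony$generations)
  keep <- seq_len(colony$cells_per_colony)
  region_of <- ceiling(keep / (colony$cells_per_colony / colony$n_regions_per_colony))

  out <- purrr::map(seq_len(colony$n_colonies), function(ci) {
    states <- leaves[ci, keep]
    expr <- draw_cell_expression(states, params, n_alleles = 1L)
    cid <- sprintf("colony%02d", ci)
    cell_table(
      cell_id = sprintf("%s_cell%04d", cid, keep),
      population_id = cid,
      colony_id = cid,
      region_id = sprintf("%s_region%d", cid, region_of),
      channel1 = expr$channels[[1]],
      true_state = ifelse(states, "active", "silent"),
      true_signal = expr$latent
    )
  })
  bind_rows(out)
}

#' Simulate mother-daughter pedigree populations
#'
#' Mirrors a pedigree dissection experiment: for each of `n_pairs` pairs a
#' founder state is drawn; the mother cell and her first daughter each found
#' an independent population that grows for `generations` divisions with
#' per-division state flips, and `cells_per_population` cells are measured
#' from each. Mother and daughter share the founder state, so when switching
#' is slow the paired populations have correlated expression.
#'
#' @param params A [telegraph_params()] object.
#' @param n_pairs Number of mother-daughter pairs (`>= 2`; the permutation
#'   test downstream needs at least two).
#' @param cells_per_population Cells measured per population (default 50).
#' @param p_switch_per_division Per-division state-flip probability.
#' @param generations Divisions grown after dissection.
#' @param p_founder_on Probability a pair's founder starts active.
#' @param seed Integer seed.
#'
#' @return A cell-table tibble; `role` is `"mother"` or `"daughter"` and
#'   `pedigree_pair_id` links the two populations of a pair.
#' @export
simulate_pedigree <- function(params, n_pairs = 10, cells_per_population = 50,
                              p_switch_per_division = 0.02, generations = 6,
                              p_founder_on = 0.5, seed) {
  stopifnot(inherits(params, "telegraph_params"))
  if (n_pairs < 2) {
    abort("`n_pairs` must be >= 2.", class = "telonoise_error_config")
  }
  n_leaves <- 2^generations
  if (cells_per_population > n_leaves) {
    abort(sprintf("cells_per_population (%d) exceeds 2^generations (%d).",
                  cells_per_population, n_leaves),
          class = "telonoise_error_config")
  }
  withr::local_seed(seed)

  n_pairs <- as.integer(n_pairs)
  founders <- runif(n_pairs) < p_founder_on
  # Two independent lineages (mother, daughter) per pair, same founder state.
  lineage_founders <- rep(founders, each = 2)
  leaves <- grow_lineage_states(lineage_founders, p_switch_per_division,
                                as.integer(generations))
  keep <- seq_len(as.integer(cells_per_population))
  roles <- rep(c("mother", "daughter"), times = n_pairs)
  pair_of <- rep(seq_len(n_pairs), each = 2)

  out <- purrr::map(seq_len(nrow(leaves)), function(li) {
    states <- leaves[li, keep]
    expr <- draw_cell_expression(states, params, n_alleles = 1L)
    pid <- sprintf("pair%02d", pair_of[li])
    pop <- sprintf("%s_%s", pid, roles[li])
    cell_table(
      cell_id = sprintf("%s_cell%04d", pop, keep),
      population_id = pop,
      pedigree_pair_id = pid,
      role = roles[li],
      channel1 = expr$channels[[1]],
      true_state = ifelse(states, "active", "silent"),
      true_signal = expr$latent
    )
  })
  bind_rows(out)
}
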