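#' Simulate a multi-condition expression matrix with telomere-rank structure
#'
#' Emulates a multi-condition RNA-Seq design (default: 11 conditions in
#' biological duplicate) over a synthetic genome in which the telegraph
#' parameters of a gene depend on its telomere rank. Genes are laid out on
#' `n_arms` chromosome arms; the gene at rank 1 is the most telomere-proximal
#' on its arm.
#'
#' Each biological replicate of a (gene, condition) cell is modelled as the
#' mean expression of a small population grown from a single founder: the
#' founder chromatin state is drawn from the rank's stationary distribution
#' and propagated through `generations` divisions, flipping active to silent
#' with probability `1 - exp(-k_off)` per division (and silent to active with
#' `1 - exp(-k_on)`). Slow toggling therefore yields founder-dominated,
#' near-bimodal replicate means (high CV across replicates) while fast
#' toggling yields well-mixed replicates (low CV), at identical stationary
#' state occupancy. Condition-specific mean shifts are lognormal multipliers
#' shared by the replicates of a (gene, condition) pair.
#'
#' @param rank_params Named list mapping telomere rank (`"1"`, `"2"`, ...) to
#'   [telegraph_params()]. Ranks above the largest named rank reuse the
#'   largest named rank's parameters. Must be non-empty.
#' @param n_genes Total genes.
#' @param n_conditions,n_replicates Design size; `n_replicates >= 2` so a CV
#'   can be computed.
#' @param n_arms Number of chromosome arms (two per chromosome).
#' @param condition_sd Log-scale sd of the per-(gene, condition) mean shift.
#' @param cells_per_replicate,generations Size of the founder-seeded
#'   population behind each replicate value.
#' @param seed Integer seed.
#'
#' @return A list with `expression` (long tibble: `gene_id`, `condition`,
#'   `replicate`, `value`) and `positions` (tibble of gene coordinates:
#'   `gene_id`, `chromosome`, `arm`, `start`, `end`, `telomere_rank`,
#'   `distance_to_telomere`, `chrom_length`).
#' @examples
#' rp <- list("1" = telegraph_params(k_on = 0.02, k_off = 0.02),
#'            "2" = telegraph_params(k_on = 2, k_off = 2))
#' sim <- simulate_expression_matrix(rp, n_genes = 32, n_arms = 8, seed = 1)
#' head(sim$expression)
#' @export
simulate_expression_matrix <- function(rank_params, n_genes = 500,
                                       n_conditions = 11, n_replicates = 2,
                                       n_arms = 8, condition_sd = 0.2,
                                       cells_per_replicate = 64,
                                       generations = 6, seed) {
  if (length(rank_params) == 0) {
    abort("`rank_params` must map at least one telomere rank to parameters.",
          class = "telonoise_error_config")
  }
  stopifnot(all(purrr::map_lgl(rank_params, inherits, "telegraph_params")))
  if (n_replicates < 2) {
    abort("`n_replicates` must be >= 2 for a CV to exist.",
          class = "telonoise_error_config")
  }
  named_ranks <- sort(as.integer(names(rank_params)))
  if (any(is.na(named_ranks))) {
    abort("Names of `rank_params` must be integer telomere ranks.",
          class = "telonoise_error_config")
  }
  withr::local_seed(seed)

  # --- genome layout -------------------------------------------------------
  arm_of <- sort(rep(seq_len(n_arms), length.out = n_genes))
  rank_of <- unlist(lapply(split(arm_of, arm_of), seq_along), use.names = FALSE)
  max_per_arm <- max(rank_of)
  gene_len <- 2000
  pitch <- 3000
  chrom_length <- 2 * (max_per_arm * pitch) + 10000
  chromosome <- sprintf("chr%d", ceiling(arm_of / 2))
  side <- ifelse(arm_of %% 2 == 1, "left", "right")
  start <- ifelse(side == "left",
                  (rank_of - 1) * pitch,
                  chrom_length - (rank_of - 1) * pitch - gene_len)
  end <- start + gene_len
  positions <- tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chromosome = chromosome,
    arm = side,
    start = start,
    end = end,
    telomere_rank = rank_of,
    distance_to_telomere = ifelse(side == "left", start, chrom_length - end),
    chrom_length = chrom_length
  )

  # --- expression draws, one rank-parameter group at a time ----------------
  param_rank <- pmin(rank_of, max(named_ranks))
  param_rank <- vapply(param_rank, function(r) max(named_ranks[named_ranks <= r]),
                       integer(1))
  design <- tidyr::expand_grid(
    gene_idx = seq_len(n_genes),
    condition = sprintf("cond%02d", seq_len(n_conditions)),
    replicate = seq_len(n_replicates)
  )
  design$param_rank <- param_rank[design$gene_idx]
  design$value <- NA_real_

  # condition shifts shared across replicates of a (gene, condition) pair
  shift_tbl <- tidyr::expand_grid(gene_idx = seq_len(n_genes),
                                  condition = sprintf("cond%02d", seq_len(n_conditions)))
  shift_tbl$shift <- rlnorm_unit_sdlog(nrow(shift_tbl), condition_sd)

  for (r in named_ranks) {
    rows <- which(design$param_rank == r)
    if (length(rows) == 0) next
    p <- rank_params[[as.character(r)]]
    n_lin <- length(rows)
    p_on <- stationary_active_fraction(p)
    founders <- runif(n_lin) < p_on
    flips <- if (p$lock_mode == "toggling") {
      c(active = 1 - exp(-p$k_off), silent = 1 - exp(-p$k_on))
    } else {
      c(active = 0, silent = 0)
    }
    leaves <- grow_lineage_states(founders, flips, as.integer(generations))
    leaves <- leaves[, seq_len(cells_per_replicate), drop = FALSE]
    expr <- draw_cell_expression(as.vector(leaves), p, n_alleles = 1L)
    vals <- rowMeans(matrix(expr$channels[[1]], nrow = n_lin))
    design$value[rows] <- vals
  }

  expression <- design %>%
    left_join(shift_tbl, by = c("gene_idx", "condition")) %>%
    mutate(gene_id = positions$gene_id[.data$gene_idx],
           value = .data$value * .data$shift) %>%
    select("gene_id", "condition", "replicate", "value") %>%
    arrange(.data$gene_id, .data$condition, .data$replicate)

  list(expression = expression, positions = positions)
}
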