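# Constructor for resampling results. `alternative` is "greater" (observed
# larger than null is extreme) or "less" (observed smaller is extreme).
new_resampling_result <- function(observed, null, alternative, seed,
                                  statistic = "statistic", extra = list()) {
  qs <- quantile(null, probs = c(0.025, 0.05, 0.95, 0.975), names = FALSE,
                 type = 7)
  n <- length(null)
  if (alternative == "greater") {
    p <- (1 + sum(null >= observed)) / (n + 1)
    crit <- qs[4]  # 97.5% quantile
    significant <- observed > crit
  } else {
    p <- (1 + sum(null <= observed)) / (n + 1)
    crit <- qs[2]  # 5% quantile
    significant <- observed < crit
  }
  structure(
    c(list(observed = observed,
           null_quantiles = setNames(qs, c("2.5%", "5%", "95%", "97.5%")),
           critical_value = crit, empirical_p = p, significant = significant,
           n_resamples = n, alternative = alternative, seed = seed,
           statistic = statistic, null = null),
      extra),
    class = "telonoise_resample"
  )
}

#' @export
print.telonoise_resample <- function(x, ...) {
  cat("<telonoise resampling test>\n")
  cat(sprintf("  statistic: %s = %.4g\n", x$statistic, x$observed))
  cat(sprintf("  null: %d resamples; critical value (%s tail) = %.4g\n",
              x$n_resamples,
              if (x$alternative == "greater") "97.5%" else "5%",
              x$critical_value))
  cat(sprintf("  empirical p = %.4g (%ssignificant)\n", x$empirical_p,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' @method tidy telonoise_resample
#' @export
tidy.telonoise_resample <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         critical_value = x$critical_value, empirical_p = x$empirical_p,
         significant = x$significant,
         null_q2.5 = x$null_quantiles[["2.5%"]],
         null_q5 = x$null_quantiles[["5%"]],
         null_q95 = x$null_quantiles[["95%"]],
         null_q97.5 = x$null_quantiles[["97.5%"]],
         n_resamples = x$n_resamples, alternative = x$alternative)
}

#' @method glance telonoise_resample
#' @export
glance.telonoise_resample <- function(x, ...) tidy(x)

#' Histogram of a resampling null with the observed statistic
#'
#' Plots the null distribution of a resampling test with the observed value
#' (solid line) and the critical value (dashed line), the usual way
#' permutation nulls are displayed.
#'
#' @param object A `telonoise_resample` result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot telonoise_resample
#' @export
autoplot.telonoise_resample <- function(object, bins = 40, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$critical_value,
                        linetype = "dashed") +
    ggplot2::labs(x = object$statistic, y = "resamples",
                  title = sprintf("Observed = %.3g, empirical p = %.3g",
                                  object$observed, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Bootstrap test of a gene set's transcriptional variability
#'
#' Tests whether a set of genes is more transcriptionally variable than
#' average: the observed statistic is the mean `mean_cv` of the target set;
#' the null is built from `n_boot` random gene sets of the same size drawn
#' uniformly without replacement from the gene universe (genes with a defined
#' `mean_cv`). The set is called significant when the observed mean exceeds
#' the 97.5% quantile of the null (the critical value), and the one-sided
#' empirical p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (n_boot + 1)`, which can never be zero.
#'
#' @param gene_cvs Tibble from [gene_condition_cv()] (`gene_id`, `mean_cv`).
#' @param target_set Character vector of gene ids, all present in the
#'   universe.
#' @param n_boot Number of bootstrap gene sets (default 50,000).
#' @param seed Integer seed.
#' @return A `telonoise_resample` object ([tidy()] it for a one-row summary).
#' @export
geneset_variability_test <- function(gene_cvs, target_set, n_boot = 50000,
                                     seed) {
  stopifnot(all(c("gene_id", "mean_cv") %in% names(gene_cvs)))
  if (n_boot < 100) {
    abort("`n_boot` must be >= 100.", class = "telonoise_error_parameter")
  }
  universe <- gene_cvs %>%
    filter(!is.na(.data$mean_cv)) %>%
    arrange(.data$gene_id)
  missing <- setdiff(target_set, universe$gene_id)
  if (length(missing) > 0) {
    abort(paste0("Target genes absent from the universe: ",
                 paste(missing, collapse = ", ")),
          class = "telonoise_error_identifier")
  }
  if (length(target_set) < 1) {
    abort("`target_set` must contain at least one gene.",
          class = "telonoise_error_parameter")
  }
  withr::local_seed(seed)
  cvs <- universe$mean_cv
  k <- length(unique(target_set))
  observed <- mean(cvs[match(unique(target_set), universe$gene_id)])
  n_univ <- length(cvs)
  null <- vapply(seq_len(n_boot),
                 function(b) mean(cvs[sample.int(n_univ, k)]),
                 numeric(1))
  new_resampling_result(observed, null, alternative = "greater", seed = seed,
                        statistic = "mean CV of gene set",
                        extra = list(set_size = k, n_universe = n_univ))
}

#' Bootstrap test of a CV ratio between two cell groups
#'
#' Compares cell-to-cell variability between a test and a reference group of
#' per-cell intensities. The observed statistic is
#' `CV(cells_b) / CV(cells_a)` (orientation configurable); the null
#' randomises the group assignment of the pooled cells (preserving group
#' sizes) and recomputes the ratio, and the one-sided empirical p-value asks
#' for null ratios at least as large as observed.
#'
#' @param cells_a,cells_b Per-cell intensity vectors (`n >= 3` each).
#' @param n_boot Number of label randomisations (default 10,000).
#' @param seed Integer seed.
#' @param ratio `"b_over_a"` (default) or `"a_over_b"`.
#' @return A `telonoise_resample` object.
#' @export
cv_ratio_test <- function(cells_a, cells_b, n_boot = 10000, seed,
                          ratio = c("b_over_a", "a_over_b")) {
  ratio <- match.arg(ratio)
  if (length(cells_a) < 3 || length(cells_b) < 3) {
    abort("Each group needs at least three cells.",
          class = "telonoise_error_insufficient_data")
  }
  if (n_boot < 100) {
    abort("`n_boot` must be >= 100.", class = "telonoise_error_parameter")
  }
  cv_a <- coefficient_of_variation(cells_a)
  cv_b <- coefficient_of_variation(cells_b)
  if (cv_a == 0 || cv_b == 0) {
    abort("Zero variance in a group; the CV ratio is degenerate.",
          class = "telonoise_error_degenerate")
  }
  observed <- if (ratio == "b_over_a") cv_b / cv_a else cv_a / cv_b
  na <- length(cells_a)
  pool <- sort(c(cells_a, cells_b))  # row-order invariance
  n <- length(pool)
  withr::local_seed(seed)
  null <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n)
    ga <- pool[idx[seq_len(na)]]
    gb <- pool[idx[(na + 1):n]]
    ra <- sd(ga) / mean(ga)
    rb <- sd(gb) / mean(gb)
    if (ratio == "b_over_a") rb / ra else ra / rb
  }, numeric(1))
  new_resampling_result(observed, null, alternative = "greater", seed = seed,
                        statistic = sprintf("CV ratio (%s)", ratio))
}

#' Permutation test of mother-daughter expression heritability
#'
#' Each mother and daughter population is summarised by the mean of its
#' per-cell `ln(intensity)` values; the observed statistic is the mean over
#' true pairs of `|mother - daughter|`. The null permutes the daughter
#' population labels among the mothers (`n_perm` fully random relabelings;
#' the identity permutation is allowed), and heritability shows up in the
#' lower tail: pairs significantly *more similar* than random when the
#' observed statistic falls below the 5% null quantile. Cells with
#' non-positive intensity are excluded from the log (count reported via a
#' message).
#'
#' @param cells Cell table from [simulate_pedigree()] (or equivalent) with
#'   `pedigree_pair_id`, `role` (`"mother"`/`"daughter"`) and
#'   `channel1_intensity`.
#' @param n_perm Number of random relabelings (default 10,000).
#' @param seed Integer seed.
#' @param aggregate Population summary of per-cell log expression:
#'   `"mean"` (default) or `"median"`.
#' @return A `telonoise_resample` object (lower-tailed).
#' @export
pedigree_permutation_test <- function(cells, n_perm = 10000, seed,
                                      aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("pedigree_pair_id", "role", "channel1_intensity") %in%
                  names(cells)))
  n_nonpos <- sum(cells$channel1_intensity <= 0, na.rm = TRUE)
  if (n_nonpos > 0) {
    message(sprintf("Excluding %d cell(s) with non-positive intensity from ln().",
                    n_nonpos))
  }
  d <- cells %>%
    filter(.data$channel1_intensity > 0,
           .data$role %in% c("mother", "daughter"))
  agg_fun <- if (aggregate == "mean") mean else median
  pops <- d %>%
    group_by(.data$pedigree_pair_id, .data$role) %>%
    summarise(mean_ln = agg_fun(log(.data$channel1_intensity)),
              n_cells = n(), .groups = "drop")
  wide <- tidyr::pivot_wider(pops, id_cols = "pedigree_pair_id",
                             names_from = "role",
                             values_from = "mean_ln") %>%
    arrange(.data$pedigree_pair_id)
  if (!all(c("mother", "daughter") %in% names(wide)) ||
      any(!is.finite(wide$mother)) || any(!is.finite(wide$daughter))) {
    abort("Every pair needs a mother and a daughter population with cells.",
          class = "telonoise_error_data")
  }
  if (nrow(wide) < 2) {
    abort("Need at least two mother-daughter pairs.",
          class = "telonoise_error_config")
  }
  m <- wide$mother
  dt <- wide$daughter
  k <- length(m)
  observed <- mean(abs(m - dt))
  withr::local_seed(seed)
  perm_idx <- vapply(seq_len(n_perm), function(b) sample.int(k), integer(k))
  null <- colMeans(abs(m - matrix(dt[perm_idx], nrow = k)))
  new_resampling_result(observed, null, alternative = "less", seed = seed,
                        statistic = "mean |difference in mean ln(expression)|",
                        extra = list(n_pairs = k))
}

#' Uniform subsampling of cells
#'
#' Samples `n` cells uniformly without replacement, deterministically given
#' the seed, preserving the original row order; used to equalise cell counts
#' across strains before noise comparisons. When `n` equals the number of
#' available cells the input is returned unchanged. The selection depends on
#' the `cell_id` order, not on the input row order.
#'
#' @param cells Cell-table tibble with a `cell_id` column.
#' @param n Number of cells to keep (`<=` available).
#' @param seed Integer seed.
#' @return The subsampled cell table.
#' @export
subsample_cells <- function(cells, n, seed) {
  if (n > nrow(cells)) {
    abort(sprintf("Requested %d cells but only %d available.", n, nrow(cells)),
          class = "telonoise_error_insufficient_data")
  }
  if (n == nrow(cells)) return(cells)
  withr::local_seed(seed)
  ord <- order(cells$cell_id)
  pick <- sort(ord[sample.int(nrow(cells), n)])
  cells[pick, , drop = FALSE]
}
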