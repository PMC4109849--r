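#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the sample mean.
#' Scale-invariant: `coefficient_of_variation(c * x)` equals
#' `coefficient_of_variation(x)` for any `c > 0`.
#'
#' @param values Numeric vector of at least two finite values.
#' @return A dimensionless ratio.
#' @examples
#' coefficient_of_variation(c(2, 4, 6)) # sd 2 / mean 4 = 0.5
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("Need at least two values for a CV.",
          class = "telonoise_error_insufficient_data")
  }
  if (!all(is.finite(values))) {
    abort("Values must be finite.", class = "telonoise_error_parameter")
  }
  m <- mean(values)
  if (m == 0) {
    abort("CV is undefined for a zero mean.", class = "telonoise_error_degenerate")
  }
  sd(values) / m
}

#' Per-gene cross-condition expression variability
#'
#' For every gene, computes the CV across replicates within each condition,
#' then averages those per-condition CVs (unweighted) over the conditions with
#' at least two non-missing replicates. Genes with no usable condition get a
#' missing `mean_cv` and should be excluded downstream. Conditions whose
#' replicate mean is not strictly positive raise an error rather than
#' emitting infinities.
#'
#' @param expression Long tibble with columns `gene_id`, `condition`,
#'   `replicate`, `value` (see [simulate_expression_matrix()] or
#'   [read_expression_matrix()]).
#' @param per_condition If `TRUE`, also return the per-(gene, condition) CVs.
#'
#' @return A tibble `gene_id`, `mean_cv`, `n_conditions_used`,
#'   `n_conditions_skipped` — or, with `per_condition = TRUE`, a list with
#'   elements `gene` (that tibble) and `condition` (per-condition CVs).
#' @export
gene_condition_cv <- function(expression, per_condition = FALSE) {
  stopifnot(all(c("gene_id", "condition", "replicate", "value") %in%
                  names(expression)))
  cond <- expression %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(n_rep = sum(!is.na(.data$value)),
              mean_value = mean(.data$value, na.rm = TRUE),
              sd_value = sd(.data$value, na.rm = TRUE),
              .groups = "drop")
  usable <- cond$n_rep >= 2
  if (any(usable & !is.na(cond$mean_value) & cond$mean_value <= 0)) {
    abort("Non-positive replicate mean encountered; CV would be undefined.",
          class = "telonoise_error_degenerate")
  }
  cond <- cond %>%
    mutate(cv = ifelse(usable, .data$sd_value / .data$mean_value, NA_real_))
  gene <- cond %>%
    group_by(.data$gene_id) %>%
    summarise(mean_cv = ifelse(sum(!is.na(.data$cv)) > 0,
                               mean(.data$cv, na.rm = TRUE), NA_real_),
              n_conditions_used = sum(!is.na(.data$cv)),
              n_conditions_skipped = sum(is.na(.data$cv)),
              .groups = "drop")
  if (per_condition) {
    list(gene = gene, condition = select(cond, "gene_id", "condition",
                                         "n_rep", "cv"))
  } else {
    gene
  }
}

#' Relative transcript abundance from qPCR cycle thresholds
#'
#' `delta_ct = ct_gene - ct_control`; relative abundance is
#' `2^(-delta_ct)` (abundance 1 when gene and control amplify at the same
#' cycle). Vectorised.
#'
#' @param ct_gene,ct_control Finite CT values (cycles).
#' @return Relative abundance, dimensionless.
#' @examples
#' delta_ct_abundance(21, 20) # one cycle later than control -> 0.5
#' @export
delta_ct_abundance <- function(ct_gene, ct_control) {
  if (!all(is.finite(ct_gene)) || !all(is.finite(ct_control))) {
    abort("CT values must be finite.", class = "telonoise_error_parameter")
  }
  2^(-(ct_gene - ct_control))
}

#' Two-sided variance-ratio (F) test
#'
#' `F = var(a) / var(b)` with sample variances; the two-sided p-value is
#' `2 * min(P(F <= f), P(F >= f))`, capped at 1. Used to compare
#' population-to-population variability between growth regimes (e.g. colony
#' isolates before and after liquid passaging).
#'
#' @param sample_a,sample_b Numeric vectors, each of length `>= 2`.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p.value`.
#' @export
variance_ratio_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("Each sample needs at least two values.",
          class = "telonoise_error_insufficient_data")
  }
  vb <- var(sample_b)
  if (vb == 0) {
    abort("Zero variance in the denominator sample.",
          class = "telonoise_error_degenerate")
  }
  f <- var(sample_a) / vb
  df1 <- length(sample_a) - 1
  df2 <- length(sample_b) - 1
  lower <- pf(f, df1, df2)
  p <- min(1, 2 * min(lower, 1 - lower))
  tibble(statistic = f, df1 = df1, df2 = df2, p.value = p)
}
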