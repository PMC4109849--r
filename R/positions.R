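#' Assign telomere ranks and distances to genes
#'
#' Maps genes (0-based, half-open coordinates) to chromosome arms and orders
#' them by proximity to their arm's telomere. Each gene is assigned to the
#' arm whose telomere is nearer to its nearest edge (`start` for the left
#' telomere, `chrom_length - end` for the right; ties go left). When a
#' centromere table is supplied, arms are split at the centromere midpoint
#' instead of `chrom_length / 2`, and genes are assigned to the arm they lie
#' on. Rank 1 is the most telomere-proximal gene of an arm; ties in distance
#' are broken by `gene_id` lexicographic order.
#'
#' @param genes Tibble with columns `chromosome` (or `chrom`), `start`,
#'   `end`, `gene_id`.
#' @param chrom_lengths Tibble with columns `chromosome` (or `chrom`) and
#'   `length`.
#' @param centromeres Optional tibble `chromosome`, `start`, `end` of
#'   centromere positions.
#' @return A tibble: `gene_id`, `chromosome`, `arm` (`"left"`/`"right"`),
#'   `start`, `end`, `telomere_rank`, `distance_to_telomere`, `chrom_length`,
#'   `arm_length`.
#' @export
assign_telomere_ranks <- function(genes, chrom_lengths, centromeres = NULL) {
  genes <- normalise_chrom(genes)
  chrom_lengths <- normalise_chrom(chrom_lengths)
  stopifnot(all(c("chromosome", "start", "end", "gene_id") %in% names(genes)),
            all(c("chromosome", "length") %in% names(chrom_lengths)))
  d <- left_join(genes, select(chrom_lengths, "chromosome", "length"),
                 by = "chromosome")
  if (any(is.na(d$length))) {
    abort("Every gene's chromosome needs a length.",
          class = "telonoise_error_coordinate")
  }
  if (any(d$start < 0 | d$end > d$length | d$start >= d$end)) {
    abort("Gene coordinates must satisfy 0 <= start < end <= chromosome length.",
          class = "telonoise_error_coordinate")
  }
  if (!is.null(centromeres)) {
    centromeres <- normalise_chrom(centromeres)
    cen <- centromeres %>%
      mutate(cen_mid = (.data$start + .data$end) / 2) %>%
      select("chromosome", "cen_mid")
    d <- left_join(d, cen, by = "chromosome")
    if (any(is.na(d$cen_mid))) {
      abort("Every chromosome needs a centromere entry when `centromeres` is supplied.",
            class = "telonoise_error_coordinate")
    }
  } else {
    d$cen_mid <- d$length / 2
  }
  d <- d %>%
    mutate(
      dist_left = .data$start,
      dist_right = .data$length - .data$end,
      arm = dplyr::case_when(
        !is.null(centromeres) & .data$end <= .data$cen_mid ~ "left",
        !is.null(centromeres) & .data$start >= .data$cen_mid ~ "right",
        .data$dist_left <= .data$dist_right ~ "left",
        TRUE ~ "right"
      ),
      distance_to_telomere = ifelse(.data$arm == "left",
                                    .data$dist_left, .data$dist_right),
      arm_length = ifelse(.data$arm == "left", .data$cen_mid,
                          .data$length - .data$cen_mid)
    ) %>%
    group_by(.data$chromosome, .data$arm) %>%
    arrange(.data$distance_to_telomere, .data$gene_id, .by_group = TRUE) %>%
    mutate(telomere_rank = dplyr::row_number()) %>%
    ungroup()
  d %>%
    select("gene_id", "chromosome", "arm", "start", "end", "telomere_rank",
           "distance_to_telomere", chrom_length = "length", "arm_length") %>%
    arrange(.data$chromosome, .data$arm, .data$telomere_rank)
}

normalise_chrom <- function(x) {
  if ("chrom" %in% names(x) && !"chromosome" %in% names(x)) {
    names(x)[names(x) == "chrom"] <- "chromosome"
  }
  x
}

#' Positional scan of gene-set variability by telomere rank
#'
#' For each telomere rank `k = 1, 2, ...`, forms the set of the `group_size`
#' genes closest to the telomeres starting at rank `k` (genes with rank
#' `>= k`, ordered by rank, then distance, then id, pooled across arms) and
#' tests it against the full gene universe with
#' [geneset_variability_test()]. This is the "sets of N genes starting at the
#' most telomere-proximal, stepping inward" scan.
#'
#' @param variability Tibble from [gene_condition_cv()].
#' @param positions Tibble from [assign_telomere_ranks()] (same genes).
#' @param group_size Genes per set (default 16; `>= 2`).
#' @param max_rank Deepest starting rank scanned; defaults to the largest
#'   rank at which a full group exists.
#' @param n_boot Bootstrap sets per rank.
#' @param seed Integer seed; rank `k` uses `seed + k`.
#' @return A tibble with one row per rank: `rank`, `n_genes`, `observed`,
#'   `critical_value`, `empirical_p`, `significant`, and the full
#'   `telonoise_resample` object in the `result` list-column.
#' @export
positional_group_scan <- function(variability, positions, group_size = 16,
                                  max_rank = NULL, n_boot = 5000, seed) {
  if (group_size < 2) {
    abort("`group_size` must be >= 2.", class = "telonoise_error_parameter")
  }
  d <- left_join(positions, variability, by = "gene_id") %>%
    filter(!is.na(.data$mean_cv)) %>%
    arrange(.data$telomere_rank, .data$distance_to_telomere, .data$gene_id)
  top_rank <- max(d$telomere_rank)
  if (is.null(max_rank)) {
    max_rank <- max(1, top_rank - ceiling(group_size / dplyr::n_distinct(
      paste(d$chromosome, d$arm))) + 1)
  }
  purrr::map(seq_len(max_rank), function(k) {
    grp <- d %>% filter(.data$telomere_rank >= k)
    ids <- head(grp$gene_id, group_size)
    if (length(ids) < group_size) {
      warn(sprintf("Rank %d: only %d genes available; group truncated.",
                   k, length(ids)))
    }
    res <- geneset_variability_test(d, ids, n_boot = n_boot, seed = seed + k)
    tibble(rank = k, n_genes = length(ids), observed = res$observed,
           critical_value = res$critical_value,
           empirical_p = res$empirical_p, significant = res$significant,
           result = list(res))
  }) %>% bind_rows()
}

#' Linear trend of variability with genomic distance
#'
#' Least-squares slope and Pearson correlation of per-gene `mean_cv` against
#' a genomic distance coordinate: distance to the telomere (default) or
#' distance from the centromere (`arm_length - distance_to_telomere`).
#'
#' @param variability Tibble from [gene_condition_cv()].
#' @param positions Tibble from [assign_telomere_ranks()].
#' @param orientation `"telomere"` or `"centromere"`.
#' @return One-row tibble: `orientation`, `slope` (per bp), `intercept`,
#'   `pearson_r`, `p.value`, `n_genes`.
#' @export
distance_trend <- function(variability, positions,
                           orientation = c("telomere", "centromere")) {
  orientation <- match.arg(orientation)
  d <- left_join(positions, variability, by = "gene_id") %>%
    filter(!is.na(.data$mean_cv))
  if (nrow(d) < 3) {
    abort("Need at least three genes.",
          class = "telonoise_error_insufficient_data")
  }
  x <- if (orientation == "telomere") {
    d$distance_to_telomere
  } else {
    d$arm_length - d$distance_to_telomere
  }
  if (sd(x) == 0 || sd(d$mean_cv) == 0) {
    abort("Zero variance in distance or CV; the trend is degenerate.",
          class = "telonoise_error_degenerate")
  }
  fit <- lm(d$mean_cv ~ x)
  ct <- cor.test(x, d$mean_cv, method = "pearson")
  tibble(orientation = orientation,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         pearson_r = unname(ct$estimate), p.value = ct$p.value,
         n_genes = nrow(d))
}

#' Plot a positional variability scan
#'
#' Observed mean CV per starting rank with the bootstrap critical value, the
#' standard display for a telomere-rank scan.
#'
#' @param scan Tibble from [positional_group_scan()].
#' @return A ggplot object.
#' @export
plot_rank_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed,
                                   fill = .data$significant)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$critical_value), shape = 95,
                        size = 8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "telomere rank of set start",
                  y = "mean CV of gene set",
                  fill = "beyond 97.5% critical value") +
    ggplot2::theme_minimal()
}
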