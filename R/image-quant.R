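#' Sum-project a z-stack
#'
#' Pixel-wise sum of all focal planes (the stack-arithmetic "sum" projection).
#' Accumulation is in double precision, so integer inputs cannot overflow.
#'
#' @param stack A numeric array `height x width x n_z`, or a list of equally
#'   sized matrices (frames in z order).
#' @return A numeric matrix, the summed projection.
#' @examples
#' project_zstack(list(matrix(1, 2, 2), matrix(2, 2, 2)))
#' @export
project_zstack <- function(stack) {
  if (is.list(stack)) {
    dims <- unique(lapply(stack, dim))
    if (length(dims) != 1) {
      abort("All frames must share the same dimensions.",
            class = "telonoise_error_geometry")
    }
    return(Reduce(`+`, lapply(stack, function(f) f * 1.0)))
  }
  if (!is.array(stack) || length(dim(stack)) != 3) {
    abort("`stack` must be a height x width x n_z array or list of matrices.",
          class = "telonoise_error_geometry")
  }
  apply(stack, c(1, 2), sum) * 1.0
}

# Mean pixel intensity of one 4x4 half-open box with 0-based corner (x0, y0).
box_mean <- function(image, x0, y0, size = 4L) {
  if (x0 < 0 || y0 < 0 || x0 + size > ncol(image) || y0 + size > nrow(image)) {
    abort(sprintf("Box at (%d, %d) falls outside the %d x %d image.",
                  x0, y0, ncol(image), nrow(image)),
          class = "telonoise_error_geometry")
  }
  mean(image[(y0 + 1):(y0 + size), (x0 + 1):(x0 + size)])
}

# Shared quantifier for one cell's annotation rows (both box types).
quantify_boxes <- function(image, ann, background = c("pooled", "paired")) {
  background <- match.arg(background)
  nuc <- ann[ann$box_type == "nuclear", ]
  bg <- ann[ann$box_type == "background", ]
  stopifnot(nrow(nuc) == 3, nrow(bg) == 3)
  nuc <- nuc[order(nuc$box_index), ]
  bg <- bg[order(bg$box_index), ]
  nuc_means <- mapply(box_mean, x0 = nuc$x0, y0 = nuc$y0,
                      MoreArgs = list(image = image, size = nuc$size[1]))
  bg_means <- mapply(box_mean, x0 = bg$x0, y0 = bg$y0,
                     MoreArgs = list(image = image, size = bg$size[1]))
  if (background == "pooled") {
    bg_level <- mean(bg_means)
    region_vals <- nuc_means - bg_level
  } else {
    bg_level <- mean(bg_means)
    region_vals <- nuc_means - bg_means
  }
  list(signal = mean(region_vals), background = bg_level,
       region_values = region_vals)
}

#' Nuclear fluorescence from annotated 4x4-pixel regions
#'
#' Quantifies each cell on a (projected) image the way manual region-based
#' microscopy quantification is done: the background is the mean pixel
#' intensity over the cell's three 4x4 background boxes, each of the three
#' 4x4 nuclear boxes is background-subtracted, and the cell's signal is the
#' mean of the three background-subtracted nuclear values. Negative signals
#' are reported as-is (clamping would bias downstream CV statistics); the
#' count of negative signals is attached as attribute `n_negative`.
#'
#' @param image A numeric matrix (e.g. from [project_zstack()]).
#' @param annotations Tibble of box annotations with columns `cell_id`,
#'   `box_type` (`"nuclear"` / `"background"`), `box_index` (1..3), `x0`,
#'   `y0` (0-based top-left corners), `size` (pixels, half-open extent).
#' @param background `"pooled"` (default): subtract the pooled mean of the
#'   three background boxes from every nuclear box; `"paired"`: subtract
#'   background box *i* from nuclear box *i*. The two coincide when the
#'   background boxes are equal.
#'
#' @return A tibble with one row per cell: `cell_id`, `signal`, `background`
#'   and the three background-subtracted region values `nuc1`..`nuc3`.
#' @export
nuclear_intensity <- function(image, annotations,
                              background = c("pooled", "paired")) {
  background <- match.arg(background)
  out <- annotations %>%
    dplyr::group_split(.data$cell_id) %>%
    purrr::map(function(a) {
      q <- quantify_boxes(image, a, background = background)
      tibble(cell_id = a$cell_id[1], signal = q$signal,
             background = q$background,
             nuc1 = q$region_values[1], nuc2 = q$region_values[2],
             nuc3 = q$region_values[3])
    }) %>%
    bind_rows() %>%
    arrange(.data$cell_id)
  attr(out, "n_negative") <- sum(out$signal < 0)
  out
}
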