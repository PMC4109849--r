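#' Read and write the package's tabular formats
#'
#' Cell tables and flow event tables travel as CSV with a header; expression
#' matrices as TSV with genes as rows and `condition:replicate` columns;
#' region annotations as JSON with 0-based pixel coordinates and half-open
#' boxes; z-stacks as multi-page 16-bit TIFF. Every simulation output
#' directory can carry a provenance JSON recording parameters, seed and
#' package version.
#'
#' @param x Object to write.
#' @param path File path.
#' @name telonoise-io
NULL

#' @rdname telonoise-io
#' @export
write_cell_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname telonoise-io
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname telonoise-io
#' @export
write_flow_events <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname telonoise-io
#' @export
read_flow_events <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "gated") <- FALSE
  out
}

#' @rdname telonoise-io
#' @export
write_expression_matrix <- function(x, path) {
  wide <- x %>%
    mutate(column = paste0(.data$condition, ":", .data$replicate)) %>%
    select("gene_id", "column", "value") %>%
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname telonoise-io
#' @export
read_expression_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide %>%
    tidyr::pivot_longer(-"gene_id", names_to = "column", values_to = "value") %>%
    tidyr::separate_wider_delim("column", delim = ":",
                                names = c("condition", "replicate")) %>%
    mutate(replicate = as.integer(.data$replicate)) %>%
    arrange(.data$gene_id, .data$condition, .data$replicate)
}

#' @rdname telonoise-io
#' @export
write_region_annotations <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname telonoise-io
#' @export
read_region_annotations <- function(path) {
  as_tibble(jsonlite::fromJSON(path))
}

#' @rdname telonoise-io
#' @param max_value Intensity mapped to the top of the 16-bit range.
#' @export
write_zstack_tiff <- function(x, path, max_value = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (is.null(max_value)) max_value <- max(x, 1)
  frames <- lapply(seq_len(dim(x)[3]), function(z) {
    pmin(pmax(x[, , z] / max_value, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname telonoise-io
#' @export
read_zstack_tiff <- function(path, max_value = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  for (z in seq_along(frames)) stack[, , z] <- frames[[z]] * max_value
  stack
}

#' Write a provenance record for a simulation output directory
#'
#' @param dir Output directory (created if needed).
#' @param params Named list of generator/analysis parameters.
#' @param seed Integer seed used.
#' @return The provenance file path, invisibly.
#' @export
write_provenance <- function(dir, params, seed) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "provenance.json")
  rec <- list(
    package = "telonoise",
    version = as.character(utils::packageVersion("telonoise")),
    seed = seed,
    parameters = params
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read generator parameters from a YAML or JSON file
#'
#' Recognised keys mirror the constructors: a `telegraph` block is passed to
#' [telegraph_params()], a `colony` block to [colony_model()]; all other
#' keys are returned as-is. Unknown telegraph/colony fields are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list; `telegraph`/`colony` entries are constructed
#'   objects.
#' @export
read_params_file <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$telegraph)) {
    unknown <- setdiff(names(raw$telegraph), names(formals(telegraph_params)))
    if (length(unknown) > 0) {
      abort(paste0("Unknown telegraph parameter(s): ",
                   paste(unknown, collapse = ", ")),
            class = "telonoise_error_config")
    }
    raw$telegraph <- do.call(telegraph_params, raw$telegraph)
  }
  if (!is.null(raw$colony)) {
    unknown <- setdiff(names(raw$colony), names(formals(colony_model)))
    if (length(unknown) > 0) {
      abort(paste0("Unknown colony parameter(s): ",
                   paste(unknown, collapse = ", ")),
            class = "telonoise_error_config")
    }
    raw$colony <- do.call(colony_model, raw$colony)
  }
  raw
}
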