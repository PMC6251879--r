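#' Read a field from a multi-page TIFF
#'
#' Expects 11 pages: one DAPI plane followed by the five red (53BP1) and
#' five green (gamma-H2AX) z-planes, in the order named by `page_order`.
#' Grey values are rescaled to 0-255.
#'
#' @param path TIFF file path.
#' @param page_order Channel order of the pages, a permutation of
#'   `c("dapi", "red", "green")`.
#' @return A [field_image()].
#' @export
read_field <- function(path, page_order = c("dapi", "red", "green")) {
  stopifnot(setequal(page_order, c("dapi", "red", "green")))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 11) {
    abort(sprintf("%s: expected 11 pages (DAPI + 2 x 5 planes), found %d.",
                  path, length(pages)),
          class = "focimetry_format_error")
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * 255)
  })
  sizes <- c(dapi = 1L, red = 5L, green = 5L)[page_order]
  offsets <- cumsum(c(0L, sizes[-3]))
  chan <- setNames(vector("list", 3), page_order)
  for (i in 1:3) {
    chan[[page_order[i]]] <- pages[offsets[i] + seq_len(sizes[i])]
  }
  to_stack <- function(lst) array(unlist(lst), c(dim(lst[[1]]), length(lst)))
  field_image(chan$dapi[[1]], to_stack(chan$red), to_stack(chan$green))
}

#' Write a field to a multi-page TIFF
#'
#' Pages are written as DAPI, red z1..z5, green z1..z5, 8-bit.
#'
#' @param field A [field_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- c(list(field$dapi),
             lapply(1:5, function(p) field$red_stack[, , p]),
             lapply(1:5, function(p) field$green_stack[, , p]))
  pages <- lapply(pages, function(m) pmin(pmax(m, 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write / read a ground-truth sidecar
#'
#' Ground truth travels as JSON next to the simulated TIFF.
#'
#' @param truth Truth list from [synth_field()].
#' @param path JSON path.
#' @return `path` invisibly (write); the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, as_tibble)
}

#' Serialize a simulation spec or run configuration as YAML
#'
#' @param x A [synth_spec()] or [run_config()].
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(x, path) {
  # named atomic vectors become YAML maps so their names survive the trip
  to_map <- function(v) if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  yaml::write_yaml(lapply(unclass(x), to_map), path)
  invisible(path)
}

#' Read a simulation spec back from YAML
#'
#' @param path YAML path.
#' @return A [synth_spec()].
#' @export
read_synth_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$nucleus_radius_px <- unlist(raw$nucleus_radius_px)
  raw$cycle_fractions <- unlist(raw$cycle_fractions)
  do.call(synth_spec, raw)
}

#' Read a run configuration back from YAML
#'
#' @param path YAML path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a table as CSV with full numeric precision
#'
#' CSV with headers and '.' decimal separator; numbers keep 15 significant
#' digits so a round trip preserves them exactly.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE) & !vapply(x, is.integer, TRUE)
  x[num] <- lapply(x[num], function(v) sprintf("%.15g", v))
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
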