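# Delimited-text readers/writers for cell tables and JSON serialisation of
# ground truths and evaluation results.

#' Write a cell table to CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal; coordinates in um with
#' 6 decimal places.
#'
#' @param cells Data frame with `colony_id`, `cell_id`, `cell_type`, `x_um`,
#'   `y_um`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cols <- c("colony_id", "cell_id", "cell_type", "x_um", "y_um")
  stopifnot(all(cols %in% names(cells)))
  out <- cells[, cols]
  out$x_um <- sprintf("%.6f", out$x_um)
  out$y_um <- sprintf("%.6f", out$y_um)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cell table from CSV
#'
#' @param path CSV file written by [write_cell_table()] (or any CSV with the
#'   same columns).
#' @return Data frame with `colony_id`, `cell_id`, `cell_type`, `x_um`,
#'   `y_um`.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  cols <- c("colony_id", "cell_id", "cell_type", "x_um", "y_um")
  if (!all(cols %in% names(df))) {
    stop("cell table must have columns: ", paste(cols, collapse = ", "))
  }
  if (!all(df$cell_type %in% c("Tplus", "Tminus"))) {
    stop("cell_type must be 'Tplus' or 'Tminus'")
  }
  df[, cols]
}

# micropattern <-> plain list (for JSON round-trips)
pattern_to_list <- function(pattern) {
  pattern[c("kind", "disc_radius", "semi_major", "semi_minor",
            "interior_margin")]
}

pattern_from_list <- function(x) {
  micropattern(kind = x$kind, disc_radius = x$disc_radius,
               semi_major = x$semi_major, semi_minor = x$semi_minor,
               interior_margin = x$interior_margin)
}

#' Serialise a ground truth to JSON
#'
#' @param gt A [build_ground_truth()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  obj <- list(pattern = pattern_to_list(gt$pattern),
              Te = as.list(gt$Te),
              borders = lapply(gt$borders, function(b) {
                list(shape = b$shape, hda_side = b$hda_side,
                     components = b$components)
              }),
              bandwidths = gt$bandwidths)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground truth from JSON
#'
#' @param path JSON file written by [write_ground_truth()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path)
  borders <- lapply(obj$borders, function(b) {
    structure(list(shape = b$shape,
                   components = lapply(b$components, function(cp)
                     lapply(cp, as.numeric)),
                   hda_side = b$hda_side, symmetrized = TRUE),
              class = "fitted_border")
  })
  Te <- unlist(lapply(obj$Te, as.numeric))
  structure(list(pattern = pattern_from_list(obj$pattern),
                 borders = borders,
                 Te = Te[c("Tplus", "Tminus")],
                 bandwidths = lapply(obj$bandwidths, function(b)
                   as.numeric(unlist(b)))),
            class = "ground_truth")
}

#' Write an evaluation result to JSON
#'
#' @param result Named list (e.g. SCAPD and baseline metric values).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(result, path) {
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
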