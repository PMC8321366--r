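# File formats and run manifests tying the analysis stages together: palettes
# as JSON/CSV, observer click lists as CSV, and a JSON manifest per run so
# every seed and parameter of a result is recorded.

#' Write a palette to JSON
#'
#' One entry per colour: CIELAB coordinates, the derived (gamut-clipped) sRGB
#' hex value, provenance, and source information when present.
#'
#' @param palette A `relevant_palette`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_palette_json <- function(palette, path) {
  obj <- list(
    provenance = palette$provenance,
    size = palette$size,
    colors = data.frame(L = palette$colors[, 1], a = palette$colors[, 2],
                        b = palette$colors[, 3], hex = palette_hex(palette)))
  if (!is.null(palette$source)) obj$source <- palette$source
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a palette from JSON
#' @param path Path written by [write_palette_json()].
#' @return A `relevant_palette`.
#' @export
read_palette_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_palette(as.matrix(obj$colors[, c("L", "a", "b")]),
              provenance = obj$provenance,
              source = obj$source)
}

#' Write a palette as CSV
#' @param palette A `relevant_palette`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_palette_csv <- function(palette, path) {
  df <- data.frame(L = palette$colors[, 1], a = palette$colors[, 2],
                   b = palette$colors[, 3], hex = palette_hex(palette),
                   provenance = palette$provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an observer click list from CSV
#'
#' Expected columns: `image_id`, `observer_id`, `x`, `y` (extra columns pass
#' through).
#'
#' @param path CSV path.
#' @return Data frame of clicks.
#' @export
read_clicks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("image_id", "observer_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clicks CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a click list as CSV
#' @param clicks Data frame with at least `image_id`, `observer_id`, `x`, `y`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clicks_csv <- function(clicks, path) {
  utils::write.csv(clicks, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: free-form parameters (including
#' every seed used), the output files, and the package version. Analyses
#' here involve randomness (palette sampling, patch sampling, ICA), so
#' reproducibility is explicit rather than implied.
#'
#' @param path Manifest path (JSON).
#' @param params Named list of parameters and seeds.
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, outputs = character(0)) {
  jsonlite::write_json(list(
    package = "relcolors",
    version = as.character(utils::packageVersion("relcolors")),
    params = params,
    outputs = outputs), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
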