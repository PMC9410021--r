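#' Sparse centroid annotations
#'
#' A `centroid_set` maps vertebra ids (1 = C1 ... 26 = S2) to 3D positions in
#' millimetres, in the package's `(sagittal, row, column)` axis order. The
#' CSV/JSON on-disk schema uses columns `id, x_mm, y_mm, z_mm` in that same
#' axis order.
#'
#' @param id integer vertebra ids in 1..26, unique.
#' @param position numeric matrix with one row per id and 3 columns (mm).
#' @return An object of class `centroid_set`: a data.frame with columns
#'   `id`, `x_mm`, `y_mm`, `z_mm`, sorted by id.
#' @examples
#' cs <- centroid_set(8, matrix(c(10, 40, 60), 1))
#' centroid_position(cs, 8)
#' @export
centroid_set <- function(id = integer(), position = matrix(numeric(), 0, 3)) {
  id <- as.integer(id)
  position <- matrix(as.numeric(position), ncol = 3)
  assert_that(nrow(position) == length(id), "one position row per id required")
  validate_centroid_df(data.frame(id = id, x_mm = position[, 1],
                                  y_mm = position[, 2], z_mm = position[, 3]))
}

validate_centroid_df <- function(df) {
  assert_that(all(c("id", "x_mm", "y_mm", "z_mm") %in% names(df)),
              "centroid table needs columns id, x_mm, y_mm, z_mm")
  df$id <- as.integer(df$id)
  assert_that(!anyNA(df$id) && all(df$id >= 1L & df$id <= 26L),
              "vertebra ids must lie in 1..26")
  assert_that(!anyDuplicated(df$id),
              "duplicate vertebra id in centroid set: ",
              paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  pos <- as.matrix(df[c("x_mm", "y_mm", "z_mm")])
  assert_that(all(is.finite(pos)), "centroid positions must be finite")
  df <- df[order(df$id), c("id", "x_mm", "y_mm", "z_mm"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("centroid_set", "data.frame")
  df
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("Centroid set: %d vertebrae%s\n", nrow(x),
              if (nrow(x)) paste0(" (", vertebra_names()[min(x$id)], "-",
                                  vertebra_names()[max(x$id)], ")") else ""))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

#' @rdname centroid_set
#' @param cs a `centroid_set`.
#' @export
centroid_ids <- function(cs) cs$id

#' @rdname centroid_set
#' @param vertebra a single vertebra id present in `cs`.
#' @export
centroid_position <- function(cs, vertebra) {
  i <- match(as.integer(vertebra), cs$id)
  assert_that(!is.na(i), "vertebra ", vertebra, " not present in centroid set")
  unlist(cs[i, c("x_mm", "y_mm", "z_mm")], use.names = FALSE)
}

#' Read centroid annotations from CSV or JSON
#'
#' @param path file with columns/fields `id, x_mm, y_mm, z_mm`; the format is
#'   chosen by extension (`.json` vs anything else = CSV).
#' @return A [centroid_set()].
#' @export
read_centroids <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.csv(path)
  }
  if (nrow(df) == 0) return(centroid_set())
  validate_centroid_df(df)
}

#' Write centroid annotations
#'
#' Round-trips with [read_centroids()]: `read_centroids(write_centroids(cs, f))`
#' equals `cs`.
#'
#' @param cs a [centroid_set()].
#' @param path output `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(cs, path) {
  if (!inherits(cs, "centroid_set")) cs <- validate_centroid_df(cs)
  df <- as.data.frame(unclass(cs), stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
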