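# Reading/writing spot tables and scale factors, and mapping full-resolution
# spot coordinates into the pixel space of the provided tissue image.

# Header names recognised during column auto-detection (lower-cased).
.id_aliases <- c("barcode", "spot", "id", "spot_id", "tag", "cell")
.x_aliases  <- c("x", "imagecol", "pxl_col_in_fullres", "pxl_col", "xcoord", "x_coord")
.y_aliases  <- c("y", "imagerow", "pxl_row_in_fullres", "pxl_row", "ycoord", "y_coord")

.stop_spotgate <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spotgate_error")))
}

#' Construct a spot table
#'
#' A spot table is a `data.frame` carrying one row per capture spot: a unique
#' text tag, X/Y coordinates (full-resolution pixels unless already in image
#' space, origin top-left, y increasing downward), and any number of feature
#' columns (expression, signature scores, antibody levels, cluster labels).
#'
#' @param df A data.frame holding id, x, y and feature columns.
#' @param id_col,x_col,y_col Names of the tag and coordinate columns.
#' @return A `spot_table`: the same data.frame, classed, with the column
#'   roles recorded in attributes.
#' @export
spot_table <- function(df, id_col = "spot_id", x_col = "x", y_col = "y") {
  stopifnot(is.data.frame(df))
  for (col in c(id_col, x_col, y_col)) {
    if (!col %in% names(df)) {
      .stop_spotgate(sprintf("column '%s' not found in table", col),
                     "spotgate_column_error")
    }
  }
  ids <- as.character(df[[id_col]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    .stop_spotgate("spot tags must be non-empty", "spotgate_integrity_error")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    .stop_spotgate(sprintf("duplicated spot tag(s): %s",
                           paste(utils::head(dup, 5), collapse = ", ")),
                   "spotgate_integrity_error")
  }
  for (col in c(x_col, y_col)) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      bad <- if (is.numeric(v)) which(!is.finite(v))[1] else 1L
      .stop_spotgate(sprintf("coordinate column '%s' is not finite numeric (row %d)",
                             col, bad), "spotgate_parse_error")
    }
  }
  df[[id_col]] <- ids
  structure(df,
            id_col = id_col, x_col = x_col, y_col = y_col,
            class = c("spot_table", "data.frame"))
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots, %d feature column(s)\n",
              nrow(x), length(feature_names(x))))
  cat(sprintf("  id: '%s'  x: '%s'  y: '%s'%s\n",
              attr(x, "id_col"), attr(x, "x_col"), attr(x, "y_col"),
              if (all(c("x_px", "y_px") %in% names(x))) "  [pixel coords present]" else ""))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Spot tags of a spot table
#' @param table A `spot_table`.
#' @return Character vector of tags, in row order.
#' @export
spot_ids <- function(table) as.character(table[[attr(table, "id_col")]])

#' Spot coordinates in image-pixel space
#'
#' Returns the `x_px`/`y_px` columns added by [to_image_coords()] when
#' present, otherwise the raw coordinate columns.
#' @param table A `spot_table`.
#' @return Two-column numeric matrix (x, y).
#' @export
spot_coords <- function(table) {
  if (all(c("x_px", "y_px") %in% names(table))) {
    cbind(x = table$x_px, y = table$y_px)
  } else {
    cbind(x = table[[attr(table, "x_col")]], y = table[[attr(table, "y_col")]])
  }
}

#' Feature column names of a spot table
#' @param table A `spot_table`.
#' @param numeric_only Keep only numeric (testable/renderable) features.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table, numeric_only = FALSE) {
  reserved <- c(attr(table, "id_col"), attr(table, "x_col"), attr(table, "y_col"),
                "x_px", "y_px")
  out <- setdiff(names(table), reserved)
  if (numeric_only) out <- out[vapply(out, function(f) is.numeric(table[[f]]), logical(1))]
  out
}

.detect_column <- function(header, aliases, role, given) {
  if (!is.null(given)) {
    if (!given %in% header) {
      .stop_spotgate(sprintf("%s column '%s' not in header: %s",
                             role, given, paste(header, collapse = ", ")),
                     "spotgate_column_error")
    }
    return(given)
  }
  hits <- header[tolower(header) %in% aliases]
  if (length(hits) == 0) {
    .stop_spotgate(sprintf("cannot auto-detect the %s column; pass it explicitly (header: %s)",
                           role, paste(header, collapse = ", ")),
                   "spotgate_column_error")
  }
  if (length(hits) > 1) {
    .stop_spotgate(sprintf("ambiguous %s column, candidates: %s",
                           role, paste(hits, collapse = ", ")),
                   "spotgate_column_error")
  }
  hits
}

# Dot-decimal numeric parse; scientific notation accepted. A column is
# categorical if any non-missing cell fails to parse.
.parse_column <- function(v) {
  missing <- is.na(v) | v == "" | v == "NA"
  num <- suppressWarnings(as.numeric(v))
  if (any(is.na(num) & !missing)) return(v)
  num
}

#' Read a tab-separated spot table
#'
#' The file must have a header row and tab-separated fields. The tag and
#' coordinate columns are found by name; when not given they are
#' auto-detected from common dialects (`barcode`/`spot`/`id`,
#' `x`/`imagecol`/`pxl_col_in_fullres`, `y`/`imagerow`/`pxl_row_in_fullres`,
#' case-insensitive); ambiguity is an error, never a guess. All remaining
#' columns are kept as features: fully numeric columns are parsed as numbers
#' (dot decimal separator, scientific notation accepted), anything else is
#' retained as categorical text. Row order is preserved.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param id_col,x_col,y_col Column names; `NULL` to auto-detect.
#' @return A [spot_table()].
#' @export
read_spot_table <- function(path, id_col = NULL, x_col = NULL, y_col = NULL) {
  if (!file.exists(path)) .stop_spotgate(paste0("no such file: ", path), "spotgate_io_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  header <- names(df)
  id_col <- .detect_column(header, .id_aliases, "id", id_col)
  x_col  <- .detect_column(header, .x_aliases, "x", x_col)
  y_col  <- .detect_column(header, .y_aliases, "y", y_col)
  for (col in c(x_col, y_col)) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(num)) {
      .stop_spotgate(sprintf("unparseable coordinate in column '%s', row %d: '%s'",
                             col, which(is.na(num))[1], df[[col]][which(is.na(num))[1]]),
                     "spotgate_parse_error")
    }
    df[[col]] <- num
  }
  for (col in setdiff(header, c(id_col, x_col, y_col))) {
    df[[col]] <- .parse_column(df[[col]])
  }
  spot_table(df, id_col = id_col, x_col = x_col, y_col = y_col)
}

#' Write a spot table as TSV
#'
#' Tab-separated, header row, no quoting, full numeric precision (a write
#' followed by [read_spot_table()] reproduces values to better than 1e-9).
#' @param table A `spot_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 15, trim = TRUE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a Visium-style scalefactors JSON file
#'
#' Recognised keys: `tissue_hires_scalef`, `tissue_lowres_scalef`,
#' `spot_diameter_fullres`, `fiducial_diameter_fullres`. Absent scale
#' factors default to 1.0 with a warning; all values must be strictly
#' positive.
#'
#' @param path Path to `scalefactors_json.json`.
#' @return A `scale_factors` list with the four fields.
#' @export
read_scalefactors <- function(path) {
  if (!file.exists(path)) .stop_spotgate(paste0("no such file: ", path), "spotgate_io_error")
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) .stop_spotgate(
                    paste0("malformed scalefactors JSON: ", conditionMessage(e)),
                    "spotgate_parse_error"))
  known <- c("tissue_hires_scalef", "tissue_lowres_scalef",
             "spot_diameter_fullres", "fiducial_diameter_fullres")
  if (!any(known %in% names(obj))) {
    .stop_spotgate("no recognised Visium scalefactor key in JSON", "spotgate_parse_error")
  }
  defaults <- c(tissue_hires_scalef = 1, tissue_lowres_scalef = 1,
                spot_diameter_fullres = 1, fiducial_diameter_fullres = 1)
  out <- as.list(defaults)
  for (k in intersect(known, names(obj))) {
    v <- as.numeric(obj[[k]])
    if (!is.finite(v) || v <= 0) {
      .stop_spotgate(sprintf("scalefactor '%s' must be strictly positive, got %s", k, v),
                     "spotgate_range_error")
    }
    out[[k]] <- v
  }
  missing_sf <- setdiff(c("tissue_hires_scalef", "tissue_lowres_scalef"), names(obj))
  if (length(missing_sf)) {
    warning(sprintf("scalefactor(s) %s absent; defaulting to 1.0",
                    paste(missing_sf, collapse = ", ")))
  }
  structure(out, class = "scale_factors")
}

#' Write scale factors as Visium-style JSON
#' @param sf A `scale_factors` object (or named list with the Visium keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalefactors <- function(sf, path) {
  jsonlite::write_json(unclass(sf)[c("tissue_hires_scalef", "tissue_lowres_scalef",
                                     "spot_diameter_fullres", "fiducial_diameter_fullres")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.scale_factors <- function(x, ...) {
  cat("scale_factors:\n")
  for (k in names(x)) cat(sprintf("  %s: %g\n", k, x[[k]]))
  invisible(x)
}

#' Map spot coordinates into image-pixel space
#'
#' Multiplies full-resolution coordinates by the hires or lowres scale
#' factor to land them on the provided image raster; `which = "none"` is
#' the identity (for platforms whose coordinates are already in image
#' space). The original coordinates are kept; pixel coordinates are added
#' as `x_px`/`y_px`.
#'
#' @param table A `spot_table` with full-resolution coordinates (unless
#'   `which = "none"`).
#' @param sf A `scale_factors` object; may be `NULL` when `which = "none"`.
#' @param which One of `"hires"`, `"lowres"`, `"none"`.
#' @return The table with `x_px`, `y_px` columns.
#' @export
to_image_coords <- function(table, sf = NULL, which = c("hires", "lowres", "none")) {
  which <- match.arg(which)
  s <- switch(which,
              hires  = sf$tissue_hires_scalef,
              lowres = sf$tissue_lowres_scalef,
              none   = 1)
  if (is.null(s) || !is.finite(s)) {
    .stop_spotgate("scale factors required for which != 'none'", "spotgate_range_error")
  }
  table$x_px <- table[[attr(table, "x_col")]] * s
  table$y_px <- table[[attr(table, "y_col")]] * s
  table
}

#' Merge a feature matrix with spatial coordinates
#'
#' Inner join on the spot tag: the result keeps exactly the tags present in
#' both inputs, in the row order of `coords`, with the feature columns of
#' both. Duplicate feature names in `features` are dropped with a warning.
#'
#' @param features A data.frame (or `spot_table`) keyed by spot tag.
#' @param coords A `spot_table` providing the coordinates and row order.
#' @param features_id_col Tag column in `features`; `NULL` to auto-detect
#'   (falling back to the first column).
#' @return A `spot_table` over the tag intersection.
#' @export
merge_feature_matrix <- function(features, coords, features_id_col = NULL) {
  stopifnot(is.data.frame(features), inherits(coords, "spot_table"))
  if (is.null(features_id_col)) {
    if (inherits(features, "spot_table")) {
      features_id_col <- attr(features, "id_col")
    } else {
      hits <- names(features)[tolower(names(features)) %in% .id_aliases]
      features_id_col <- if (length(hits) == 1) hits else names(features)[1]
    }
  }
  ftags <- as.character(features[[features_id_col]])
  ctags <- spot_ids(coords)
  common <- intersect(ctags, ftags)
  if (length(common) == 0) {
    .stop_spotgate(sprintf(
      "no common spot tags; coords has e.g. [%s], features has e.g. [%s]",
      paste(utils::head(ctags, 5), collapse = ", "),
      paste(utils::head(ftags, 5), collapse = ", ")),
      "spotgate_join_error")
  }
  keep <- ctags %in% common
  out <- as.data.frame(coords)[keep, , drop = FALSE]
  frows <- features[match(ctags[keep], ftags),
                    setdiff(names(features), features_id_col), drop = FALSE]
  dup <- intersect(names(frows), names(out))
  if (length(dup)) {
    warning(sprintf("dropping duplicated feature column(s) from features: %s",
                    paste(dup, collapse = ", ")))
    frows <- frows[, setdiff(names(frows), dup), drop = FALSE]
  }
  out <- cbind(out, frows)
  rownames(out) <- NULL
  spot_table(out, id_col = attr(coords, "id_col"),
             x_col = attr(coords, "x_col"), y_col = attr(coords, "y_col"))
}

#' Read a PNG tissue image
#'
#' @param path Path to a PNG file (RGB, RGBA or grayscale; grayscale is
#'   expanded to RGB).
#' @return Numeric array `height x width x channels`, values in `[0, 1]`,
#'   origin top-left.
#' @export
read_tissue_image <- function(path) {
  if (!file.exists(path)) .stop_spotgate(paste0("no such file: ", path), "spotgate_io_error")
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 2) { # gray + alpha
    img <- array(c(rep(img[, , 1], 3), img[, , 2]), c(dim(img)[1:2], 4))
  }
  img
}

#' Write a tissue image as PNG
#' @param image Numeric array `height x width x channels` in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tissue_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
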