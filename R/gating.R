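# Polygon gates in image-pixel space: membership testing, ImageJ/Fiji ROI
# CSV interchange, cell-list interchange and gate-based table filtering.

#' Construct a polygon gate
#'
#' A named polygon in image-pixel space (origin top-left, y downward),
#' implicitly closed (the last vertex joins the first), optionally assigned
#' to comparison group 1 or group 2.
#'
#' @param name Gate name (unique within a [gate_set()]).
#' @param vertices Two-column numeric matrix or data.frame of (x, y) pixel
#'   coordinates; at least 3 vertices, no NA/NaN.
#' @param group One of `"none"`, `"group1"`, `"group2"`.
#' @return A `polygon_gate`.
#' @export
polygon_gate <- function(name, vertices, group = c("none", "group1", "group2")) {
  group <- match.arg(group)
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2) {
    .stop_spotgate("vertices must be a two-column numeric matrix", "spotgate_geometry_error")
  }
  if (nrow(v) < 3) {
    .stop_spotgate(sprintf("gate '%s' needs at least 3 vertices, got %d", name, nrow(v)),
                   "spotgate_geometry_error")
  }
  if (any(!is.finite(v))) {
    .stop_spotgate(sprintf("gate '%s' has non-finite vertices", name),
                   "spotgate_geometry_error")
  }
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(name = as.character(name), vertices = v, group = group),
            class = "polygon_gate")
}

#' @export
print.polygon_gate <- function(x, ...) {
  cat(sprintf("polygon_gate '%s': %d vertices, group = %s\n",
              x$name, nrow(x$vertices), x$group))
  invisible(x)
}

#' Construct a gate set
#'
#' An ordered collection of [polygon_gate()]s with unique names. Any number
#' of gates may be combined; each can independently be flagged as group 1
#' or group 2 for differential comparison.
#'
#' @param ... `polygon_gate` objects, or a single list of them.
#' @return A `gate_set`.
#' @export
gate_set <- function(...) {
  gates <- list(...)
  if (length(gates) == 1 && is.list(gates[[1]]) && !inherits(gates[[1]], "polygon_gate")) {
    gates <- gates[[1]]
  }
  ok <- vapply(gates, inherits, logical(1), what = "polygon_gate")
  if (!all(ok)) .stop_spotgate("all elements must be polygon_gate objects",
                               "spotgate_geometry_error")
  nm <- vapply(gates, function(g) g$name, character(1))
  if (anyDuplicated(nm)) {
    .stop_spotgate(sprintf("duplicated gate name(s): %s",
                           paste(unique(nm[duplicated(nm)]), collapse = ", ")),
                   "spotgate_integrity_error")
  }
  names(gates) <- nm
  structure(gates, class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("gate_set with %d gate(s):\n", length(x)))
  for (g in x) cat(sprintf("  %-20s %3d vertices  group=%s\n",
                           g$name, nrow(g$vertices), g$group))
  invisible(x)
}

#' Test points against a polygon gate
#'
#' Even-odd (ray-casting) membership. Points exactly on an edge or vertex
#' count as inside; for a degenerate zero-area polygon only boundary points
#' are inside. Even-odd (rather than nonzero winding) keeps the rule
#' well-defined for self-intersecting hand-drawn lassos.
#'
#' @param x,y Numeric vectors of point coordinates (pixel space).
#' @param poly A `polygon_gate`.
#' @param eps Absolute tolerance for the on-edge test.
#' @return Logical vector, one per point.
#' @export
point_in_polygon <- function(x, y, poly, eps = 1e-9) {
  stopifnot(inherits(poly, "polygon_gate"), length(x) == length(y))
  vx <- poly$vertices[, 1]; vy <- poly$vertices[, 2]
  n <- length(vx)
  inside <- logical(length(x))
  on_edge <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # on-segment: zero cross product (within eps, scaled by edge length)
    # and inside the segment's bounding box
    len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    cr <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
    on <- cr <= eps * max(1, len) &
      x >= pmin(xi, xj) - eps & x <= pmax(xi, xj) + eps &
      y >= pmin(yi, yj) - eps & y <= pmax(yi, yj) + eps
    on_edge <- on_edge | on
    j <- i
  }
  inside | on_edge
}

#' Spots captured by gates
#'
#' Union of per-gate membership over the selected gates, using the table's
#' image-pixel coordinates ([spot_coords()]).
#'
#' @param table A `spot_table` with pixel coordinates.
#' @param gates A `gate_set`.
#' @param select `"all"`, `"group1"`, `"group2"`, or a character vector of
#'   gate names.
#' @return Character vector of member spot tags, in table row order.
#' @export
spots_in_gates <- function(table, gates, select = "all") {
  stopifnot(inherits(gates, "gate_set"))
  if (length(select) == 1 && select %in% c("all", "group1", "group2")) {
    use <- switch(select,
                  all = gates,
                  group1 = Filter(function(g) g$group == "group1", gates),
                  group2 = Filter(function(g) g$group == "group2", gates))
  } else {
    missing_nm <- setdiff(select, names(gates))
    if (length(missing_nm)) {
      .stop_spotgate(sprintf("unknown gate name(s): %s",
                             paste(missing_nm, collapse = ", ")),
                     "spotgate_lookup_error")
    }
    use <- gates[select]
  }
  xy <- spot_coords(table)
  member <- logical(nrow(table))
  for (g in use) member <- member | point_in_polygon(xy[, 1], xy[, 2], g)
  spot_ids(table)[member]
}

#' Import an ImageJ/Fiji ROI vertex CSV as a polygon gate
#'
#' Vertex-list CSV as written by ImageJ's "save XY coordinates": one vertex
#' per line, comma-separated, optional header line (`X,Y` or `BX,BY`
#' variants) skipped if present.
#'
#' @param path Path to the CSV.
#' @param name Gate name; default the file name without extension.
#' @param group Group assignment for the imported gate.
#' @return A `polygon_gate`.
#' @export
import_imagej_roi <- function(path, name = NULL,
                              group = c("none", "group1", "group2")) {
  group <- match.arg(group)
  if (!file.exists(path)) .stop_spotgate(paste0("no such file: ", path), "spotgate_io_error")
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (anyNA(suppressWarnings(as.numeric(first)))) lines <- lines[-1]
  }
  if (length(lines) < 3) {
    .stop_spotgate(sprintf("ROI file '%s' has fewer than 3 vertices", path),
                   "spotgate_geometry_error")
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad)) {
    .stop_spotgate(sprintf("ROI file '%s': vertex line %d lacks two fields", path, bad[1]),
                   "spotgate_parse_error")
  }
  xs <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1)))
  ys <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(xs) || anyNA(ys)) {
    .stop_spotgate(sprintf("ROI file '%s': non-numeric vertex on line %d",
                           path, which(is.na(xs) | is.na(ys))[1]),
                   "spotgate_parse_error")
  }
  polygon_gate(name, cbind(xs, ys), group = group)
}

#' Export a polygon gate as an ImageJ/Fiji ROI vertex CSV
#'
#' Two-column CSV with header `X,Y`, one vertex per line, full precision,
#' closing vertex not duplicated.
#'
#' @param gate A `polygon_gate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_imagej_roi <- function(gate, path) {
  stopifnot(inherits(gate, "polygon_gate"))
  lines <- c("X,Y",
             paste(format(gate$vertices[, 1], digits = 15, trim = TRUE),
                   format(gate$vertices[, 2], digits = 15, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gate set as ROI CSVs plus a manifest
#'
#' One ROI CSV per gate (`<name>.roi.csv`) and a TSV manifest
#' (name, group, roi file) so group-1/group-2 assignment survives the
#' round trip.
#'
#' @param gates A `gate_set`.
#' @param dir Output directory (created if absent).
#' @param manifest Manifest file name within `dir`.
#' @return Manifest path, invisibly.
#' @export
write_gate_set <- function(gates, dir, manifest = "gates.tsv") {
  stopifnot(inherits(gates, "gate_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(names(gates), ".roi.csv")
  for (i in seq_along(gates)) export_imagej_roi(gates[[i]], file.path(dir, files[i]))
  man <- data.frame(name = names(gates),
                    group = vapply(gates, function(g) g$group, character(1)),
                    roi_file = files)
  utils::write.table(man, file.path(dir, manifest), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file.path(dir, manifest))
}

#' Read a gate set from a manifest or a directory of ROI CSVs
#'
#' With a manifest TSV (name, group, roi_file) the groups are restored;
#' with a bare directory every `*.csv` becomes a group-`none` gate named
#' by its file stem.
#'
#' @param path Manifest TSV path or a directory.
#' @return A `gate_set`.
#' @export
read_gate_set <- function(path) {
  if (dir.exists(path)) {
    man_path <- file.path(path, "gates.tsv")
    if (file.exists(man_path)) return(read_gate_set(man_path))
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) .stop_spotgate(paste0("no ROI CSV files in ", path),
                                       "spotgate_io_error")
    gates <- lapply(files, function(f)
      import_imagej_roi(f, name = sub("\\.roi$", "", tools::file_path_sans_ext(basename(f)))))
    return(gate_set(gates))
  }
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  gates <- lapply(seq_len(nrow(man)), function(i) {
    g <- import_imagej_roi(file.path(dirname(path), man$roi_file[i]),
                           name = man$name[i])
    g$group <- match.arg(man$group[i], c("none", "group1", "group2"))
    g
  })
  gate_set(gates)
}

#' Filter spot tables by a set of spot tags
#'
#' Each table keeps exactly the rows whose tag is in `ids`; row order and
#' columns are preserved. Tables left empty trigger a warning.
#'
#' @param tables A list of `spot_table`s (a single table is accepted).
#' @param ids Character vector (or set) of spot tags to keep.
#' @return A list of filtered `spot_table`s (same length and names).
#' @export
filter_tables <- function(tables, ids) {
  single <- inherits(tables, "spot_table")
  if (single) tables <- list(tables)
  ids <- unique(as.character(ids))
  out <- lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    stopifnot(inherits(tab, "spot_table"))
    keep <- spot_ids(tab) %in% ids
    if (!any(keep)) warning(sprintf("table %d: no spots survive the filter", i))
    res <- as.data.frame(tab)[keep, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "id_col") <- attr(tab, "id_col")
    attr(res, "x_col") <- attr(tab, "x_col")
    attr(res, "y_col") <- attr(tab, "y_col")
    class(res) <- c("spot_table", "data.frame")
    res
  })
  names(out) <- names(tables)
  if (single) out[[1]] else out
}

#' Import a plain-text spot/cell list
#'
#' One tag per line (the Single-Cell Virtual Cytometer interchange). An
#' optional single header line is skipped when it matches `id_col`
#' (case-insensitive); if a line carries extra tab- or comma-separated
#' fields only the first is used. Duplicates are collapsed.
#'
#' @param path Path to the list file.
#' @param id_col Header name to recognise and skip, if any.
#' @return Character vector of unique tags (insertion order).
#' @export
import_cell_list <- function(path, id_col = NULL) {
  if (!file.exists(path)) .stop_spotgate(paste0("no such file: ", path), "spotgate_io_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  lines <- vapply(strsplit(lines, "[\t,]"), `[[`, character(1), 1)
  if (length(lines) && !is.null(id_col) &&
      tolower(lines[1]) == tolower(id_col)) {
    lines <- lines[-1]
  }
  if (!length(lines)) {
    warning(sprintf("cell list '%s' is empty", path))
    return(character(0))
  }
  unique(lines)
}

#' Export a spot/cell list
#'
#' Newline-separated tags, directly re-importable with
#' [import_cell_list()].
#' @param ids Character vector of tags.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_cell_list <- function(ids, path) {
  writeLines(unique(as.character(ids)), path)
  invisible(path)
}
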