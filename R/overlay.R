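# Mapping feature values and cluster labels to colors/opacities and
# compositing them as filled discs over the tissue image; slideshow batch
# rendering; zoom and native-resolution export.

.two_color_presets <- list(
  black_white   = list(start = c(0, 0, 0),       end = c(255, 255, 255)),
  blue_yellow   = list(start = c(0, 0, 255),     end = c(255, 255, 0)),
  blue_red      = list(start = c(0, 0, 255),     end = c(255, 0, 0)),
  white_red     = list(start = c(255, 255, 255), end = c(255, 0, 0)),
  green_magenta = list(start = c(0, 255, 0),     end = c(255, 0, 255))
)

#' Preset gradient names
#'
#' Eight presets: five two-color low-to-high ramps plus the Turbo, Viridis
#' and Inferno rainbow lookup tables.
#' @return Character vector of preset names accepted by [gradient_spec()].
#' @export
preset_gradients <- function() {
  c(names(.two_color_presets), "turbo", "viridis", "inferno")
}

#' Construct a gradient specification
#'
#' Describes how feature values map to colors: a two-color channel-wise
#' ramp or one of the Turbo/Viridis/Inferno 256-entry lookup tables, with
#' min/max intensity clipping bounds (the contrast sliders: values outside
#' `[vmin, vmax]` are clamped so outliers cannot wash out the map).
#'
#' @param kind A preset name from [preset_gradients()], or `"two_color"`
#'   with explicit `start_rgb`/`end_rgb`.
#' @param start_rgb,end_rgb Length-3 RGB vectors in `[0, 255]`
#'   (two-color gradients only).
#' @param vmin,vmax Clip bounds in feature units; `NA` means "take the
#'   finite data range at render time". When both are set, `vmin < vmax`.
#' @param legend_rgb Legend/text color.
#' @return A `gradient_spec`.
#' @export
gradient_spec <- function(kind = "viridis",
                          start_rgb = c(0, 0, 0), end_rgb = c(255, 255, 255),
                          vmin = NA_real_, vmax = NA_real_,
                          legend_rgb = c(0, 0, 0)) {
  if (kind %in% names(.two_color_presets)) {
    start_rgb <- .two_color_presets[[kind]]$start
    end_rgb <- .two_color_presets[[kind]]$end
    kind <- "two_color"
  }
  if (!kind %in% c("two_color", "turbo", "viridis", "inferno")) {
    .stop_spotgate(sprintf("unknown gradient kind '%s'; presets: %s", kind,
                           paste(preset_gradients(), collapse = ", ")),
                   "spotgate_lookup_error")
  }
  for (v in list(start_rgb, end_rgb, legend_rgb)) {
    if (length(v) != 3 || any(!is.finite(v)) || any(v < 0 | v > 255)) {
      .stop_spotgate("RGB channels must be length-3 in [0, 255]", "spotgate_range_error")
    }
  }
  if (is.finite(vmin) && is.finite(vmax) && vmin >= vmax) {
    .stop_spotgate("vmin must be strictly less than vmax", "spotgate_range_error")
  }
  structure(list(kind = kind, start_rgb = start_rgb, end_rgb = end_rgb,
                 vmin = vmin, vmax = vmax, legend_rgb = legend_rgb),
            class = "gradient_spec")
}

#' Construct an opacity specification
#'
#' Constant opacity, or a transparency gradient driven by the feature
#' value: `alpha = base_alpha * clamp((v - amin) / (amax - amin), 0, 1)`,
#' so spots below `amin` vanish and spots above `amax` get the full base
#' opacity.
#'
#' @param mode `"constant"` or `"gradient"`.
#' @param base_alpha Base opacity in `[0, 1]`.
#' @param amin,amax Gradient thresholds in feature units (`amin < amax`);
#'   `NA` means "take the finite data range at render time".
#' @return An `opacity_spec`.
#' @export
opacity_spec <- function(mode = c("constant", "gradient"), base_alpha = 1,
                         amin = NA_real_, amax = NA_real_) {
  mode <- match.arg(mode)
  if (!is.finite(base_alpha) || base_alpha < 0 || base_alpha > 1) {
    .stop_spotgate("base_alpha must lie in [0, 1]", "spotgate_range_error")
  }
  if (mode == "gradient" && is.finite(amin) && is.finite(amax) && amin >= amax) {
    .stop_spotgate("amin must be strictly less than amax", "spotgate_range_error")
  }
  structure(list(mode = mode, base_alpha = base_alpha, amin = amin, amax = amax),
            class = "opacity_spec")
}

# Fill NA clip bounds from the finite data range; constant data gets a
# half-unit pad so the map stays defined.
.resolve_bounds <- function(lo, hi, values) {
  fin <- values[is.finite(values)]
  if (!length(fin)) fin <- c(0, 1)
  if (!is.finite(lo)) lo <- min(fin)
  if (!is.finite(hi)) hi <- max(fin)
  if (lo >= hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  c(lo, hi)
}

#' Normalize a feature value to `[0, 1]` under a gradient's clip bounds
#'
#' `t = clamp((v - vmin) / (vmax - vmin), 0, 1)`; monotone non-decreasing
#' in `v`. Non-finite values map to `NA` (rendered fully transparent).
#'
#' @param v Numeric vector of feature values.
#' @param spec A `gradient_spec` with resolved `vmin`/`vmax`.
#' @return Numeric vector in `[0, 1]` (or `NA`).
#' @export
normalize_value <- function(v, spec) {
  if (!is.finite(spec$vmin) || !is.finite(spec$vmax)) {
    .stop_spotgate("vmin/vmax must be set (resolve them from data first)",
                   "spotgate_range_error")
  }
  t <- (v - spec$vmin) / (spec$vmax - spec$vmin)
  t <- pmin(pmax(t, 0), 1)
  t[!is.finite(v)] <- NA_real_
  t
}

# hex "#RRGGBB" vector -> n x 3 integer matrix
.hex_to_rgb <- function(hex) t(grDevices::col2rgb(hex))

#' Map normalized values to RGB colors
#'
#' Two-color gradients interpolate channel-wise between the start and end
#' colors (rounded to integer channels); the rainbow kinds interpolate
#' linearly between adjacent entries of the embedded 256-entry lookup
#' table, hitting the first/last entry exactly at `t = 0` / `t = 1`.
#'
#' @param t Numeric vector in `[0, 1]` (NA allowed; yields NA rows).
#' @param spec A `gradient_spec`.
#' @return Integer matrix `length(t) x 3` with columns r, g, b in
#'   `[0, 255]`.
#' @export
value_to_color <- function(t, spec) {
  if (any(t < -1e-12 | t > 1 + 1e-12, na.rm = TRUE)) {
    .stop_spotgate("t must lie in [0, 1]", "spotgate_range_error")
  }
  t <- pmin(pmax(t, 0), 1)
  n <- length(t)
  out <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("r", "g", "b")))
  ok <- which(is.finite(t))
  if (!length(ok)) return(out)
  if (spec$kind == "two_color") {
    for (ch in 1:3) {
      out[ok, ch] <- as.integer(round(spec$start_rgb[ch] +
                                        t[ok] * (spec$end_rgb[ch] - spec$start_rgb[ch])))
    }
  } else {
    lut <- .hex_to_rgb(switch(spec$kind,
                              turbo = .turbo_lut,
                              viridis = .viridis_lut,
                              inferno = .inferno_lut))
    pos <- t[ok] * 255
    i0 <- pmin(floor(pos), 254)
    frac <- pos - i0
    for (ch in 1:3) {
      out[ok, ch] <- as.integer(round(lut[i0 + 1, ch] * (1 - frac) +
                                        lut[i0 + 2, ch] * frac))
    }
  }
  out
}

#' Map feature values to opacities
#'
#' @param v Numeric vector of feature values.
#' @param spec An `opacity_spec` with resolved thresholds.
#' @return Numeric vector of alphas in `[0, 1]`; non-finite values give 0.
#' @export
value_to_alpha <- function(v, spec) {
  if (spec$mode == "constant") {
    a <- rep(spec$base_alpha, length(v))
  } else {
    if (!is.finite(spec$amin) || !is.finite(spec$amax)) {
      .stop_spotgate("amin/amax must be set (resolve them from data first)",
                     "spotgate_range_error")
    }
    a <- spec$base_alpha * pmin(pmax((v - spec$amin) / (spec$amax - spec$amin), 0), 1)
  }
  a[!is.finite(v)] <- 0
  a
}

.cluster_palette_presets <- list(
  classic = c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD", "#8C564B",
              "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF", "#AEC7E8", "#FFBB78",
              "#98DF8A", "#FF9896", "#C5B0D5", "#C49C94"),
  bright  = c("#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231", "#911EB4",
              "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE", "#008080", "#E6BEFF",
              "#9A6324", "#FFFAC8", "#800000", "#AAFFC3"),
  muted   = c("#332288", "#88CCEE", "#44AA99", "#117733", "#999933", "#DDCC77",
              "#CC6677", "#882255", "#AA4499", "#DDDDDD", "#6699CC", "#661100",
              "#994455", "#997700", "#004488", "#EE99AA")
)

#' Construct a cluster palette
#'
#' One of three preset qualitative palettes (16 colors each) or a custom
#' color list. Colors are assigned to clusters in sorted label order and
#' then re-ordered by the palette's permutation, so a shuffle seed
#' reproduces the same map across runs.
#'
#' @param palette_id `"classic"`, `"bright"` or `"muted"`.
#' @param colors Optional custom vector of hex colors (overrides
#'   `palette_id`'s colors, keeps its name).
#' @return A `cluster_palette` with identity permutation.
#' @export
cluster_palette <- function(palette_id = c("classic", "bright", "muted"),
                            colors = NULL) {
  palette_id <- match.arg(palette_id)
  if (is.null(colors)) colors <- .cluster_palette_presets[[palette_id]]
  colors <- toupper(as.character(colors))
  if (length(colors) < 2) .stop_spotgate("a palette needs at least 2 colors",
                                         "spotgate_range_error")
  structure(list(colors = colors, palette_id = palette_id,
                 permutation = seq_along(colors)),
            class = "cluster_palette")
}

#' Number of preset cluster palettes
#' @return Integer count (3).
#' @export
n_cluster_palettes <- function() length(.cluster_palette_presets)

#' Shuffle the color-to-cluster assignment of a palette
#'
#' Applies a seeded permutation to the color indices; the color multiset is
#' unchanged, only which cluster gets which color. With k clusters and the
#' preset palettes this spans `n_cluster_palettes() * k!` distinct maps.
#' The caller's RNG state is left untouched.
#'
#' @param palette A `cluster_palette`.
#' @param seed Integer seed; the same seed always yields the same
#'   permutation.
#' @return The palette with a new `permutation`.
#' @export
shuffle_palette <- function(palette, seed) {
  stopifnot(inherits(palette, "cluster_palette"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  palette$permutation <- sample(length(palette$colors))
  palette
}

#' Colors for a vector of cluster labels
#'
#' Labels are mapped in sorted order to the palette's (possibly shuffled)
#' colors.
#'
#' @param labels Vector of cluster labels (integer, factor or text).
#' @param palette A `cluster_palette`.
#' @return Character vector of hex colors, one per label.
#' @export
cluster_colors <- function(labels, palette) {
  lev <- sort(unique(labels))
  if (length(lev) > length(palette$colors)) {
    .stop_spotgate(sprintf("%d clusters but only %d palette colors",
                           length(lev), length(palette$colors)),
                   "spotgate_range_error")
  }
  assigned <- palette$colors[palette$permutation]
  assigned[match(labels, lev)]
}

# Nearest-neighbor raster rescale; z is the linear scale factor.
.zoom_raster <- function(image, z) {
  d <- dim(image)
  H2 <- max(1L, as.integer(round(d[1] * z)))
  W2 <- max(1L, as.integer(round(d[2] * z)))
  ri <- pmin(pmax(ceiling((seq_len(H2) - 0.5) / z), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(W2) - 0.5) / z), 1L), d[2])
  image[ri, ci, , drop = FALSE]
}

#' Composite spot discs over a tissue image
#'
#' Draws hard-edged filled discs (a pixel is covered when its center lies
#' within `dot_radius` of the spot) in table order using source-over
#' compositing, `out = alpha * color + (1 - alpha) * background` per
#' channel, then optionally rescales the final raster. Pixel centers are at
#' `(col - 0.5, row - 0.5)` in the image coordinate system (origin
#' top-left). Hard edges keep rendering exactly reproducible; no
#' antialiasing is applied.
#'
#' @param image Numeric array `H x W x channels` in `[0, 1]` (RGB or RGBA;
#'   an alpha channel is preserved untouched).
#' @param x,y Spot centers in image-pixel coordinates.
#' @param color Spot colors: `n x 3` matrix in `[0, 255]` or a vector of
#'   hex colors (recycled if length 1).
#' @param alpha Per-spot opacities in `[0, 1]` (recycled if length 1);
#'   `NA` alpha or non-finite coordinates skip the spot.
#' @param dot_radius Disc radius in pixels.
#' @param zoom Output scale in percent, within `[10, 200]`; 100 keeps the
#'   native raster.
#' @return The composited image array.
#' @export
render_overlay <- function(image, x, y, color, alpha = 1, dot_radius = 3,
                           zoom = 100) {
  if (!is.finite(zoom) || zoom < 10 || zoom > 200) {
    .stop_spotgate("zoom must lie in [10, 200] percent", "spotgate_range_error")
  }
  d <- dim(image)
  if (length(d) != 3) .stop_spotgate("image must be an H x W x channels array",
                                     "spotgate_geometry_error")
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.character(color)) color <- .hex_to_rgb(color)
  if (is.null(dim(color))) color <- matrix(color, ncol = 3, byrow = TRUE)
  if (nrow(color) == 1 && n > 1) color <- color[rep(1, n), , drop = FALSE]
  alpha <- rep_len(alpha, n)
  H <- d[1]; W <- d[2]
  col01 <- color / 255
  r2 <- dot_radius^2
  for (s in seq_len(n)) {
    a <- alpha[s]
    if (!is.finite(a) || a <= 0 || !is.finite(x[s]) || !is.finite(y[s]) ||
        anyNA(col01[s, ])) next
    r0 <- max(1L, as.integer(floor(y[s] - dot_radius)))
    r1 <- min(H, as.integer(ceiling(y[s] + dot_radius + 1)))
    c0 <- max(1L, as.integer(floor(x[s] - dot_radius)))
    c1 <- min(W, as.integer(ceiling(x[s] + dot_radius + 1)))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1
    cols <- c0:c1
    dy2 <- ((rows - 0.5) - y[s])^2
    dx2 <- ((cols - 0.5) - x[s])^2
    covered <- outer(dy2, dx2, `+`) <= r2
    if (!any(covered)) next
    for (ch in 1:3) {
      block <- image[rows, cols, ch, drop = FALSE]
      dim(block) <- dim(covered)
      block[covered] <- a * col01[s, ch] + (1 - a) * block[covered]
      image[rows, cols, ch] <- block
    }
  }
  if (zoom != 100) image <- .zoom_raster(image, zoom / 100)
  image
}

# Resolve a gradient/opacity pair against actual feature values.
.resolve_specs <- function(values, gradient, opacity) {
  vb <- .resolve_bounds(gradient$vmin, gradient$vmax, values)
  gradient$vmin <- vb[1]; gradient$vmax <- vb[2]
  if (opacity$mode == "gradient") {
    ab <- .resolve_bounds(opacity$amin, opacity$amax, values)
    opacity$amin <- ab[1]; opacity$amax <- ab[2]
  }
  list(gradient = gradient, opacity = opacity)
}

#' Render a feature expression overlay
#'
#' Looks up the feature column, applies the gradient's min/max intensity
#' clipping, maps values to colors and opacities and composites the discs
#' over the image.
#'
#' @param image Tissue image array (see [render_overlay()]).
#' @param table A `spot_table` with pixel coordinates.
#' @param feature Numeric feature column name.
#' @param gradient A `gradient_spec`; unset `vmin`/`vmax` are resolved
#'   from the finite feature range.
#' @param opacity An `opacity_spec`; unset thresholds resolved likewise.
#' @param dot_radius,zoom Passed to [render_overlay()].
#' @return List with the rendered `image` and the resolved `gradient` and
#'   `opacity` specs.
#' @export
render_feature_overlay <- function(image, table, feature,
                                   gradient = gradient_spec("viridis"),
                                   opacity = opacity_spec("constant", 1),
                                   dot_radius = 3, zoom = 100) {
  if (!feature %in% names(table) || !is.numeric(table[[feature]])) {
    .stop_spotgate(sprintf("no numeric feature column '%s'", feature),
                   "spotgate_lookup_error")
  }
  v <- table[[feature]]
  rs <- .resolve_specs(v, gradient, opacity)
  t <- normalize_value(v, rs$gradient)
  cols <- value_to_color(t, rs$gradient)
  al <- value_to_alpha(v, rs$opacity)
  xy <- spot_coords(table)
  img <- render_overlay(image, xy[, 1], xy[, 2], cols, al,
                        dot_radius = dot_radius, zoom = zoom)
  list(image = img, gradient = rs$gradient, opacity = rs$opacity)
}

#' Render a cluster overlay
#'
#' @param image Tissue image array.
#' @param table A `spot_table` with pixel coordinates.
#' @param cluster_col Column holding cluster labels.
#' @param palette A `cluster_palette` (shuffle it first for a different
#'   color arrangement).
#' @param alpha Constant dot opacity.
#' @param dot_radius,zoom Passed to [render_overlay()].
#' @return The rendered image array.
#' @export
render_cluster_overlay <- function(image, table, cluster_col,
                                   palette = cluster_palette("classic"),
                                   alpha = 1, dot_radius = 3, zoom = 100) {
  if (!cluster_col %in% names(table)) {
    .stop_spotgate(sprintf("no cluster column '%s'", cluster_col),
                   "spotgate_lookup_error")
  }
  cols <- cluster_colors(table[[cluster_col]], palette)
  xy <- spot_coords(table)
  render_overlay(image, xy[, 1], xy[, 2], cols, alpha,
                 dot_radius = dot_radius, zoom = zoom)
}

#' Batch-render one overlay PNG per feature (slide show)
#'
#' Writes `<feature>.png` per requested feature plus a TSV manifest
#' (feature, file, vmin, vmax, status). Missing features are skipped with
#' a warning and recorded in the manifest; each written image is identical
#' to a single [render_feature_overlay()] call.
#'
#' @param image Tissue image array.
#' @param table A `spot_table` with pixel coordinates.
#' @param features Character vector of feature names.
#' @param gradient,opacity Specs applied to every feature (unset bounds
#'   are resolved per feature).
#' @param outdir Output directory (created if absent).
#' @param dot_radius,zoom Passed to [render_overlay()].
#' @return The manifest data.frame, invisibly; written to
#'   `slideshow_manifest.tsv` in `outdir`.
#' @export
slideshow <- function(image, table, features,
                      gradient = gradient_spec("viridis"),
                      opacity = opacity_spec("constant", 1),
                      outdir, dot_radius = 3, zoom = 100) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(features, function(f) {
    if (!f %in% names(table) || !is.numeric(table[[f]])) {
      warning(sprintf("feature '%s' missing or not numeric; skipped", f))
      return(data.frame(feature = f, file = NA_character_,
                        vmin = NA_real_, vmax = NA_real_, status = "missing",
                        stringsAsFactors = FALSE))
    }
    res <- render_feature_overlay(image, table, f, gradient, opacity,
                                  dot_radius = dot_radius, zoom = zoom)
    file <- paste0(f, ".png")
    write_tissue_image(res$image, file.path(outdir, file))
    data.frame(feature = f, file = file,
               vmin = res$gradient$vmin, vmax = res$gradient$vmax,
               status = "ok", stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), file = character(0),
               vmin = numeric(0), vmax = numeric(0), status = character(0))
  utils::write.table(manifest, file.path(outdir, "slideshow_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
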