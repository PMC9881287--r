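# Fully synthetic, ground-truth-annotated datasets: a Visium-like hexagonal
# spot grid over a flat tissue image, Gaussian feature noise, planted region
# effects, a region gate, and region-correlated cluster labels. Everything
# the other modules read can be generated here, so no download is ever
# needed.

#' Specify a synthetic spatial dataset
#'
#' Spots sit on a hexagonal-offset grid (odd rows shifted half a spacing,
#' rows `spacing * sqrt(3)/2` apart), mimicking Visium spot geometry so gate
#' areas translate predictably into spot counts. Features are Gaussian
#' noise; the planted features gain a mean shift of
#' `effect_size * noise_sd` for every spot inside `region`. The generator
#' emulates post-normalization expression/score tables, not raw counts.
#'
#' @param n_rows,n_cols Grid dimensions (default 15 x 14, about 200 spots).
#' @param spacing Pixels between spot centers at full resolution.
#' @param n_features Number of feature columns.
#' @param n_planted Number of features carrying the region effect.
#' @param effect_size Mean shift inside the region, in units of `noise_sd`.
#' @param noise_sd Per-feature standard deviation.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param region Optional `polygon_gate` in image-pixel coordinates
#'   defining the "inside" population; `NULL` uses a central rectangle.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 15, n_cols = 14, spacing = 20,
                           n_features = 500, n_planted = 5,
                           effect_size = 2, noise_sd = 1, seed = 1,
                           region = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, spacing >= 2,
            n_features >= 1, n_planted >= 0, n_planted <= n_features,
            effect_size >= 0, noise_sd > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 n_features = n_features, n_planted = n_planted,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed), region = region),
            class = "synthetic_spec")
}

# run expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic spatial dataset
#'
#' Builds the full bundle the rest of the package consumes: a tissue image
#' (flat background with the region outline faintly drawn), a spot table in
#' full-resolution coordinates with `n_features` numeric features, a
#' scale-factor set (hires 0.5, so full-resolution and image coordinates
#' genuinely differ), the region gate (assigned to group 1), and a truth
#' manifest naming the planted features and per-spot region membership.
#'
#' @param spec A [synthetic_spec()].
#' @return List (class `synthetic_dataset`) with `image`, `spots`
#'   (a `spot_table` with `x_px`/`y_px` already computed), `scalefactors`,
#'   `gates`, `truth` (list: `planted`, `spots` data.frame with
#'   `spot_id`, `inside`), and `spec`.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    margin <- spec$spacing
    rows <- rep(seq_len(spec$n_rows) - 1L, each = spec$n_cols)
    cols <- rep(seq_len(spec$n_cols) - 1L, times = spec$n_rows)
    x_full <- margin + (cols + 0.5 * (rows %% 2)) * spec$spacing
    y_full <- margin + rows * spec$spacing * sqrt(3) / 2
    n <- length(x_full)
    sf <- structure(list(tissue_hires_scalef = 0.5,
                         tissue_lowres_scalef = 0.25,
                         spot_diameter_fullres = spec$spacing * 0.7,
                         fiducial_diameter_fullres = spec$spacing * 1.2),
                    class = "scale_factors")
    W <- ceiling((max(x_full) + margin) * sf$tissue_hires_scalef)
    H <- ceiling((max(y_full) + margin) * sf$tissue_hires_scalef)
    region <- spec$region
    if (is.null(region)) {
      region <- polygon_gate("region",
                             cbind(c(0.25, 0.65, 0.65, 0.25) * W,
                                   c(0.25, 0.25, 0.65, 0.65) * H),
                             group = "group1")
    } else if (region$group != "group1") {
      region$group <- "group1"
    }
    x_px <- x_full * sf$tissue_hires_scalef
    y_px <- y_full * sf$tissue_hires_scalef
    inside <- point_in_polygon(x_px, y_px, region)
    if (!any(inside)) {
      .stop_spotgate("the region gate covers no spots", "spotgate_spec_error")
    }
    feat_names <- sprintf("feature_%03d", seq_len(spec$n_features))
    planted_idx <- if (spec$n_planted > 0) sample(spec$n_features, spec$n_planted) else integer(0)
    X <- matrix(stats::rnorm(n * spec$n_features, sd = spec$noise_sd),
                nrow = n, ncol = spec$n_features, dimnames = list(NULL, feat_names))
    if (length(planted_idx)) {
      X[inside, planted_idx] <- X[inside, planted_idx] +
        spec$effect_size * spec$noise_sd
    }
    df <- data.frame(spot_id = sprintf("spot_%04d", seq_len(n)),
                     x = x_full, y = y_full, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(X))
    spots <- spot_table(df)
    spots <- to_image_coords(spots, sf, which = "hires")
    image <- array(0.95, dim = c(H, W, 3))
    image <- .draw_outline(image, region$vertices, value = 0.75)
    truth <- list(planted = feat_names[sort(planted_idx)],
                  spots = data.frame(spot_id = df$spot_id, inside = inside,
                                     stringsAsFactors = FALSE))
    structure(list(image = image, spots = spots, scalefactors = sf,
                   gates = gate_set(list(region)), truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

# set pixels along polygon edges (sampled densely) to `value` in all channels
.draw_outline <- function(image, vertices, value = 0.75) {
  d <- dim(image)
  v <- rbind(vertices, vertices[1, ])
  for (i in seq_len(nrow(v) - 1)) {
    len <- sqrt(sum((v[i + 1, ] - v[i, ])^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
    px <- v[i, 1] + ts * (v[i + 1, 1] - v[i, 1])
    py <- v[i, 2] + ts * (v[i + 1, 2] - v[i, 2])
    r <- pmin(pmax(ceiling(py), 1), d[1])
    c <- pmin(pmax(ceiling(px), 1), d[2])
    for (ch in seq_len(min(3, d[3]))) image[cbind(r, c, ch)] <- value
  }
  image
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d spots, %d features (%d planted, effect %.1f SD), image %dx%d\n",
              nrow(x$spots), x$spec$n_features, x$spec$n_planted,
              x$spec$effect_size, dim(x$image)[2], dim(x$image)[1]))
  invisible(x)
}

#' Region-correlated cluster labels
#'
#' Spots inside the region draw labels uniformly from clusters
#' `1..ceiling(k/2)`, outside spots from the remainder, so `k = 2`
#' separates the region perfectly. Deterministic per seed.
#'
#' @param table A `spot_table` with pixel coordinates.
#' @param k Number of clusters (`1 <= k <=` number of spots).
#' @param seed Integer seed.
#' @param region A `polygon_gate` defining "inside" (image-pixel space).
#' @return Integer vector of labels in `1..k`, one per spot.
#' @export
make_cluster_labels <- function(table, k, seed, region) {
  n <- nrow(table)
  if (k < 1 || k > n) {
    .stop_spotgate(sprintf("k must lie in [1, %d]", n), "spotgate_spec_error")
  }
  xy <- spot_coords(table)
  inside <- point_in_polygon(xy[, 1], xy[, 2], region)
  .with_seed(seed, {
    labels <- integer(n)
    k_in <- ceiling(k / 2)
    labels[inside] <- sample.int(k_in, sum(inside), replace = TRUE)
    if (k_in < k) {
      labels[!inside] <- sample.int(k - k_in, sum(!inside), replace = TRUE) + k_in
    } else {
      labels[!inside] <- sample.int(k_in, sum(!inside), replace = TRUE)
    }
    labels
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the package reads back: `spots.tsv`,
#' `scalefactors_json.json`, `tissue.png`, a gate directory with ROI CSVs
#' and manifest, and the truth manifest (`truth_features.tsv`,
#' `truth_spots.tsv`). Output is byte-identical for a given spec.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # drop derived pixel coords; readers recompute them from the scalefactors
  tab <- ds$spots
  tab$x_px <- NULL; tab$y_px <- NULL
  write_spot_table(tab, file.path(dir, "spots.tsv"))
  write_scalefactors(ds$scalefactors, file.path(dir, "scalefactors_json.json"))
  write_tissue_image(ds$image, file.path(dir, "tissue.png"))
  write_gate_set(ds$gates, file.path(dir, "gates"))
  utils::write.table(data.frame(feature = ds$truth$planted, planted = TRUE),
                     file.path(dir, "truth_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$spots, file.path(dir, "truth_spots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
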