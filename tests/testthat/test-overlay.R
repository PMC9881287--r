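# Color/opacity mapping, palette shuffling and disc compositing.

test_that("normalize_value clamps to the clip bounds and stays monotone", {
  spec <- gradient_spec("black_white", vmin = 2, vmax = 6)
  expect_equal(normalize_value(c(2, 6, 4), spec), c(0, 1, 0.5))
  expect_equal(normalize_value(c(-10, 100), spec), c(0, 1))  # outlier clipping
  expect_true(is.na(normalize_value(NaN, spec)))
  v <- sort(runif(100, -5, 15))
  expect_true(all(diff(normalize_value(v, spec)) >= 0))
})

test_that("two-color gradients interpolate channel-wise with rounding", {
  spec <- gradient_spec("black_white", vmin = 0, vmax = 1)
  expect_equal(unname(value_to_color(0, spec)[1, ]), c(0, 0, 0))
  expect_equal(unname(value_to_color(1, spec)[1, ]), c(255, 255, 255))
  expect_equal(unname(value_to_color(0.5, spec)[1, ]), c(128, 128, 128))
})

test_that("rainbow LUTs hit their endpoints exactly and interpolate between entries", {
  for (kind in c("turbo", "viridis", "inferno")) {
    spec <- gradient_spec(kind, vmin = 0, vmax = 1)
    first <- value_to_color(0, spec)[1, ]
    last <- value_to_color(1, spec)[1, ]
    mid <- value_to_color(128 / 255, spec)[1, ]  # lands exactly on entry 129
    lut_hex <- switch(kind, turbo = spotgate:::.turbo_lut,
                      viridis = spotgate:::.viridis_lut,
                      inferno = spotgate:::.inferno_lut)
    lut_rgb <- t(grDevices::col2rgb(lut_hex))
    expect_equal(unname(first), unname(lut_rgb[1, ]))
    expect_equal(unname(last), unname(lut_rgb[256, ]))
    expect_equal(unname(mid), unname(lut_rgb[129, ]))
  }
})

test_that("value_to_alpha implements constant and thresholded gradient modes", {
  const <- opacity_spec("constant", 0.7)
  expect_equal(value_to_alpha(c(-1, 0, 99), const), rep(0.7, 3))
  grad <- opacity_spec("gradient", 1, amin = 10, amax = 20)
  expect_equal(value_to_alpha(c(5, 10), grad), c(0, 0))
  expect_equal(value_to_alpha(c(20, 50), grad), c(1, 1))
  expect_equal(value_to_alpha(15, grad), 0.5)
  half <- opacity_spec("gradient", 0.6, amin = 0, amax = 1)
  expect_equal(value_to_alpha(0.5, half), 0.3)
  expect_equal(value_to_alpha(NA, half), 0)
})

test_that("shuffle_palette is a seeded bijection conserving the color multiset", {
  pal <- cluster_palette("bright")
  s1 <- shuffle_palette(pal, 99)
  s2 <- shuffle_palette(pal, 99)
  expect_identical(s1$permutation, s2$permutation)
  expect_false(identical(shuffle_palette(pal, 100)$permutation, s1$permutation))
  expect_identical(sort(s1$permutation), seq_along(pal$colors))
  expect_identical(sort(s1$colors[s1$permutation]), sort(pal$colors))
  # caller RNG is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(shuffle_palette(pal, 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("cluster_colors assigns by sorted label order and bounds cluster count", {
  pal <- cluster_palette("classic")
  cols <- cluster_colors(c(2, 1, 2, 1), pal)
  expect_identical(cols, pal$colors[c(2, 1, 2, 1)])
  shuffled <- shuffle_palette(pal, 5)
  expect_identical(cluster_colors(c(1, 2), shuffled),
                   shuffled$colors[shuffled$permutation[1:2]])
  expect_error(cluster_colors(seq_len(length(pal$colors) + 1), pal),
               class = "spotgate_range_error")
})

test_that("compositing identities hold exactly", {
  img <- array(runif(40 * 50 * 3), c(40, 50, 3))
  # fully transparent overlay leaves every pixel untouched
  out <- render_overlay(img, x = c(10, 25), y = c(10, 30),
                        color = c("#FF0000", "#00FF00"), alpha = 0)
  expect_identical(out, img)

  # opaque dot of radius 1 replaces its center pixel exactly
  out1 <- render_overlay(img, x = 24.5, y = 19.5, color = "#3366CC",
                         alpha = 1, dot_radius = 1)
  expect_equal(unname(out1[20, 25, ]), c(0x33, 0x66, 0xCC) / 255)

  # two overlapping 50% dots match closed-form sequential source-over
  bg <- array(0.2, c(21, 21, 3))
  two <- render_overlay(bg, x = c(10.5, 10.5), y = c(10.5, 10.5),
                        color = c("#FF0000", "#0000FF"), alpha = 0.5,
                        dot_radius = 2)
  after1 <- 0.5 * c(1, 0, 0) + 0.5 * 0.2
  after2 <- 0.5 * c(0, 0, 1) + 0.5 * after1
  expect_equal(unname(two[11, 11, ]), after2)

  expect_error(render_overlay(img, 1, 1, "#000000", zoom = 300),
               class = "spotgate_range_error")
  expect_error(render_overlay(img, 1, 1, "#000000", zoom = 5),
               class = "spotgate_range_error")
})

test_that("zoom rescales the final raster by the requested percentage", {
  img <- array(runif(40 * 60 * 3), c(40, 60, 3))
  half <- render_overlay(img, numeric(0), numeric(0),
                         matrix(numeric(0), 0, 3), zoom = 50)
  expect_equal(dim(half), c(20, 30, 3))
  dbl <- render_overlay(img, numeric(0), numeric(0),
                        matrix(numeric(0), 0, 3), zoom = 200)
  expect_equal(dim(dbl), c(80, 120, 3))
  # nearest-neighbour upscale of an untouched image keeps original values
  expect_true(all(dbl %in% img))
})

test_that("affinely rescaling values with matching clip bounds leaves the render unchanged", {
  ds <- small_dataset(seed = 61, n_features = 3)
  f <- feature_names(ds$spots)[1]
  v <- ds$spots[[f]]
  tab2 <- ds$spots
  tab2[[f]] <- 3 * v + 7
  g1 <- gradient_spec("turbo", vmin = min(v), vmax = max(v))
  g2 <- gradient_spec("turbo", vmin = 3 * min(v) + 7, vmax = 3 * max(v) + 7)
  op <- opacity_spec("constant", 0.8)
  r1 <- render_feature_overlay(ds$image, ds$spots, f, g1, op)
  r2 <- render_feature_overlay(ds$image, tab2, f, g2, op)
  expect_identical(r1$image, r2$image)
})

test_that("rendering is deterministic down to the PNG payload", {
  ds <- small_dataset(seed = 62, n_features = 2)
  f <- feature_names(ds$spots)[1]
  render_once <- function() {
    res <- render_feature_overlay(ds$image, ds$spots, f,
                                  gradient_spec("inferno"),
                                  opacity_spec("gradient", 0.9))
    path <- tempfile(fileext = ".png")
    write_tissue_image(res$image, path)
    on.exit(unlink(path))
    readBin(path, "raw", file.info(path)$size)
  }
  expect_identical(render_once(), render_once())
})

test_that("slideshow writes one PNG per present feature plus a manifest", {
  ds <- small_dataset(seed = 63, n_features = 4)
  feats <- feature_names(ds$spots)[1:3]
  dir <- withr::local_tempdir()
  man <- slideshow(ds$image, ds$spots, feats, outdir = dir)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(file.path(dir, paste0(feats, ".png")))))

  # each frame equals the corresponding single render
  single <- render_feature_overlay(ds$image, ds$spots, feats[2])
  frame <- read_tissue_image(file.path(dir, paste0(feats[2], ".png")))
  expect_lt(max(abs(frame - pmin(pmax(single$image, 0), 1))), 1 / 255)

  # a missing feature is skipped, warned about and recorded
  dir2 <- withr::local_tempdir()
  expect_warning(man2 <- slideshow(ds$image, ds$spots, c(feats[1], "ghost"),
                                   outdir = dir2), "ghost")
  expect_identical(man2$status, c("ok", "missing"))

  dir3 <- withr::local_tempdir()
  man3 <- slideshow(ds$image, ds$spots, character(0), outdir = dir3)
  expect_equal(nrow(man3), 0)
  expect_true(file.exists(file.path(dir3, "slideshow_manifest.tsv")))
})
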