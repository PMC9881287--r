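# Group-wise differential feature analysis: Mann-Whitney U with an exact
# enumeration branch for small groups and a tie-corrected normal
# approximation otherwise, Bonferroni correction, fold change, and
# volcano-ready comparison tables.

#' Two-sided Mann-Whitney U test
#'
#' U is the rank-sum statistic of `a` under midrank tie handling:
#' \eqn{U = \sum \mathrm{rank}(a) - n_a(n_a+1)/2}. For small groups
#' (`min(n) <= 8` by default) the two-sided p-value is exact:
#' \eqn{P(|U - n_a n_b/2| \ge |U_{obs} - n_a n_b/2|)} over all
#' \eqn{\binom{n_a+n_b}{n_a}} equally likely group assignments of the
#' pooled (mid)ranks, computed by dynamic programming over the rank-sum
#' distribution. Otherwise a normal approximation with tie-corrected
#' variance and 0.5 continuity correction is used. When all pooled values
#' are identical, `U = n_a n_b / 2` and `p = 1`.
#'
#' @param a,b Numeric vectors (finite, length >= 1).
#' @param exact Force the exact branch on/off; `NULL` (default) selects
#'   exact when `min(length(a), length(b)) <= 8`.
#' @return List with `U`, `p.value`, `exact` (logical), `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b) || any(!is.finite(c(a, b)))) {
    .stop_spotgate("both groups must be non-empty with finite values",
                   "spotgate_stat_error")
  }
  na <- length(a); nb <- length(b); N <- na + nb
  if (is.null(exact)) exact <- min(na, nb) <= 8
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (length(unique(c(a, b))) == 1) {
    return(list(U = mu, p.value = 1, exact = exact, n1 = na, n2 = nb))
  }
  if (exact) {
    p <- .mwu_exact_p(r, na, U)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U - mu
      z <- (d - sign(d) * min(0.5, abs(d))) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p.value = p, exact = exact, n1 = na, n2 = nb)
}

# Exact two-sided p over all C(N, na) subsets: DP over the distribution of
# the sum of na doubled midranks (doubling makes them integers).
.mwu_exact_p <- function(r, na, U) {
  r2 <- as.integer(round(2 * r))
  N <- length(r2)
  S <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, nrow = na + 1, ncol = S + 1)
  counts[1, 1] <- 1
  for (e in r2) {
    kmax <- na
    for (k in kmax:1) {
      shifted <- c(rep(0, e), counts[k, seq_len(S + 1 - e)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  sums2 <- seq(0, S)                       # doubled rank sums
  w <- counts[na + 1, ]
  Uvals <- sums2 / 2 - na * (na + 1) / 2   # U for each rank sum
  mu <- na * (N - na) / 2
  extreme <- abs(Uvals - mu) >= abs(U - mu) - 1e-9
  sum(w[extreme]) / sum(w)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`, with `m` the number of tests performed in the
#' run (which may exceed `length(p)` if some features were dropped).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    .stop_spotgate("p-values must lie in [0, 1]", "spotgate_stat_error")
  }
  if (m < length(p)) {
    .stop_spotgate("m must be at least the number of p-values", "spotgate_stat_error")
  }
  pmin(1, m * p)
}

#' Fold change between two groups
#'
#' `fc = mean(a) / mean(b)` when both means are strictly positive
#' (after adding `offset`); otherwise the fold change is flagged
#' `fc_undefined` rather than silently patched — signed signature scores
#' have no natural ratio. `offset` lets users shift all values before the
#' ratio if they insist.
#'
#' @param a,b Numeric vectors.
#' @param offset Constant added to every value before taking means.
#' @return List with `fc`, `log2fc`, `flag` (`"ok"` or `"fc_undefined"`).
#' @export
fold_change <- function(a, b, offset = 0) {
  ma <- mean(a) + offset
  mb <- mean(b) + offset
  if (is.finite(ma) && is.finite(mb) && ma > 0 && mb > 0) {
    fc <- ma / mb
    list(fc = fc, log2fc = log2(fc), flag = "ok")
  } else {
    list(fc = NA_real_, log2fc = NA_real_, flag = "fc_undefined")
  }
}

#' Compare gate groups across all numeric features
#'
#' Splits spots into group 1 (members of any group-1 gate) and group 2
#' (members of any group-2 gate, or — in `group1_vs_rest` mode — every spot
#' not in group 1), then tests every numeric feature with
#' [mann_whitney_u()], Bonferroni-corrects over the number of features
#' tested, and computes fold changes of group means. Spots falling in both
#' groups are excluded with a warning.
#'
#' @param table A `spot_table` with pixel coordinates.
#' @param gates A `gate_set` with group assignments.
#' @param mode `"group1_vs_group2"` or `"group1_vs_rest"`.
#' @param features Feature columns to test; default all numeric features.
#' @param fc_offset Passed to [fold_change()].
#' @return A `comparison_table` data.frame with columns `feature`, `n1`,
#'   `n2`, `fc`, `log2fc`, `p_raw`, `p_adj`, `flag`; attributes `m`
#'   (tests performed), `mode`, `n1`, `n2`.
#' @export
compare_gates <- function(table, gates,
                          mode = c("group1_vs_group2", "group1_vs_rest"),
                          features = NULL, fc_offset = 0) {
  mode <- match.arg(mode)
  ids <- spot_ids(table)
  g1 <- spots_in_gates(table, gates, select = "group1")
  if (!length(g1)) .stop_spotgate("group 1 is empty", "spotgate_grouping_error")
  g2 <- if (mode == "group1_vs_group2") {
    spots_in_gates(table, gates, select = "group2")
  } else {
    setdiff(ids, g1)
  }
  if (!length(g2)) {
    .stop_spotgate(sprintf("%s is empty",
                           if (mode == "group1_vs_group2") "group 2" else "the rest (group 1 covers every spot)"),
                   "spotgate_grouping_error")
  }
  both <- intersect(g1, g2)
  if (length(both)) {
    warning(sprintf("%d spot(s) fall in both groups and are excluded", length(both)))
    g1 <- setdiff(g1, both); g2 <- setdiff(g2, both)
    if (!length(g1)) .stop_spotgate("group 1 is empty after overlap exclusion",
                                    "spotgate_grouping_error")
    if (!length(g2)) .stop_spotgate("group 2 is empty after overlap exclusion",
                                    "spotgate_grouping_error")
  }
  if (is.null(features)) features <- feature_names(table, numeric_only = TRUE)
  bad <- features[!vapply(features, function(f)
    f %in% names(table) && is.numeric(table[[f]]), logical(1))]
  if (length(bad)) {
    .stop_spotgate(sprintf("not numeric feature column(s): %s", paste(bad, collapse = ", ")),
                   "spotgate_lookup_error")
  }
  if (!length(features)) .stop_spotgate("no numeric features to test", "spotgate_stat_error")
  i1 <- which(ids %in% g1); i2 <- which(ids %in% g2)
  m <- length(features)
  rows <- lapply(features, function(f) {
    av <- table[[f]][i1]; bv <- table[[f]][i2]
    mw <- mann_whitney_u(av, bv)
    fc <- fold_change(av, bv, offset = fc_offset)
    data.frame(feature = f, n1 = length(av), n2 = length(bv),
               fc = fc$fc, log2fc = fc$log2fc,
               p_raw = mw$p.value, p_adj = NA_real_, flag = fc$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m = m)
  structure(out, m = m, mode = mode, n1 = length(i1), n2 = length(i2),
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("comparison_table: %d feature(s), n1 = %d, n2 = %d, mode = %s\n",
              nrow(x), attr(x, "n1"), attr(x, "n2"), attr(x, "mode")))
  ord <- order(x$p_adj, x$p_raw)
  print(utils::head(as.data.frame(x)[ord, ], 10))
  invisible(x)
}

#' Volcano plot coordinates
#'
#' One point per `flag == "ok"` feature: `x = log2fc`,
#' `y = -log10(p)` with p floored at 1e-300 so the y-coordinate stays
#' finite.
#'
#' @param cmp A `comparison_table`.
#' @param p Which p-value drives the y-axis: `"adjusted"` (default) or
#'   `"raw"`.
#' @return data.frame with `feature`, `x`, `y`.
#' @export
volcano_points <- function(cmp, p = c("adjusted", "raw")) {
  p <- match.arg(p)
  ok <- cmp$flag == "ok"
  pv <- if (p == "adjusted") cmp$p_adj[ok] else cmp$p_raw[ok]
  data.frame(feature = cmp$feature[ok],
             x = cmp$log2fc[ok],
             y = -log10(pmax(pv, 1e-300)),
             stringsAsFactors = FALSE)
}

#' Extract a tested feature for overlay rendering
#'
#' @param cmp A `comparison_table` (the feature must have been tested).
#' @param feature Feature name.
#' @param table The source `spot_table`.
#' @return Named numeric vector (names are spot tags).
#' @export
select_feature <- function(cmp, feature, table) {
  if (!feature %in% cmp$feature) {
    .stop_spotgate(sprintf("feature '%s' not in the comparison table", feature),
                   "spotgate_lookup_error")
  }
  if (!feature %in% names(table)) {
    .stop_spotgate(sprintf("feature '%s' not in the spot table", feature),
                   "spotgate_lookup_error")
  }
  stats::setNames(as.numeric(table[[feature]]), spot_ids(table))
}

#' Write a comparison table as TSV
#'
#' A `#`-prefixed header line records the number of tests behind the
#' Bonferroni correction and the comparison mode.
#'
#' @param cmp A `comparison_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(cmp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# features_tested=%d mode=%s n1=%d n2=%d",
                     attr(cmp, "m"), attr(cmp, "mode"),
                     attr(cmp, "n1"), attr(cmp, "n2")), con)
  df <- as.data.frame(cmp)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 15, trim = TRUE)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a comparison table written by [write_comparison_table()]
#' @param path TSV path.
#' @return A `comparison_table`.
#' @export
read_comparison_table <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.integer(sub(".*features_tested=(\\d+).*", "\\1", hdr))
  mode <- sub(".*mode=(\\S+).*", "\\1", hdr)
  structure(df, m = m, mode = mode,
            n1 = df$n1[1], n2 = df$n2[1],
            class = c("comparison_table", "data.frame"))
}

#' Render a volcano plot to PNG
#'
#' log2 fold change against `-log10(p)` across all tested features, with
#' the conventional significance guides.
#'
#' @param cmp A `comparison_table`.
#' @param path Output PNG path.
#' @param p `"adjusted"` or `"raw"` y-axis.
#' @param width,height Device size in pixels.
#' @param alpha_line Significance level drawn as a horizontal guide.
#' @return `path`, invisibly.
#' @export
plot_volcano <- function(cmp, path, p = c("adjusted", "raw"),
                         width = 800, height = 600, alpha_line = 0.05) {
  p <- match.arg(p)
  pts <- volcano_points(cmp, p = p)
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  sig <- pts$y >= -log10(alpha_line)
  graphics::plot(pts$x, pts$y, pch = 19, cex = 0.7,
                 col = ifelse(sig, "#D62728", "#666666"),
                 xlab = "log2(FC)", ylab = "-log10(p)",
                 main = sprintf("Gate comparison (%s p, %d features)",
                                p, attr(cmp, "m")))
  graphics::abline(h = -log10(alpha_line), lty = 2, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey70")
  invisible(path)
}
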