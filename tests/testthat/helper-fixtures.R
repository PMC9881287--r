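# Small synthetic datasets shared across tests.

small_dataset <- function(seed = 42, n_features = 20, ...) {
  make_dataset(synthetic_spec(n_rows = 10, n_cols = 10, n_features = n_features,
                              n_planted = 2, seed = seed, ...))
}

square_gate <- function(name = "sq", x0 = 0, y0 = 0, side = 10,
                        group = "none") {
  polygon_gate(name, cbind(c(x0, x0 + side, x0 + side, x0),
                           c(y0, y0, y0 + side, y0 + side)),
               group = group)
}

# A 60-spot dataset split into two 30-spot halves by disjoint gates
# (left/right of the hexagonal grid), for group comparisons at n = 30.
halved_dataset <- function(seed, n_features) {
  ds <- make_dataset(synthetic_spec(n_rows = 10, n_cols = 6, spacing = 20,
                                    n_features = n_features, n_planted = 0,
                                    seed = seed))
  W <- dim(ds$image)[2]; H <- dim(ds$image)[1]
  cut <- 37.5  # between column 2 (odd-row offset) and column 3 in pixel space
  left <- polygon_gate("left", cbind(c(0, cut, cut, 0), c(0, 0, H, H)),
                       group = "group1")
  right <- polygon_gate("right", cbind(c(cut, W, W, cut), c(0, 0, H, H)),
                        group = "group2")
  ds$gates <- gate_set(list(left, right))
  ds
}
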