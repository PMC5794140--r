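# Shared fixtures: small grids and landscapes built in code.

mkr <- function(values, nrow = NULL, ncol = NULL, pixel = 30, xmin = 0,
                ymin = 0, crs = metric_crs()) {
  if (!is.matrix(values)) values <- matrix(values, nrow, ncol)
  sep_raster(values, xmin = xmin, ymin = ymin, pixel = pixel, crs = crs)
}

# compact landscape for fast end-to-end tests
small_layout <- function(nrow = 80, ncol = 80, n_villages = 3) {
  landscape_layout(nrow = nrow, ncol = ncol, pixel = 30,
                   n_villages = n_villages,
                   fractions = c(field = 0.45, shrubland = 0.18,
                                 depression = 0.05, homestead = 0.03,
                                 water = 0.02, forest = 0.02, urban = 0.01))
}

small_landscape <- function(seed = 1, noise_sd = 0.01, ...) {
  generate_landscape(spectral_signature_model(noise_sd = noise_sd),
                     small_layout(...), seed = seed)
}

# random layer stack + random tree over it, for equivalence tests
random_layers <- function(n = 3, nrow = 16, ncol = 16) {
  stats::setNames(
    lapply(seq_len(n), function(i) mkr(matrix(stats::runif(nrow * ncol),
                                              nrow, ncol))),
    paste0("L", seq_len(n)))
}

random_tree <- function(layer_names, depth = 3) {
  classes <- patch_classes()
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.25) return(sample(classes, 1))
    decision_node(sample(layer_names, 1),
                  sample(c("<", "<=", ">", ">="), 1),
                  stats::runif(1), build(d - 1), build(d - 1))
  }
  # force at least one internal node
  decision_node(sample(layer_names, 1), ">=", stats::runif(1),
                build(depth - 1), build(depth - 1))
}
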