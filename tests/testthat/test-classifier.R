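test_that("burn_overlays assigns exactly the pixels whose centers fall inside", {
  tmpl <- mkr(matrix(0, 10, 10), pixel = 30)  # extent 300 x 300
  # square covering exactly the centers of a 2 x 2 pixel block
  sq <- list(x = c(50, 130, 130, 50), y = c(50, 50, 130, 130),
             class = "homestead")
  burned <- burn_overlays(tmpl, list(sq))
  bv <- rast_values(burned)
  expect_equal(sum(bv == patch_code("homestead"), na.rm = TRUE), 4)
  # cross-check against an independent even-odd point-in-polygon count
  nr <- 10
  centers <- expand.grid(row = 1:10, col = 1:10)
  cx <- (centers$col - 0.5) * 30
  cy <- (nr - centers$row + 0.5) * 30
  expect_equal(sum(oracle_pip(sq, cx, cy)), 4)
  inside <- which(oracle_pip(sq, cx, cy))
  expect_setequal(which(!is.na(bv)),
                  (centers$col[inside] - 1) * nr + centers$row[inside])

  # later overlays override earlier ones
  dep <- list(x = c(20, 160, 160, 20), y = c(20, 20, 160, 160),
              class = "depression")
  urb <- list(x = c(50, 130, 130, 50), y = c(50, 50, 130, 130),
              class = "urban")
  b2 <- rast_values(burn_overlays(tmpl, list(dep, urb)))
  expect_equal(sum(b2 == patch_code("urban"), na.rm = TRUE), 4)
  # centers at 45,75,105,135 lie in [20,160] on each axis: 16 cells, 4 urban
  expect_equal(sum(b2 == patch_code("depression"), na.rm = TRUE), 16 - 4)

  # polygon outside the extent assigns nothing; empty list is valid
  far <- list(x = c(1000, 1100, 1100, 1000), y = c(0, 0, 100, 100),
              class = "water")
  expect_true(all(is.na(rast_values(burn_overlays(tmpl, list(far))))))
  expect_true(all(is.na(rast_values(burn_overlays(tmpl, list())))))
})

test_that("detect_built_patches applies size and village rules", {
  v <- matrix(0, 30, 30)
  v[5:7, 5:7] <- 10          # 9-pixel block -> homestead
  v[15:29, 10:29] <- 10      # 300-pixel block -> urban if near a village
  br <- mkr(v, pixel = 30)
  vill <- data.frame(x = 20 * 30 - 15, y = (30 - 20) * 30 + 15)  # on big block
  got <- detect_built_patches(br, threshold = 5, size_limits = c(2, 100),
                              village_points = vill,
                              village_radius_m = 100)
  classes <- vapply(got, function(o) o$class, character(1))
  expect_setequal(classes, c("homestead", "urban"))
  n_px <- vapply(got, function(o) o$n_pixels, numeric(1))
  expect_equal(sort(n_px), c(9, 300))
  # polygons re-rasterize to the original components
  burned <- burn_overlays(br, got)
  expect_equal(sum(rast_values(burned) == patch_code("homestead"),
                   na.rm = TRUE), 9)
  expect_equal(sum(rast_values(burned) == patch_code("urban"),
                   na.rm = TRUE), 300)
  # without a village nearby the large block is dropped
  got2 <- detect_built_patches(br, threshold = 5, size_limits = c(2, 100),
                               village_points = NULL)
  expect_equal(vapply(got2, function(o) o$class, character(1)), "homestead")
  # threshold is strict: uniform raster at the boundary gives nothing
  expect_equal(detect_built_patches(mkr(matrix(5, 8, 8), pixel = 30),
                                    threshold = 5), list())
})

test_that("8-connected components are found as single patches", {
  v <- matrix(0, 10, 10)
  v[2, 2] <- 10; v[3, 3] <- 10; v[4, 4] <- 10   # diagonal chain
  got <- detect_built_patches(mkr(v, pixel = 30), threshold = 5,
                              size_limits = c(2, 100))
  expect_equal(sum(vapply(got, function(o) o$n_pixels, numeric(1)) == 3),
               length(got))
})

test_that("derive_tree places midpoint thresholds and peels in order", {
  # two classes, one layer, means 0 and 10, both sd 1: M = 5, split at 5
  sig <- data.frame(class = c("water", "field"), layer = "L", n = 10,
                    mean = c(0, 10), sd = c(1, 1))
  tree <- derive_tree(sig, class_order = c("water", "field"))
  expect_s3_class(tree, "sep_node")
  expect_equal(tree$threshold, 5)
  expect_equal(tree$layer, "L")
  expect_equal(tree$op, ">=")
  expect_equal(classify_pixel(tree, c(L = 0)), "water")
  expect_equal(classify_pixel(tree, c(L = 10)), "field")
  # ties route to the true (>=) branch
  expect_equal(classify_pixel(tree, c(L = 5)), "field")

  # identical signatures cannot be separated
  sig2 <- data.frame(class = c("water", "field"), layer = "L", n = 10,
                     mean = c(3, 3), sd = c(1, 1))
  expect_error(derive_tree(sig2, class_order = c("water", "field")),
               "not separable")

  # three well-separated classes yield exactly 2 internal nodes
  sig3 <- data.frame(class = rep(c("water", "field", "bare_soil"), 2),
                     layer = rep(c("A", "B"), each = 3), n = 10,
                     mean = c(0, 10, 20, 5, 5, 5), sd = 1)
  tree3 <- derive_tree(sig3, class_order = c("water", "field", "bare_soil"))
  expect_equal(tree_size(tree3), 2L)
  expect_equal(classify_pixel(tree3, c(A = 0, B = 5)), "water")
  expect_equal(classify_pixel(tree3, c(A = 10, B = 5)), "field")
  expect_equal(classify_pixel(tree3, c(A = 20, B = 5)), "bare_soil")
})

test_that("derive_tree requires the class to be extremal on the layer", {
  # class 'field' lies between the two others on the only layer: no single
  # threshold can peel it first
  sig <- data.frame(class = rep(c("field", "water", "bare_soil"), 1),
                    layer = "L", n = 10, mean = c(10, 0, 20), sd = 0.1)
  expect_error(derive_tree(sig, class_order = c("field", "water",
                                                "bare_soil")),
               "not separable")
  # but peeling extremes first works
  tree <- derive_tree(sig, class_order = c("water", "bare_soil", "field"))
  expect_equal(tree_size(tree), 2L)
})

test_that("classify matches a hand-traced route through a 3-node tree", {
  tree <- decision_node(
    "ndvi", ">=", 0.5, "forest",
    decision_node("wet", ">=", 0.2,
                  decision_node("bright", ">=", 0.3, "urban", "water"),
                  "bare_soil"))
  # pixel: ndvi 0.4 (no), wet 0.25 (yes), bright 0.1 (no) -> water
  expect_equal(classify_pixel(tree, c(ndvi = 0.4, wet = 0.25, bright = 0.1)),
               "water")
  layers <- list(ndvi = mkr(matrix(0.4, 1, 1)),
                 wet = mkr(matrix(0.25, 1, 1)),
                 bright = mkr(matrix(0.1, 1, 1)))
  pm <- classify(layers, classifier_spec(tree))
  expect_equal(patch_label(rast_values(pm)[1, 1]), "water")
})

test_that("classify is total, deterministic, and nodata-preserving", {
  set.seed(99)
  layers <- random_layers(3, 12, 12)
  tree <- random_tree(names(layers), 3)
  pm1 <- classify(layers, classifier_spec(tree))
  pm2 <- classify(layers, classifier_spec(tree))
  expect_identical(rast_values(pm1), rast_values(pm2))
  expect_false(anyNA(rast_values(pm1)))
  # nodata in: nodata out
  v <- rast_values(layers[[1]]); v[3, 4] <- NA
  rast_values(layers[[1]]) <- v
  pm3 <- classify(layers, classifier_spec(tree))
  if (layers_used <- names(layers)[1] %in% tree_layers(tree)) {
    expect_true(is.na(rast_values(pm3)[3, 4]))
  }
  all_na <- lapply(layers, function(l) rast_like(l, NA_real_))
  pm4 <- classify(all_na, classifier_spec(tree))
  expect_true(all(is.na(rast_values(pm4))))
  # a tree layer missing from the stack fails before any pixel work
  expect_error(classify(layers[1], classifier_spec(
    decision_node("nope", ">=", 0, "field", "water"))), "missing layer")
})

test_that("vectorized classification equals per-pixel recursion on random instances", {
  set.seed(123)
  for (i in 1:20) {
    layers <- random_layers(sample(2:4, 1), 16, 16)
    tree <- random_tree(names(layers), sample(2:4, 1))
    pm <- classify(layers, classifier_spec(tree))
    expect_identical(rast_values(pm), oracle_classify(layers, tree))
  }
})

test_that("overlay pixels are never overwritten by the tree", {
  land <- small_landscape(seed = 17)
  pts <- suppressWarnings(sample_transects(land$truth, n_transects = 12,
                                           gps_noise_m = 0, seed = 17))
  layers <- compute_indices(land$scene, dem = land$dem)
  sig <- suppressWarnings(class_signatures(layers, pts))
  tree <- derive_tree(sig, class_order = c("water", "shrubland", "field",
                                           "bare_soil"))
  spec <- classifier_spec(tree, overlays = land$truth$overlays)
  pm <- classify(layers, spec)
  burned <- burn_overlays(land$truth$patch, land$truth$overlays)
  bv <- rast_values(burned)
  expect_identical(rast_values(pm)[!is.na(bv)], bv[!is.na(bv)])
})

test_that("noise-free well-separated scenes are recovered exactly", {
  land <- small_landscape(seed = 23, noise_sd = 0)
  pts <- suppressWarnings(sample_transects(land$truth, n_transects = 15,
                                           gps_noise_m = 0, seed = 23))
  layers <- compute_indices(land$scene, dem = land$dem)
  sig <- suppressWarnings(class_signatures(layers, pts))
  tree <- derive_tree(sig, class_order = c("water", "forest", "shrubland",
                                           "field", "bare_soil"))
  pm <- classify(layers, classifier_spec(tree, land$truth$overlays))
  truthv <- rast_values(land$truth$patch)
  predv <- rast_values(pm)
  # forest may lack calibration points in a given draw; compare on classes
  # the tree knows plus all overlay classes
  known <- patch_code(c(unique(sig$class), "homestead", "depression",
                        "urban"))
  sel <- truthv %in% known
  expect_equal(mean(predv[sel] == truthv[sel]), 1)
})

test_that("classification accuracy does not increase with signature noise", {
  accs <- c()
  for (sdv in c(0, 0.01, 0.05, 0.15)) {
    land <- small_landscape(seed = 40, noise_sd = sdv)
    pts <- suppressWarnings(sample_transects(land$truth, n_transects = 15,
                                             gps_noise_m = 0, seed = 40))
    layers <- compute_indices(land$scene, dem = land$dem)
    sig <- suppressWarnings(class_signatures(layers, pts))
    tree <- derive_tree(sig, class_order = c("water", "shrubland", "field",
                                             "bare_soil"), m_threshold = 0.2)
    pm <- classify(layers, classifier_spec(tree, land$truth$overlays))
    truthv <- rast_values(land$truth$patch)
    sel <- truthv %in% patch_code(c(unique(sig$class), "homestead",
                                    "depression", "urban"))
    accs <- c(accs, mean(rast_values(pm)[sel] == truthv[sel]))
  }
  expect_true(all(diff(accs) <= 0.005))
})

test_that("trees round-trip through the YAML text serialization", {
  set.seed(7)
  for (i in 1:5) {
    tree <- random_tree(paste0("L", 1:3), 3)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_tree(tree, path)
    back <- read_tree(path)
    vals <- stats::setNames(runif(3), paste0("L", 1:3))
    expect_equal(classify_pixel(back, vals), classify_pixel(tree, vals))
    expect_equal(tree_size(back), tree_size(tree))
  }
  # nodata leaves survive too
  tnd <- decision_node("L1", "<", 0.5, NA, "field")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tree(tnd, path)
  expect_true(is.na(classify_pixel(read_tree(path), c(L1 = 0.1))))
})
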