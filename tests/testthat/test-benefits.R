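test_that("one village owns the whole extent; two split at the bisector", {
  tmpl <- mkr(matrix(0, 10, 10), pixel = 30)  # 300 x 300 extent
  one <- voronoi_territories(data.frame(x = 100, y = 100, village_id = 1),
                             tmpl)
  expect_equal(one$areas[[1]], 300 * 300)
  # villages at (0,0) and (10,0): boundary at x = 5
  tmpl2 <- mkr(matrix(0, 10, 10), pixel = 1)
  two <- voronoi_territories(data.frame(x = c(0, 10), y = c(0, 0),
                                        village_id = 1:2), tmpl2)
  expect_equal(two$areas[["1"]], 50)   # left half of the 10 x 10 square
  expect_equal(two$areas[["2"]], 50)
  expect_equal(max(two$polygons[["1"]]$x), 5)
  expect_equal(min(two$polygons[["2"]]$x), 5)
  expect_error(
    voronoi_territories(data.frame(x = c(1, 1), y = c(2, 2),
                                   village_id = 1:2), tmpl),
    "duplicate")
})

test_that("random village sets partition the extent and contain their seeds", {
  set.seed(77)
  tmpl <- mkr(matrix(0, 40, 60), pixel = 25)
  ext <- rast_extent(tmpl)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    v <- data.frame(x = runif(n, ext["xmin"], ext["xmax"]),
                    y = runif(n, ext["ymin"], ext["ymax"]),
                    village_id = seq_len(n))
    terr <- voronoi_territories(v, tmpl)
    total <- (ext["xmax"] - ext["xmin"]) * (ext["ymax"] - ext["ymin"])
    expect_equal(sum(terr$areas), unname(total), tolerance = 1e-9)
    for (k in seq_len(n)) {
      expect_true(points_in_polygon(terr$polygons[[k]], v$x[k], v$y[k]))
    }
  }
})

test_that("distance weights follow the 1.2 -> 0.8 five-zone schedule", {
  mask_v <- matrix(0, 20, 20)
  mask_v[10, 10] <- 1
  mask <- mkr(mask_v, pixel = 30)
  w <- homestead_distance_weights(mask, n_zones = 5, zone_width_m = 60)
  wv <- rast_values(w)
  expect_equal(wv[10, 10], 1.2)              # inside a homestead: weight 1.2
  expect_equal(wv[1, 1], 0.8)                # beyond the outermost zone
  # middle zone of 5 interpolates to exactly 1.0
  # pixel at distance 150 m (5 px): zone floor(150/60)+1 = 3
  expect_equal(wv[10, 15], 1.0)
  expect_true(all(wv >= 0.8 & wv <= 1.2))
  expect_error(homestead_distance_weights(mkr(matrix(0, 5, 5))), "empty")
})

test_that("distance transform agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:5) {
    mask_v <- matrix(runif(15 * 17) < 0.1, 15, 17)
    if (!any(mask_v)) mask_v[3, 3] <- TRUE
    mask <- mkr(mask_v + 0, pixel = 30)
    w <- homestead_distance_weights(mask, zone_width_m = 45)
    d_oracle <- oracle_edt(mask_v, 30)
    zone_oracle <- pmin(floor(d_oracle / 45) + 1, 5)
    w_oracle <- 1.2 + (zone_oracle - 1) * (0.8 - 1.2) / 4
    expect_equal(rast_values(w), matrix(w_oracle, 15, 17))
  }
})

test_that("shrubland-area weights bin village fractions per the schedule", {
  # patch map: village 1 territory all field (zero shrubland -> 0.8);
  # village 2 territory ~15% shrubland (mid category -> 1.2)
  v <- matrix(patch_code("field"), 20, 20)
  v[, 11:20][runif(200) < 0] <- 0  # keep deterministic; fill below
  sh <- patch_code("shrubland")
  set.seed(5)
  right <- which(col(v) > 10)
  v[sample(right, 30)] <- sh       # 30/200 = 15% of right half
  pm <- mkr(v, pixel = 30)
  vill <- data.frame(x = c(150, 450), y = c(300, 300), village_id = 1:2)
  terr <- voronoi_territories(vill, pm)
  w <- shrubland_area_weights(pm, terr)
  stats <- attr(w, "village_stats")
  expect_equal(stats$shrubland_fraction, c(0, 0.15))
  expect_equal(stats$weight, c(0.8, 1.2))
  # all pixels of one territory share one weight
  tr <- rast_values(territory_raster(terr, pm))
  expect_equal(unique(rast_values(w)[tr == 1]), 0.8)
  expect_equal(unique(rast_values(w)[tr == 2]), 1.2)
  # villages in the same category get identical weights
  expect_error(shrubland_area_weights(pm, terr, breakpoints = c(.1, .1, .2,
                                                                .3)),
               "strictly increasing")
  expect_error(shrubland_area_weights(pm, terr,
                                      weights = c(0.5, 1, 1, 1, 1)),
               "0.8")
})

test_that("benefit values compose score and weights as specified", {
  # single-pixel cases over a 2 x 2 map
  v <- matrix(c(patch_code("field"), patch_code("water"),
                patch_code("field"), patch_code("shrubland")), 2, 2)
  pm <- mkr(v, pixel = 30)
  tab <- default_score_table()
  tab$scores["field", "income"] <- 4
  dist_w <- rast_like(pm, matrix(c(1.2, 1.2, 0.8, 1.0), 2, 2))
  area_w <- rast_like(pm, 1.1)
  inc <- compute_benefit_map(pm, tab, dist_w, area_w, "income")
  iv <- rast_values(inc)
  expect_equal(iv[1, 1], 4 * 1.2)     # field, nearest zone: 4 x 1.2 = 4.8
  expect_equal(iv[2, 1], 0)           # water scores 0 for every benefit
  expect_equal(iv[1, 2], 4 * 0.8)
  # saving/insurance ignores distance for fields
  sav <- compute_benefit_map(pm, tab, dist_w, area_w, "saving_insurance")
  sv <- rast_values(sav)
  expect_equal(sv[1, 1], tab$scores["field", "saving_insurance"])
  expect_equal(sv[1, 2], tab$scores["field", "saving_insurance"])
  # shrubland saving/insurance is area-weighted instead
  expect_equal(sv[2, 2], tab$scores["shrubland", "saving_insurance"] * 1.1)
  # a mapped class without a score entry aborts
  bad <- mkr(matrix(9L, 2, 2), pixel = 30)
  expect_error(compute_benefit_map(bad, tab, dist_w, area_w, "income"),
               "score")
})

test_that("default score table obeys the documented structure", {
  tab <- default_score_table()
  expect_true(all(tab$scores[c("water", "urban"), ] == 0))
  expect_true(all(tab$scores[social_patches(), "saving_insurance"] > 0))
  expect_true(all(tab$scores[c("bare_soil", "shrubland", "forest"),
                             "annual_crops"] == 0))
  expect_true(all(!tab$distance_weighted[, "saving_insurance"]))
  expect_setequal(rownames(tab$distance_weighted)[
    rowSums(tab$distance_weighted) > 0], c("field", "shrubland"))
  expect_setequal(colnames(tab$area_weighted)[
    tab$area_weighted["shrubland", ]],
    c("nutritional_diversity_medicinal", "material_assets_energy",
      "saving_insurance"))
  expect_error(benefit_score_table(tab$scores * -1, tab$distance_weighted,
                                   tab$area_weighted), "nonnegative")
  bad <- tab$scores; bad["water", "income"] <- 1
  expect_error(benefit_score_table(bad, tab$distance_weighted,
                                   tab$area_weighted), "land cover")
})

test_that("distance-weighted benefits decay monotonically across zones", {
  mask_v <- matrix(0, 25, 25); mask_v[13, 13] <- 1
  mask <- mkr(mask_v, pixel = 30)
  dist_w <- homestead_distance_weights(mask, zone_width_m = 90)
  pm <- rast_like(mask, matrix(patch_code("field"), 25, 25))
  area_w <- rast_like(mask, 1)
  tab <- default_score_table()
  for (b in setdiff(benefit_labels(), "saving_insurance")) {
    bm <- compute_benefit_map(pm, tab, dist_w, area_w, b)
    zones <- rast_values(attr(dist_w, "zones"))
    vals <- vapply(sort(unique(c(zones))), function(z)
      mean(rast_values(bm)[zones == z]), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("heat map is the exact sum of the five benefit maps", {
  set.seed(8)
  maps <- lapply(1:5, function(i) mkr(matrix(runif(100), 10, 10)))
  hm <- heat_map(maps)
  expect_equal(rast_values(hm), oracle_heat(maps), tolerance = 1e-15)
  # all-constant case
  ones <- lapply(1:5, function(i) mkr(matrix(1, 4, 4)))
  expect_true(all(rast_values(heat_map(ones)) == 5))
  zeros <- lapply(1:5, function(i) mkr(matrix(0, 4, 4)))
  expect_true(all(rast_values(heat_map(zeros)) == 0))
  # nodata propagates; wrong count rejected
  m2 <- maps; v <- rast_values(m2[[3]]); v[2, 2] <- NA
  rast_values(m2[[3]]) <- v
  expect_true(is.na(rast_values(heat_map(m2))[2, 2]))
  expect_error(heat_map(maps[1:4]), "exactly 5")
})

test_that("zero-scoring classes contribute zero regardless of weights", {
  v <- matrix(c(patch_code("shrubland"), patch_code("water"),
                patch_code("urban"), patch_code("bare_soil")), 2, 2)
  pm <- mkr(v, pixel = 30)
  tab <- default_score_table()
  dist_w <- rast_like(pm, 1.2)
  area_w <- rast_like(pm, 1.2)
  crops <- compute_benefit_map(pm, tab, dist_w, area_w, "annual_crops")
  expect_true(all(rast_values(crops) == 0))
})
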