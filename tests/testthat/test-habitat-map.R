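train_on_scene <- function(sc, seed = 34, n = 1500) {
  # labelled points over sea pixels with a reef-driven label
  withr::with_seed(seed, {
    sea <- which(sc$land == 0L, arr.ind = TRUE)
    pick <- sea[sample.int(nrow(sea), n, replace = TRUE), ]
    ctr <- cell_xy(sc$grid, pick[, 1], pick[, 2])
    pts <- data.frame(label = 0L, animal_id = 1, segment_id = 1,
                      timestamp = as.POSIXct(sc$dates[1], tz = "UTC"),
                      x = ctr$x, y = ctr$y)
    tab <- annotate(pts, sc)
    pr <- stats::plogis(2 - 2.5 * tab$distance_to_reef / 1000)
    tab$label <- stats::rbinom(n, 1, pr)
    tab
  })
}

test_that("grid prediction equals point-wise annotate-then-predict", {
  sc <- build_scene(7, 32, 32, 3)
  tab <- train_on_scene(sc)
  m <- brt_fit(tab, brt_config(learning_rate = 0.1, max_trees = 120,
                               tree_complexity = 2))
  surf <- predict_surface(m, sc, sc$dates[2])
  expect_true(all(is.na(surf$prob[sc$land == 1L])))
  pv <- surf$prob[sc$land == 0L]
  expect_true(all(pv >= 0 & pv <= 1, na.rm = TRUE))
  withr::with_seed(41, {
    sea <- which(sc$land == 0L, arr.ind = TRUE)
    pick <- sea[sample.int(nrow(sea), 10), ]
  })
  ctr <- cell_xy(sc$grid, pick[, 1], pick[, 2])
  pts <- data.frame(label = 0L, animal_id = 1, segment_id = 1,
                    timestamp = as.POSIXct(sc$dates[2], tz = "UTC"),
                    x = ctr$x, y = ctr$y)
  ann <- annotate(pts, sc)
  p_pt <- predict(m, ann)
  p_grid <- surf$prob[cbind(pick[, 1], pick[, 2])]
  expect_equal(p_grid, p_pt, tolerance = 1e-9)
})

test_that("spatially constant scenes give constant surfaces; equal dynamics give equal surfaces", {
  sc <- tiny_scene()
  # make every layer constant
  for (nm in names(sc$static)) sc$static[[nm]][] <- 1
  for (nm in names(sc$dynamic)) sc$dynamic[[nm]][] <- 5
  tab <- data.frame(label = rep(0:1, each = 100),
                    distance_to_reef = 1, distance_to_coast = 1,
                    distance_to_facility = 1, distance_to_river = 1,
                    seagrass_probability = 1, geohabitat = 1,
                    temperature = 5, salinity = 5, current_speed = 5)
  m <- suppressMessages(brt_fit(tab, brt_config(max_trees = 5,
                                                learning_rate = 0.1)))
  s1 <- predict_surface(m, sc, sc$dates[1])
  s2 <- predict_surface(m, sc, sc$dates[2])
  v <- s1$prob[sc$land == 0L]
  expect_equal(length(unique(v)), 1)
  expect_equal(unique(v),
               unname(predict(m, tab[1, , drop = FALSE])), tolerance = 1e-12)
  expect_identical(s1$prob, s2$prob)  # identical dynamic fields
  # missing predictor layer fails with the layer's name
  m$predictors <- c(m$predictors, "bathymetry")
  expect_error(predict_surface(m, sc, sc$dates[1]), "bathymetry")
})

test_that("suitable-area arithmetic is exact", {
  pr <- matrix(NA_real_, 10, 10)
  pr[1:100] <- 0.2
  pr[1:8] <- 0.7
  surf <- fake_surface(pr, px = 500)  # 0.25 km2 pixels
  a <- suitable_area(surf, 0.5)
  expect_equal(a$area_km2, 2.0)
  expect_equal(a$percent_of_modelled_area, 8)
  # all-zero surface
  expect_equal(suitable_area(fake_surface(matrix(0, 5, 5)))$area_km2, 0)
  # pixels exactly at the threshold are not suitable (strict >)
  pr2 <- matrix(0.5, 4, 4)
  expect_equal(suitable_area(fake_surface(pr2), 0.5)$n_suitable, 0)
  # threshold monotonicity
  withr::with_seed(42, {
    pr3 <- matrix(stats::runif(100), 10, 10)
  })
  s3 <- fake_surface(pr3)
  expect_lte(suitable_area(s3, 0.6)$area_km2, suitable_area(s3, 0.5)$area_km2)
})

test_that("zone accounting assigns pixel centres and sums to 100", {
  withr::with_seed(43, {
    pr <- matrix(stats::runif(32 * 32), 32, 32)
  })
  surf <- fake_surface(pr, px = 500)
  W <- 32 * 500
  whole <- zone_polygon("all", c(-1, W + 1, W + 1, -1), c(-1, -1, W + 1, W + 1))
  zt <- zone_overlap(surf, list(whole))
  expect_equal(zt$percent_of_suitable[zt$zone == "all"], 100)
  expect_equal(sum(zt$percent_of_suitable), 100)
  # two disjoint half-plane zones: percentages reflect the pixel split
  left <- zone_polygon("left", c(-1, W / 2, W / 2, -1), c(-1, -1, W + 1, W + 1))
  right <- zone_polygon("right", c(W / 2, W + 1, W + 1, W / 2),
                        c(-1, -1, W + 1, W + 1))
  zt2 <- zone_overlap(surf, list(left, right))
  expect_equal(sum(zt2$percent_of_suitable), 100)
  expect_equal(zt2$area_km2[3], 0)  # nothing outside the two half planes
  # pixel-centre assignment equals a per-pixel containment loop
  tri <- zone_polygon("tri", c(0, W, 0), c(0, 0, W))
  zt3 <- zone_overlap(surf, list(tri), threshold = 0.5)
  suit <- which(pr > 0.5, arr.ind = TRUE)
  inside <- 0
  for (r in seq_len(nrow(suit))) {
    cx <- (suit[r, 2] - 0.5) * 500
    cy <- (suit[r, 1] - 0.5) * 500
    if (point_in_polygon(cx, cy, tri$x, tri$y)) inside <- inside + 1
  }
  expect_equal(zt3$area_km2[1], inside * 0.25)
  # invalid geometry rejected
  expect_error(zone_overlap(surf, list(list(name = "bad"))), "invalid zone")
  expect_error(zone_polygon("bad", c(0, 1), c(0, 1)), "invalid polygon")
})

test_that("temporal change arithmetic, conservation and symmetry", {
  pr_a <- matrix(0.1, 16, 16)
  pr_a[1:101] <- 0.9
  pr_b <- pr_a
  pr_b[102:128] <- 0.9  # 27 extra suitable pixels on top of 101
  a <- fake_surface(pr_a); b <- fake_surface(pr_b)
  ch <- temporal_change(a, b)
  expect_equal(ch$percent_change, 100 * 27 / 101, tolerance = 1e-12)
  expect_equal(ch$n_gained, 27)
  expect_equal(ch$n_lost, 0)
  expect_equal(ch$n_stable, 101)
  # identical surfaces: zero change, all stable
  ch0 <- temporal_change(a, a)
  expect_equal(ch0$percent_change, 0)
  expect_equal(ch0$n_gained + ch0$n_lost, 0)
  # gained/lost/stable partition the suitable union
  withr::with_seed(44, {
    x <- fake_surface(matrix(stats::runif(256), 16, 16))
    y <- fake_surface(matrix(stats::runif(256), 16, 16))
  })
  ch2 <- temporal_change(x, y)
  union_n <- sum(x$prob > 0.5 | y$prob > 0.5)
  expect_equal(ch2$n_gained + ch2$n_lost + ch2$n_stable, union_n)
  # swapping arguments negates the absolute area difference
  ch3 <- temporal_change(y, x)
  expect_equal(ch3$area_b_km2 - ch3$area_a_km2,
               -(ch2$area_b_km2 - ch2$area_a_km2))
  # zero baseline: undefined percent change reported as NA
  z <- fake_surface(matrix(0.1, 16, 16))
  expect_true(is.na(temporal_change(z, a)$percent_change))
})
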